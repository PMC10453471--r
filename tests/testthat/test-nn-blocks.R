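# Closed-form parameter counts are verified against a per-layer enumeration
# oracle: walk the module tree and tally every parameter array.
enumerate_params <- function(m) {
  own <- sum(vapply(m$p, length, numeric(1)))
  own + sum(vapply(m$children, enumerate_params, numeric(1)))
}

test_that("residual block: shortcut identity, shape contract, parameter count", {
  set.seed(1)
  # conv-path weights zero, matching channels, nonnegative input -> identity
  m <- nn_residual_block(4, 4, norm = FALSE)
  p <- mod_params(m)
  mod_set_params(m, lapply(p, function(w) { w[] <- 0; w }))
  x <- array(abs(rnorm(5 * 5 * 4)), c(5, 5, 4))
  expect_equal(spineseg:::mod_forward(m, x), x)

  # shape contract with projection shortcut
  m2 <- nn_residual_block(8, 16)
  y <- spineseg:::mod_forward(m2, array(rnorm(32 * 32 * 8), c(32, 32, 8)))
  expect_identical(dim(y), c(32L, 32L, 16L))

  # closed-form count: two 3x3 C->C convs with biases, identity shortcut
  for (C in c(3, 8)) {
    mc <- nn_residual_block(C, C, norm = FALSE)
    expect_equal(count_parameters(mc), 2 * (9 * C^2 + C))
    expect_equal(count_parameters(mc), enumerate_params(mc))
  }
  # frozen modules drop out of the count
  m3 <- nn_residual_block(4, 4)
  n_all <- count_parameters(m3)
  m3$children$unit1$frozen <- TRUE
  expect_lt(count_parameters(m3), n_all)
})

test_that("attention gate: annihilation, logistic midpoint, bounded output", {
  set.seed(2)
  m <- nn_attention_gate(3, 5)
  skip <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  gate <- array(rnorm(6 * 6 * 5), c(6, 6, 5))

  # v == 0 -> output all zeros
  p <- mod_params(m)
  p_zero_v <- p
  p_zero_v[["proj_v.w"]][] <- 0
  p_zero_v[["proj_v.b"]][] <- 0
  mod_set_params(m, p_zero_v)
  y <- spineseg:::mod_forward(m, list(skip = skip, gate = gate))
  expect_equal(max(abs(y)), 0)

  # e == 0 everywhere (zero projections) -> output = 0.5 * v
  p_zero_qk <- p
  for (nm in c("proj_q.w", "proj_q.b", "proj_k.w", "proj_k.b")) {
    p_zero_qk[[nm]][] <- 0
  }
  mod_set_params(m, p_zero_qk)
  y2 <- spineseg:::mod_forward(m, list(skip = skip, gate = gate))
  v <- spineseg:::mod_forward(m$children$proj_v, skip)
  expect_equal(y2, 0.5 * v, tolerance = 1e-12)

  # attention weights strictly inside (0, 1); |output| <= |v| element-wise
  mod_set_params(m, p)
  y3 <- spineseg:::mod_forward(m, list(skip = skip, gate = gate))
  alpha <- m$cache$alpha
  expect_true(all(alpha > 0 & alpha < 1))
  v3 <- spineseg:::mod_forward(m$children$proj_v, skip)
  expect_true(all(abs(y3) <= abs(v3) + 1e-12))
  expect_identical(dim(y3)[1:2], dim(skip)[1:2])

  # gate at half resolution is resampled internally
  gate_half <- array(rnorm(3 * 3 * 5), c(3, 3, 5))
  y4 <- spineseg:::mod_forward(m, list(skip = skip, gate = gate_half))
  expect_identical(dim(y4)[1:2], dim(skip)[1:2])
  expect_module_gradients_attention(m, skip, gate)
})

test_that("aspp: shape contract, concatenation arithmetic, receptive field", {
  set.seed(3)
  m <- nn_aspp(4, rates = c(1, 2, 4), out_channels = 6, branch_width = 3)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  y <- spineseg:::mod_forward(m, x)
  expect_identical(dim(y), c(16L, 16L, 6L))
  # pre-projection channels = (|rates| + 1) * branch_width
  expect_equal(m$children$proj$children$conv$cin, (3 + 1) * 3)
  expect_error(nn_aspp(4, rates = numeric(0)), "non-empty")

  # receptive field of a rate-3 3x3 dilated convolution is 7: probe with an
  # impulse through the raw convolution primitive
  imp <- array(0, c(15, 15, 1)); imp[8, 8, 1] <- 1
  w <- matrix(1, 9, 1)
  resp <- spineseg:::cpp_conv2d_fwd(imp, w, 0, 3, 3, 1, 3)
  on <- which(resp[, , 1] != 0, arr.ind = TRUE)
  expect_equal(diff(range(on[, 1])) + 1, 7)
  expect_equal(diff(range(on[, 2])) + 1, 7)

  # single-rate aspp still preserves extents
  m1 <- nn_aspp(2, rates = 1, out_channels = 2)
  expect_identical(dim(spineseg:::mod_forward(m1, array(rnorm(8 * 8 * 2),
                                                        c(8, 8, 2)))),
                   c(8L, 8L, 2L))
})

test_that("chaspp: shape, composed receptive field 11, denser sampling than one kernel", {
  set.seed(4)
  m <- nn_chaspp(3, root_rate = 2, branch_rates = c(1, 2, 3),
                 out_channels = 5, width = 3)
  x <- array(rnorm(18 * 18 * 3), c(18, 18, 3))
  expect_identical(dim(spineseg:::mod_forward(m, x)), c(18L, 18L, 5L))
  expect_error(nn_chaspp(3, root_rate = 0), "positive")

  # root rate 2 (RF 5) composed with branch rate 3 (RF 7): RF 5 + 7 - 1 = 11,
  # and the composed operator touches more than the 9 taps of a single 3x3
  imp <- array(0, c(25, 25, 1)); imp[13, 13, 1] <- 1
  ones <- matrix(1, 9, 1)
  root <- spineseg:::cpp_conv2d_fwd(imp, ones, 0, 3, 3, 1, 2)
  comp <- spineseg:::cpp_conv2d_fwd(root, ones, 0, 3, 3, 1, 3)
  on <- which(comp[, , 1] != 0, arr.ind = TRUE)
  expect_equal(diff(range(on[, 1])) + 1, 11)
  expect_equal(diff(range(on[, 2])) + 1, 11)
  expect_gt(nrow(on), 9)
})

test_that("inverted residual: standard-table row shape, expansion width, counts", {
  set.seed(5)
  # table row: 112^2 x 16 input, t=6 c=24 n=2 a=2 -> 56^2 x 24
  m <- nn_inverted_residual(16, list(t = 6, c = 24, n = 2, a = 2))
  x <- array(rnorm(112 * 112 * 16, sd = 0.1), c(112, 112, 16))
  y <- spineseg:::mod_forward(m, x)
  expect_identical(dim(y), c(56L, 56L, 24L))

  # expansion width 16 * 6 = 96 hidden channels
  expect_equal(m$children$rep1$children$expand$children$conv$cout, 96)

  # depthwise 3x3 over 8 channels with bias contributes 9*8 + 8 = 80
  dw <- spineseg:::layer_dwconv2d(8, k = 3)
  expect_equal(count_parameters(dw), 80)
  # a single 3x3 convolution 1 -> 8 with bias is 9*1*8 + 8 = 80
  expect_equal(count_parameters(spineseg:::layer_conv2d(1, 8, 3)), 80)

  # stride-1 matching-channel repeats carry the residual shortcut
  m2 <- nn_inverted_residual(6, list(t = 2, c = 6, n = 2, a = 1))
  expect_true(m2$children$rep1$shortcut)
  expect_true(m2$children$rep2$shortcut)
  m3 <- nn_inverted_residual(6, list(t = 2, c = 8, n = 2, a = 2))
  expect_false(m3$children$rep1$shortcut)  # stride 2, channel change
  expect_true(m3$children$rep2$shortcut)   # second repeat: stride 1, 8 -> 8
})

test_that("blocks preserve spatial extents except strided bottlenecks", {
  set.seed(6)
  x <- array(rnorm(12 * 10 * 4), c(12, 10, 4))
  for (m in list(nn_residual_block(4, 7), nn_aspp(4, c(1, 2), 5),
                 nn_chaspp(4, 2, c(1, 2, 3), 5),
                 nn_inverted_residual(4, list(t = 2, c = 6, n = 1, a = 1)))) {
    expect_identical(dim(spineseg:::mod_forward(m, x))[1:2], c(12L, 10L))
  }
  ms <- nn_inverted_residual(4, list(t = 2, c = 6, n = 1, a = 2))
  expect_identical(dim(spineseg:::mod_forward(ms, x))[1:2], c(6L, 5L))
})

test_that("composite blocks pass finite-difference gradient checks", {
  set.seed(7)
  expect_module_gradients(nn_residual_block(2, 4), c(6, 6, 2))
  expect_module_gradients(nn_aspp(2, c(1, 2), 3, branch_width = 2), c(8, 8, 2))
  expect_module_gradients(nn_chaspp(2, 2, c(1, 2, 3), 3, width = 2), c(9, 9, 2))
  expect_module_gradients(nn_inverted_residual(3, list(t = 2, c = 3, n = 2,
                                                       a = 2)), c(8, 8, 3))
})
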