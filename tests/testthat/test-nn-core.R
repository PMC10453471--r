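# The backward passes are all hand-derived; these finite-difference checks
# are the ground truth for the whole training machinery.

test_that("primitive layers pass finite-difference gradient checks", {
  set.seed(1)
  expect_module_gradients(spineseg:::layer_conv2d(2, 3, k = 3), c(6, 5, 2))
  expect_module_gradients(spineseg:::layer_conv2d(2, 3, k = 3, dilation = 2),
                          c(7, 7, 2))
  expect_module_gradients(spineseg:::layer_conv2d(2, 4, k = 3, stride = 2),
                          c(8, 6, 2))
  expect_module_gradients(spineseg:::layer_conv2d(3, 2, k = 1), c(5, 5, 3))
  expect_module_gradients(spineseg:::layer_dwconv2d(3, k = 3, stride = 2),
                          c(6, 8, 3))
  expect_module_gradients(spineseg:::layer_conv3d(2, 3), c(4, 5, 3, 2))
  expect_module_gradients(spineseg:::layer_conv3d(2, 3, k = 1), c(4, 4, 3, 2))
  expect_module_gradients(spineseg:::layer_norm_ch(3), c(5, 4, 3))
  expect_module_gradients(spineseg:::layer_maxpool2(), c(6, 4, 2))
  expect_module_gradients(spineseg:::layer_upsample2(), c(3, 4, 2))
  expect_module_gradients(spineseg:::layer_resize3d(c(5, 6, 4)), c(3, 4, 2, 2))
})

test_that("compiled 2D convolution matches a naive R oracle", {
  set.seed(2)
  x <- array(rnorm(9 * 8 * 2), c(9, 8, 2))
  w <- array(rnorm(3 * 3 * 2 * 4, sd = 0.3), c(3, 3, 2, 4))
  b <- rnorm(4)
  y <- spineseg:::cpp_conv2d_fwd(x, matrix(w, 18, 4), b, 3, 3, 1, 1)
  oracle <- array(0, c(9, 8, 4))
  for (co in 1:4) for (ho in 1:9) for (wo in 1:8) {
    acc <- b[co]
    for (ci in 1:2) for (ki in 1:3) for (kj in 1:3) {
      hi <- ho + ki - 2; wi <- wo + kj - 2
      if (hi >= 1 && hi <= 9 && wi >= 1 && wi <= 8) {
        acc <- acc + x[hi, wi, ci] * w[ki, kj, ci, co]
      }
    }
    oracle[ho, wo, co] <- acc
  }
  expect_equal(y, oracle, tolerance = 1e-12)
})

test_that("strided convolutions halve spatial extents with ceiling semantics", {
  x <- array(rnorm(10 * 7 * 2), c(10, 7, 2))
  m <- spineseg:::layer_conv2d(2, 3, k = 3, stride = 2)
  expect_identical(dim(spineseg:::mod_forward(m, x))[1:2], c(5L, 4L))
})

test_that("softmax normalises channels and the loss gradient is exact", {
  set.seed(3)
  logits <- array(rnorm(5 * 4 * 3, sd = 3), c(5, 4, 3))
  p <- spineseg:::softmax_channels(logits)
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-12)

  truth <- array(sample(0:2, 20, TRUE), c(5, 4))
  for (cw in list(NULL, "balanced")) {
    lg <- spineseg:::seg_loss_grad(logits, truth, class_weights = cw)
    ng <- numeric_gradient(function(v) {
      spineseg:::seg_loss_grad(array(v, dim(logits)), truth,
                               class_weights = cw)$loss
    }, as.numeric(logits), eps = 1e-6)
    expect_lt(max(abs(ng - as.numeric(lg$grad))), 1e-6)
  }
})

test_that("segmentation loss is zero at one-hot truth and ln 2 under uniform 2-class", {
  truth <- array(sample(0:1, 16, TRUE), c(4, 4))
  onehot <- spineseg:::one_hot(truth, 2)
  perfect <- pmin(pmax(onehot, 1e-9), 1 - 1e-9)
  expect_lt(segmentation_loss(perfect, truth), 1e-6)

  uniform <- array(0.5, c(4, 4, 2))
  l <- segmentation_loss(uniform, truth, weights = c(0, 1))
  expect_equal(as.numeric(l), log(2), tolerance = 1e-12)
  expect_gte(segmentation_loss(uniform, truth), 0)
  expect_error(segmentation_loss(uniform, array(0L, c(3, 3))), "misaligned")
})

test_that("loss decreases monotonically when overfitting one fixed sample", {
  set.seed(4)
  m <- spineseg:::seq_module(list(
    spineseg:::conv_norm_act(1, 6),
    spineseg:::layer_conv2d(6, 2, 1)
  ))
  x <- array(rnorm(12 * 12), c(12, 12, 1))
  y <- matrix(0L, 12, 12); y[4:9, 4:9] <- 1L
  opt <- spineseg:::make_adam(m, lr = 5e-3)
  losses <- numeric(50)
  for (s in 1:50) {
    spineseg:::mod_zero_grads(m)
    lo <- spineseg:::mod_forward(m, x, train = TRUE)
    lg <- spineseg:::seg_loss_grad(lo, y)
    spineseg:::mod_backward(m, lg$grad)
    spineseg:::adam_step(opt)
    losses[s] <- lg$loss
  }
  # smoothed trajectory decreases monotonically and ends below the start
  expect_lt(losses[50], losses[1])
  smoothed <- stats::filter(losses, rep(1 / 5, 5), sides = 1)
  expect_true(all(diff(smoothed[5:50]) < 0))
})

test_that("parameter snapshots round-trip through set/get", {
  set.seed(5)
  m <- nn_residual_block(2, 4)
  p0 <- mod_params(m)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  y0 <- spineseg:::mod_forward(m, x)
  p_perturbed <- lapply(p0, function(w) w + 0.1)
  mod_set_params(m, p_perturbed)
  expect_false(isTRUE(all.equal(spineseg:::mod_forward(m, x), y0)))
  mod_set_params(m, p0)
  expect_equal(spineseg:::mod_forward(m, x), y0)
})
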