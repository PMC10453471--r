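tiny_recog_config <- function(out_classes = 4, dropout = 0) {
  recog_model_config(
    stem_width = 4,
    bottlenecks = list(list(t = 1, c = 4, n = 1, a = 1),
                       list(t = 2, c = 6, n = 1, a = 2),
                       list(t = 2, c = 8, n = 1, a = 2)),
    fused_channels = 8, decoder_widths = c(8, 6, 4),
    dropout = dropout, out_classes = out_classes)
}

test_that("encode_view maps volumes to the 1/8 fusion grid in every plane", {
  set.seed(1)
  m <- build_recog_model(tiny_recog_config())
  x <- array(rnorm(16 * 24 * 24 * 2, sd = 0.1), c(16, 24, 24, 2))
  fa <- encode_view(m, x, "axial")
  fs <- encode_view(m, x, "sagittal")
  fc <- encode_view(m, x, "coronal")
  expect_identical(dim(fa), c(2L, 3L, 3L, 8L))
  expect_identical(dim(fs), dim(fa))
  expect_identical(dim(fc), dim(fa))
  expect_error(encode_view(m, array(0, c(15, 24, 24, 2)), "axial"),
               "divisible")
})

test_that("slicing is symmetric: permuting axes and the view argument commutes", {
  set.seed(2)
  m <- build_recog_model(tiny_recog_config())
  # give the coronal encoder the axial encoder's weights, then feed it the
  # permuted volume whose coronal slices are the original axial slices
  p <- mod_params(m)
  p_ax <- p[startsWith(names(p), "enc_axial.")]
  names(p_ax) <- sub("^enc_axial\\.", "enc_coronal.", names(p_ax))
  mod_set_params(m, p_ax)
  x <- array(rnorm(16 * 16 * 16 * 2, sd = 0.1), c(16, 16, 16, 2))
  f_ax <- encode_view(m, x, "axial")
  xp <- aperm(x, c(2, 1, 3, 4))
  f_cor <- encode_view(m, xp, "coronal")
  expect_equal(f_cor, aperm(f_ax, c(2, 1, 3, 4)), tolerance = 1e-10)
})

test_that("fuse_views concatenates in fixed order with block structure", {
  set.seed(3)
  fa <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  fs <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  fc <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  fu <- fuse_views(fa, fs, fc)
  expect_identical(dim(fu), c(2L, 3L, 3L, 12L))
  expect_identical(fu[, , , 1:4], fa)
  expect_identical(fu[, , , 5:8], fs)
  expect_identical(fu[, , , 9:12], fc)
  # zeroing one view zeroes exactly its block
  fu0 <- fuse_views(fa * 0, fs, fc)
  expect_true(all(fu0[, , , 1:4] == 0))
  expect_identical(fu0[, , , 5:12], fu[, , , 5:12])
  expect_error(fuse_views(fa, fs, array(0, c(2, 3, 3, 5))), "differ")
})

test_that("the three view encoders share no parameters", {
  set.seed(4)
  m <- build_recog_model(tiny_recog_config())
  n_ax <- count_parameters(m$children$enc_axial)
  n_sag <- count_parameters(m$children$enc_sagittal)
  n_cor <- count_parameters(m$children$enc_coronal)
  expect_equal(n_ax, n_sag)
  # weight identifiers are disjoint and counts sum
  nm <- names(mod_params(m))
  expect_equal(sum(startsWith(nm, "enc_axial.")) +
                 sum(startsWith(nm, "enc_sagittal.")) +
                 sum(startsWith(nm, "enc_coronal.")) > 0, TRUE)
  expect_equal(count_parameters(m),
               sum(vapply(mod_params(m), length, numeric(1))))
  # perturbing one encoder leaves the others' outputs unchanged
  x <- array(rnorm(16 * 16 * 16 * 2, sd = 0.1), c(16, 16, 16, 2))
  f_sag_before <- encode_view(m, x, "sagittal")
  p <- mod_params(m)
  p_ax <- p[startsWith(names(p), "enc_axial.")]
  mod_set_params(m, lapply(p_ax, function(w) w + 0.3))
  expect_identical(encode_view(m, x, "sagittal"), f_sag_before)
  expect_equal(n_ax + n_sag + n_cor +
                 count_parameters(m) - n_ax - n_sag - n_cor,
               count_parameters(m))
})

test_that("recognize returns aligned, masked, in-range labels with unit probabilities", {
  set.seed(5)
  ph <- generate_phantom(tiny_phantom_spec())
  pp <- preprocess_pipeline(ph$volume, ph$labels,
                            preprocess_config(target_inplane = c(24, 24),
                                              target_depth = 16,
                                              mode = "unit_range"))
  mask <- new_labelmap(array(as.integer(pp$labels$data > 0),
                             dim(pp$labels$data)),
                       pp$labels$spacing, pp$labels$affine)
  m <- build_recog_model(tiny_recog_config(out_classes = 4))
  out <- recognize(m, pp$volume, mask)
  expect_identical(dim(out$data), dim(pp$volume$data))
  expect_true(all(out$data %in% 0:3))
  expect_true(all(out$data[mask$data == 0] == 0))

  logits <- spineseg:::mod_forward(m, spineseg:::recog_input(pp$volume, mask),
                                   train = FALSE)
  p <- spineseg:::softmax_channels(logits)
  expect_lt(max(abs(apply(p, c(1, 2, 3), sum) - 1)), 1e-5)
  expect_error(recognize(m, pp$volume,
                         new_labelmap(array(0L, c(8, 8, 8)))),
               "misaligned")
})

test_that("the full recognition model backpropagates correctly", {
  set.seed(6)
  cfg <- recog_model_config(
    stem_width = 3,
    bottlenecks = list(list(t = 1, c = 3, n = 1, a = 1),
                       list(t = 2, c = 4, n = 1, a = 2),
                       list(t = 2, c = 4, n = 1, a = 2)),
    fused_channels = 4, decoder_widths = c(4, 4, 3),
    dropout = 0, out_classes = 3)
  m <- build_recog_model(cfg)
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  spineseg:::mod_zero_grads(m)
  y <- spineseg:::mod_forward(m, x, train = TRUE)
  dy <- array(rnorm(length(y), sd = 0.1), dim(y))
  y <- spineseg:::mod_forward(m, x, train = TRUE)
  dx <- spineseg:::mod_backward(m, dy)
  f0 <- sum(y * dy)
  idx <- sample(length(x), 6)
  for (i in idx) {
    xp <- x
    xp[i] <- xp[i] + 1e-5
    yp <- spineseg:::mod_forward(m, xp, train = TRUE)
    expect_equal((sum(yp * dy) - f0) / 1e-5, dx[i], tolerance = 1e-3)
  }
})
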