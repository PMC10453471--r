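test_that("clamping enforces the Hounsfield window and is identity inside it", {
  v <- new_volume(array(c(1200, -1500, 400, 0, 800, -1000, 250, 799),
                        c(2, 2, 2)))
  cl <- clamp_hu(v, -1000, 800)
  expect_equal(cl$data[1, 1, 1], 800)    # above the window clips down
  expect_equal(cl$data[2, 1, 1], -1000)  # below the window clips up
  expect_equal(cl$data[1, 2, 1], 400)    # inside the window unchanged
  expect_true(all(cl$data >= -1000 & cl$data <= 800))
  expect_error(clamp_hu(v, 800, -1000), "lo")
})

test_that("smoothing with sigma 0 is the identity and constants are fixed points", {
  set.seed(1)
  v <- new_volume(array(rnorm(6 * 7 * 8), c(6, 7, 8)), spacing = c(1, 2, 1.5))
  expect_identical(smooth_volume(v, 0)$data, v$data)
  const <- new_volume(array(5, c(6, 6, 6)))
  expect_equal(smooth_volume(const, 2)$data, const$data, tolerance = 1e-12)
  expect_error(smooth_volume(v, -1), "nonnegative")
})

test_that("smoothing matches a direct discrete-convolution oracle", {
  set.seed(2)
  v <- new_volume(array(rnorm(9 * 8 * 7), c(9, 8, 7)), spacing = c(2, 1, 1))
  sm <- smooth_volume(v, 1.5)
  # oracle: brute-force separable convolution with boundary-renormalised
  # Gaussian taps, one axis at a time
  oracle_1d <- function(x, sigma_vox) {
    n <- length(x)
    r <- max(1L, ceiling(3 * sigma_vox))
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- exp(-0.5 * ((j - i) / sigma_vox)^2)
      out[i] <- sum(w * x[j]) / sum(w)
    }
    out
  }
  x <- v$data
  for (a in 1:3) {
    sv <- 1.5 / v$spacing[a]
    x <- apply(x, setdiff(1:3, a), oracle_1d, sigma_vox = sv)
    x <- aperm(x, order(c(a, setdiff(1:3, a))))
  }
  expect_equal(sm$data, x, tolerance = 1e-10)
  # mean of an interior-supported blob is conserved to < 1%
  blob <- array(0, c(20, 20, 20))
  blob[8:13, 8:13, 8:13] <- 100
  vb <- new_volume(blob)
  expect_lt(abs(mean(smooth_volume(vb, 1)$data) - mean(blob)) / mean(blob),
            0.01)
})

test_that("the four normalization modes produce their documented ranges", {
  set.seed(3)
  raw <- array(runif(4 * 5 * 6, -1000, 800), c(4, 5, 6))
  v <- new_volume(raw)
  expect_identical(normalize_volume(v, "clamped_hu")$data, raw)

  zm <- normalize_volume(v, "zero_mean")$data
  expect_lt(abs(mean(zm)), 1e-6)
  expect_lt(abs(stats::sd(as.numeric(zm)) - 1), 1e-6)

  ur <- normalize_volume(v, "unit_range")$data
  expect_true(all(ur >= 0 & ur <= 1))
  sr <- normalize_volume(v, "symmetric_range")$data
  expect_true(all(sr >= -1 & sr <= 1))

  # worked endpoint and midpoint values of the affine maps
  pts <- new_volume(array(c(-1000, 800, -100, 0, 0, 0, 0, 0), c(2, 2, 2)))
  urp <- normalize_volume(pts, "unit_range")$data
  expect_equal(urp[1, 1, 1], 0)
  expect_equal(urp[2, 1, 1], 1)
  expect_equal(urp[1, 2, 1], 0.5)     # (-100 + 1000) / 1800
  srp <- normalize_volume(pts, "symmetric_range")$data
  expect_equal(srp[1, 2, 1], 0)       # 2 * 0.5 - 1

  # degenerate-variance rule
  const <- new_volume(array(300, c(3, 3, 3)))
  expect_identical(normalize_volume(const, "zero_mean")$data,
                   array(0, c(3, 3, 3)))
})

test_that("normalization is monotone in every mode", {
  set.seed(4)
  raw <- array(runif(1000, -1000, 800), c(10, 10, 10))
  v <- new_volume(raw)
  ord <- order(raw)
  for (mode in spineseg:::NORMALIZATION_MODES) {
    out <- normalize_volume(v, mode)$data
    expect_false(is.unsorted(out[ord]))
  }
})

test_that("resizing hits the working grid, preserves extent, labels never grow", {
  set.seed(5)
  ph <- generate_phantom(tiny_phantom_spec())
  cfg <- preprocess_config(target_inplane = c(24, 24), target_depth = "keep")
  rv <- resize_to_grid(ph$volume, cfg)
  expect_identical(dim(rv$data), c(32L, 24L, 24L))
  # physical extent preserved: spacing doubles where extents halve
  expect_equal(rv$spacing, c(2, 4, 4))
  rl <- resize_to_grid(ph$labels, cfg)
  expect_true(all(rl$data %in% ph$labels$data))
  expect_true(all(rl$data == round(rl$data)))
  # identity resize returns the object unchanged
  same <- resize_to_grid(ph$volume,
                         preprocess_config(target_inplane = c(48, 48)))
  expect_identical(same$data, ph$volume$data)
  expect_error(resize_to_grid(ph$volume,
                              preprocess_config(target_inplane = c(0, 24))),
               "positive")
})

test_that("the full pipeline composes, keeps labels aligned, identity when trivial", {
  set.seed(6)
  ph <- generate_phantom(tiny_phantom_spec())
  cfg <- preprocess_config(target_inplane = c(32, 32), target_depth = 16,
                           mode = "unit_range", smooth_sigma = 0.75)
  pp <- preprocess_pipeline(ph$volume, ph$labels, cfg)
  expect_identical(dim(pp$volume$data), c(16L, 32L, 32L))
  expect_identical(dim(pp$volume$data), dim(pp$labels$data))
  expect_true(all(pp$volume$data >= 0 & pp$volume$data <= 1))
  expect_true(all(pp$labels$data %in% ph$labels$data))

  # all-identity settings: in-range data returned unchanged
  vin <- new_volume(array(runif(16 * 16 * 16, -500, 500), c(16, 16, 16)),
                    spacing = c(1, 1, 1),
                    affine = spineseg:::phantom_affine(c(1, 1, 1)))
  idcfg <- preprocess_config(smooth_sigma = 0,
                             target_inplane = c(16, 16),
                             target_depth = "keep", mode = "clamped_hu")
  out <- preprocess_pipeline(vin, NULL, idcfg)
  expect_identical(out$volume$data, vin$data)
})

test_that("noise-free phantoms keep bone at exactly the bone intensity through clamping", {
  set.seed(7)
  ph <- generate_phantom(tiny_phantom_spec(noise_sd = 0))
  cfg <- preprocess_config(smooth_sigma = 0,
                           target_inplane = c(48, 48), mode = "clamped_hu")
  pp <- preprocess_pipeline(ph$volume, ph$labels, cfg)
  expect_identical(unique(as.numeric(pp$volume$data[pp$labels$data > 0])),
                   700)
})
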