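test_that("splitting is a deterministic, exhaustive, disjoint partition", {
  items <- as.list(letters[1:10])
  sp <- split_dataset(items, 0.8, seed = 4)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(unlist(c(sp$train, sp$test)), letters[1:10])
  sp2 <- split_dataset(items, 0.8, seed = 4)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(items, 0.8, seed = 5)))
  expect_error(split_dataset(list(1), 0.8, 1), "two")
  # both sides always non-empty
  sp3 <- split_dataset(as.list(1:2), 0.9, 1)
  expect_length(sp3$train, 1)
  expect_length(sp3$test, 1)
})

make_slice_set <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(phantom_spec(grid = c(16, 24, 24),
                                        spacing = c(2, 2, 2),
                                        n_vertebrae = 2,
                                        body_radius_mm = c(6, 8),
                                        curvature_amp_mm = 2,
                                        seed = 1000 + i))
    mid <- round(dim(ph$volume$data)[3] / 2)
    x <- spineseg:::get_slice(ph$volume$data, 3, mid) / 800
    dim(x) <- c(dim(x), 1)
    list(x = x,
         y = matrix(as.integer(spineseg:::get_slice(ph$labels$data, 3,
                                                    mid) > 0),
                    nrow = dim(x)[1]))
  })
}

test_that("training logs one history row per epoch and improves the fit", {
  samples <- make_slice_set(6)
  set.seed(2)
  m <- build_seg_model(seg_model_config(base_width = 4, depth = 2,
                                        dropout = 0))
  fit <- train(m, samples[1:4], samples[5:6],
               train_config(epochs = 4, lr = 3e-3, batch_size = 2, seed = 9))
  expect_equal(nrow(fit$history), 4)
  expect_identical(fit$history$epoch, 1:4)
  expect_lt(fit$history$train_loss[4], fit$history$train_loss[1])
  expect_equal(fit$best, max(fit$history$val_dice))
  expect_error(train(m, list(), samples[5:6], train_config(epochs = 1)),
               "non-empty")
})

test_that("training is bit-reproducible under a fixed seed", {
  samples <- make_slice_set(5, seed = 3)
  run_once <- function() {
    set.seed(7)
    m <- build_seg_model(seg_model_config(base_width = 4, depth = 2))
    fit <- train(m, samples[1:4], samples[5],
                 train_config(epochs = 2, lr = 1e-3, batch_size = 2,
                              augment = augmentation_spec(), seed = 7))
    list(h = fit$history, p = mod_params(m))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$h, b$h)
  expect_identical(a$p, b$p)
})

test_that("evaluation of the truth against itself scores 100 everywhere", {
  samples <- make_slice_set(3, seed = 4)
  # an oracle "model": a module that returns logits reproducing the truth
  oracle <- spineseg:::new_module(
    "oracle",
    fwd = function(m, x, train) {
      y <- m$truth_lookup[[digest_key(x)]]
      spineseg:::one_hot(y, 2) * 10
    },
    bwd = function(m, dy) dy
  )
  digest_key <- function(x) as.character(round(sum(x) * 1e6))
  oracle$truth_lookup <- setNames(
    lapply(samples, `[[`, "y"),
    vapply(samples, function(s) digest_key(s$x), character(1))
  )
  res <- evaluate(oracle, samples, task = "seg")
  expect_true(all(res$per_sample$dsc_pct == 100))
  expect_equal(unname(res$aggregate["dsc_pct"]), 100)
  # aggregate equals the mean of per-sample macro rows; one macro row per
  # sample plus the per-class rows
  macro_rows <- res$per_sample[res$per_sample$class == "macro", ]
  expect_equal(nrow(macro_rows), length(samples))
  expect_equal(unname(res$aggregate["iou_pct"]), mean(macro_rows$iou_pct))
})

test_that("evaluation writes CSV and JSON reports", {
  samples <- make_slice_set(2, seed = 5)
  set.seed(6)
  m <- build_seg_model(seg_model_config(base_width = 4, depth = 2))
  csvf <- withr::local_tempfile(fileext = ".csv")
  jsonf <- withr::local_tempfile(fileext = ".json")
  res <- evaluate(m, samples, task = "seg", csv_path = csvf,
                  json_path = jsonf)
  expect_true(file.exists(csvf))
  tab <- utils::read.csv(csvf)
  expect_identical(sort(unique(tab$scan_id)),
                   sort(unique(res$per_sample$scan_id)))
  js <- jsonlite::read_json(jsonf)
  expect_equal(js$dsc_pct, unname(res$aggregate["dsc_pct"]), tolerance = 1e-9)
})

test_that("stage-2 samples carry the cascade mask into validation scoring", {
  set.seed(8)
  ph <- generate_phantom(tiny_phantom_spec())
  pp <- preprocess_pipeline(ph$volume, ph$labels,
                            preprocess_config(target_inplane = c(24, 24),
                                              target_depth = 16,
                                              mode = "unit_range"))
  mask <- new_labelmap(array(as.integer(pp$labels$data > 0),
                             dim(pp$labels$data)),
                       pp$labels$spacing, pp$labels$affine)
  s <- spineseg:::prepare_recog_sample(pp$volume, mask, pp$labels)
  expect_identical(dim(s$x), c(16L, 24L, 24L, 2L))
  expect_identical(s$mask, array(as.integer(mask$data), dim(mask$data)))
  m <- build_recog_model(recog_model_config(
    stem_width = 4,
    bottlenecks = list(list(t = 1, c = 4, n = 1, a = 1),
                       list(t = 2, c = 6, n = 1, a = 2),
                       list(t = 2, c = 8, n = 1, a = 2)),
    fused_channels = 8, decoder_widths = c(8, 6, 4), out_classes = 4))
  pred <- spineseg:::predict_sample(m, s)
  expect_true(all(pred[s$mask == 0] == 0))
})
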