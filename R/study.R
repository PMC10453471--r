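# The scaled-down phantom study: the package's self-contained end-to-end
# exercise of the two-stage pipeline on synthetic spine phantoms.
#
# Study conditions: 25 phantoms on the default 64 x 96 x 96 grid (2 mm
# voxels, 6 vertebrae, 25 HU noise), deterministically seeded; an 80/20
# volume-level split (20 train / 5 test). Stage 1 trains a reduced
# segmentation network (base width 8, depth 2) on sagittal slices at the
# native working grid with on-the-fly augmentation; stage 2 trains a reduced
# recognition network on a 32^3 working grid with ground-truth spine masks
# as the second input channel and inverse-frequency class weighting. Test
# metrics are computed on each stage's working grid: stage 1 as binary
# volume Dice, stage 2 through the honest cascade (stage-1 predicted masks,
# resampled to the recognition grid, gate the recognition output).
#
# Reduced-study training uses a 3e-3 initial learning rate: the compressed
# schedule (~10 epochs on small networks) needs a larger step than the
# reference 1e-3 default, which is tuned for 150-epoch full-scale runs.

#' Reduced stage-1 configuration used by the phantom study
#' @return A [seg_model_config()].
#' @export
study_seg_config <- function() {
  seg_model_config(base_width = 8, depth = 2, dropout = 0.3)
}

#' Reduced stage-2 configuration used by the phantom study
#' @param out_classes Output classes (default 7: background + 6 vertebrae).
#' @return A [recog_model_config()].
#' @export
study_recog_config <- function(out_classes = 7) {
  recog_model_config(
    stem_width = 6,
    bottlenecks = list(list(t = 1, c = 6, n = 1, a = 1),
                       list(t = 3, c = 10, n = 1, a = 2),
                       list(t = 3, c = 14, n = 1, a = 2)),
    fused_channels = 12, decoder_widths = c(16, 12, 10),
    dropout = 0.3, out_classes = out_classes)
}

#' Run the scaled-down two-stage phantom study
#'
#' Generates the phantom cohort, trains both stages and evaluates them on
#' the held-out phantoms. Fully deterministic given `seed` (single-threaded
#' execution): repeating a run reproduces the metric tables exactly.
#'
#' @param seed Master integer seed for phantom generation, splitting,
#'   initialisation, augmentation and training order.
#' @param n_phantoms Cohort size (default 25, split 80/20).
#' @param seg_epochs,recog_epochs Training epochs per stage (defaults 8
#'   and 8).
#' @param slices_per_volume Cap on stage-1 training slices per volume
#'   (default 10, drawn evenly from all spine-bearing slices plus half as
#'   many background slices).
#' @param phantom Base [phantom_spec()] describing the cohort (default:
#'   package defaults, 64 x 96 x 96 at 2 mm with 6 vertebrae).
#' @param recog_grid Stage-2 working grid (default `c(32, 32, 32)`).
#' @param lr Initial learning rate for both stages (default 3e-3, see the
#'   methods vignette).
#' @param verbose Print progress lines.
#' @return A list with `seg_metrics` (per-test-volume binary tibble),
#'   `recog_metrics` (per-test-volume cascade tibble), `summary` (named
#'   numeric: mean test percentages and parameter counts of the reference
#'   configurations), plus both training histories.
#' @export
run_phantom_study <- function(seed = 1, n_phantoms = 25, seg_epochs = 8,
                              recog_epochs = 8, slices_per_volume = 10,
                              phantom = phantom_spec(),
                              recog_grid = c(32, 32, 32), lr = 3e-3,
                              verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  say("generating ", n_phantoms, " phantoms")
  set.seed(seed)
  phs <- lapply(seq_len(n_phantoms), function(i) {
    sp <- phantom
    sp$seed <- derive_seed(seed, i)
    generate_phantom(sp)
  })
  sp <- split_dataset(seq_len(n_phantoms), 0.8, seed)

  # ---- stage 1: binary spine segmentation on sagittal slices ----
  g <- dim(phs[[1]]$volume$data)
  pcfg1 <- preprocess_config(target_inplane = g[2:3], mode = "unit_range")
  pp1 <- lapply(phs, function(p) {
    preprocess_pipeline(p$volume, p$labels, pcfg1)
  })
  mk_slices <- function(idx, cap) {
    unlist(lapply(idx, function(i) {
      s <- prepare_seg_samples(pp1[[i]]$volume, pp1[[i]]$labels, "sagittal",
                               bg_ratio = 0.5,
                               id = sprintf("phantom_%03d", i))
      if (length(s) > cap) {
        s <- s[unique(round(seq(1, length(s), length.out = cap)))]
      }
      s
    }), recursive = FALSE)
  }
  tr1 <- mk_slices(sp$train, slices_per_volume)
  va1 <- mk_slices(sp$test, max(2, slices_per_volume %/% 2))
  say("stage 1: training on ", length(tr1), " slices, ", seg_epochs,
      " epochs")
  set.seed(seed)
  seg_model <- build_seg_model(study_seg_config())
  fit1 <- train(seg_model, tr1, va1,
                train_config(epochs = seg_epochs, lr = lr, batch_size = 2,
                             augment = augmentation_spec(), seed = seed))
  seg_rows <- lapply(sp$test, function(i) {
    pred <- segment_volume(seg_model, pp1[[i]]$volume, "sagittal")
    cc <- confusion_counts(pred$data > 0, pp1[[i]]$labels$data > 0)
    tibble::tibble(sample_id = sprintf("phantom_%03d", i),
                   dsc_pct = 100 * dice(pred$data > 0,
                                        pp1[[i]]$labels$data > 0),
                   iou_pct = 100 * iou(cc),
                   precision_pct = 100 * precision(cc),
                   recall_pct = 100 * recall(cc))
  })
  seg_metrics <- do.call(rbind, seg_rows)
  say(sprintf("stage 1: mean test dice %.2f%%", mean(seg_metrics$dsc_pct)))

  # ---- stage 2: per-vertebra recognition on the recognition grid ----
  pcfg2 <- preprocess_config(target_inplane = recog_grid[2:3],
                             target_depth = recog_grid[1],
                             mode = "unit_range")
  pp2 <- lapply(phs, function(p) {
    preprocess_pipeline(p$volume, p$labels, pcfg2)
  })
  gt_mask <- function(lab) {
    new_labelmap(array(as.integer(lab$data > 0), dim(lab$data)),
                 lab$spacing, lab$affine)
  }
  tr2 <- lapply(sp$train, function(i) {
    prepare_recog_sample(pp2[[i]]$volume, gt_mask(pp2[[i]]$labels),
                         pp2[[i]]$labels, sprintf("phantom_%03d", i))
  })
  va2 <- lapply(sp$test, function(i) {
    prepare_recog_sample(pp2[[i]]$volume, gt_mask(pp2[[i]]$labels),
                         pp2[[i]]$labels, sprintf("phantom_%03d", i))
  })
  n_classes <- phantom$n_vertebrae + 1
  say("stage 2: training on ", length(tr2), " volumes, ", recog_epochs,
      " epochs")
  set.seed(seed)
  recog_model <- build_recog_model(study_recog_config(n_classes))
  fit2 <- train(recog_model, tr2, va2,
                train_config(epochs = recog_epochs, lr = lr, batch_size = 1,
                             class_weights = "balanced", seed = seed))

  # honest cascade on the test phantoms: stage-1 predicted masks gate the
  # recognition output
  recog_rows <- lapply(sp$test, function(i) {
    spine_pred <- segment_volume(seg_model, pp1[[i]]$volume, "sagittal")
    mask2 <- resize_to_grid(spine_pred, pcfg2)
    vert <- recognize(recog_model, pp2[[i]]$volume, mask2)
    rep_ <- macro_report(vert$data, pp2[[i]]$labels$data,
                         classes = seq_len(phantom$n_vertebrae))
    macro <- rep_[rep_$class == "macro", ]
    tibble::tibble(sample_id = sprintf("phantom_%03d", i),
                   dsc_pct = macro$dsc_pct, iou_pct = macro$iou_pct,
                   precision_pct = macro$precision_pct,
                   recall_pct = macro$recall_pct)
  })
  recog_metrics <- do.call(rbind, recog_rows)
  say(sprintf("stage 2: mean test macro dice %.2f%%",
              mean(recog_metrics$dsc_pct)))

  set.seed(seed)
  ref_seg <- count_parameters(build_seg_model(seg_model_config()))
  ref_recog <- count_parameters(build_recog_model(recog_model_config()))
  list(
    seg_metrics = seg_metrics,
    recog_metrics = recog_metrics,
    seg_history = fit1$history,
    recog_history = fit2$history,
    summary = c(
      seg_test_dice_pct = mean(seg_metrics$dsc_pct),
      seg_test_iou_pct = mean(seg_metrics$iou_pct),
      seg_test_precision_pct = mean(seg_metrics$precision_pct),
      seg_test_recall_pct = mean(seg_metrics$recall_pct),
      recog_test_macro_dice_pct = mean(recog_metrics$dsc_pct),
      recog_test_macro_iou_pct = mean(recog_metrics$iou_pct),
      recog_test_macro_precision_pct = mean(recog_metrics$precision_pct),
      recog_test_macro_recall_pct = mean(recog_metrics$recall_pct),
      reference_seg_parameters = ref_seg,
      reference_recog_parameters = ref_recog,
      reference_total_parameters = ref_seg + ref_recog
    )
  )
}
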