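# Training and evaluation: dataset splitting, the composite loss (defined in
# nn_core.R), an Adam training loop with reduce-on-plateau scheduling and
# best-checkpoint tracking, sample preparation from volumes, and metric
# reporting.

#' Training configuration
#'
#' @param epochs Training epochs (default 150).
#' @param lr Initial learning rate of the adaptive-moment optimizer
#'   (default 0.001); a reduce-on-plateau schedule (factor 0.5, patience 10
#'   epochs without validation improvement) decays it.
#' @param batch_size Samples per optimizer step (default 8 for 2D slices,
#'   set 2 for 3D volumes).
#' @param loss_weights Weights of the soft-Dice and cross-entropy loss terms
#'   (default `c(0.5, 0.5)`).
#' @param split_fraction Training fraction of the dataset split (default 0.8).
#' @param augment Optional [augmentation_spec()] applied on the fly to
#'   training samples (2D samples only), or `NULL`.
#' @param class_weights `NULL` (uniform) or `"balanced"`: inverse-frequency
#'   per-class weights in the cross-entropy term, countering the extreme
#'   background/vertebra voxel imbalance.
#' @param seed Integer seed for shuffling, initialisation consumers and
#'   augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 150, lr = 0.001, batch_size = 8,
                         loss_weights = c(0.5, 0.5), split_fraction = 0.8,
                         augment = NULL, class_weights = NULL, seed = 1) {
  if (epochs < 1) stop("epochs must be at least 1", call. = FALSE)
  if (lr <= 0) stop("lr must be positive", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be inside (0, 1)", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 loss_weights = loss_weights,
                 split_fraction = split_fraction, augment = augment,
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Deterministic shuffled train/test split
#'
#' Shuffles the items with the given seed and splits them into
#' `round(n * fraction)` training items and the remainder for testing;
#' the two parts are disjoint and jointly exhaust the input.
#'
#' @param items A list or vector of at least two samples.
#' @param fraction Training fraction (default 0.8, the standard 80/20 split).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
split_dataset <- function(items, fraction = 0.8, seed = 1) {
  n <- length(items)
  if (n < 2) stop("need at least two items to split", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- min(max(round(n * fraction), 1), n - 1)
  list(train = items[perm[seq_len(n_train)]],
       test = items[perm[(n_train + 1):n]])
}

# In-plane augmentation of one 2D sample (image (H,W,C), labels (H,W)).
augment_sample_2d <- function(x, y, spec) {
  angle <- if (runif(1) < spec$prob) {
    runif(1, spec$rotation_range_deg[1], spec$rotation_range_deg[2])
  } else 0
  factor <- if (runif(1) < spec$prob) {
    runif(1, spec$scale_range[1], spec$scale_range[2])
  } else 1
  do_flip <- spec$flip_lr && runif(1) < spec$prob
  if (angle != 0 || factor != 1) {
    for (ci in seq_len(dim(x)[3])) {
      x[, , ci] <- affine_resample_plane(x[, , ci], angle, factor,
                                         method = "linear",
                                         fill = min(x[, , ci]))
    }
    y <- round(affine_resample_plane(y, angle, factor,
                                     method = "nearest", fill = 0))
  }
  if (do_flip) {
    x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    y <- y[, rev(seq_len(ncol(y)))]
  }
  list(x = x, y = y)
}

# Macro Dice over classes present in the truth (fractions, not percent).
macro_dice <- function(pred, truth) {
  classes <- sort(setdiff(unique(as.integer(truth)), 0))
  if (length(classes) == 0) return(as.numeric(all(pred == 0)))
  mean(vapply(classes, function(k) dice(pred == k, truth == k), numeric(1)))
}

# Validation metric: Dice with per-class overlaps pooled across all samples
# before the ratio, then macro-averaged over classes present in the pooled
# truth. Pooling keeps the metric smooth when individual samples (e.g.
# background-only slices) carry a degenerate per-sample score.
pooled_macro_dice <- function(model, samples) {
  inter <- list(); psum <- list(); tsum <- list()
  for (s in samples) {
    pred <- predict_sample(model, s)
    for (k in sort(unique(c(as.integer(pred), as.integer(s$y))))) {
      if (k == 0) next
      key <- as.character(k)
      pk <- pred == k; tk <- s$y == k
      inter[[key]] <- sum(pk & tk) + (inter[[key]] %||% 0)
      psum[[key]] <- sum(pk) + (psum[[key]] %||% 0)
      tsum[[key]] <- sum(tk) + (tsum[[key]] %||% 0)
    }
  }
  present <- names(tsum)[vapply(tsum, `>`, logical(1), 0)]
  if (length(present) == 0) return(as.numeric(length(psum) == 0))
  mean(vapply(present, function(key) {
    2 * inter[[key]] / (psum[[key]] + tsum[[key]])
  }, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

predict_labels <- function(model, x) {
  argmax_channels(softmax_channels(mod_forward(model, x, train = FALSE)))
}

# Predict one sample; if the sample carries a spine mask (stage-2 cascade),
# labels outside it are zeroed, matching the final masking step of the
# recognition pipeline.
predict_sample <- function(model, s) {
  pred <- predict_labels(model, s$x)
  if (!is.null(s$mask)) pred[s$mask == 0] <- 0L
  pred
}

#' Train a model
#'
#' Runs the adaptive-moment optimizer over mini-batches assembled by
#' gradient accumulation, logging per-epoch training loss and validation
#' macro Dice, decaying the learning rate on validation plateaus and
#' retaining the best-validation parameters (restored into the model before
#' returning). All randomness derives from `cfg$seed`, so a fixed seed and
#' fixed data reproduce the run exactly in single-threaded execution.
#'
#' @param model A stage-1 or stage-2 model module.
#' @param train_set,val_set Non-empty lists of samples, each a list with
#'   fields `x` (input array, channel axis last) and `y` (integer truth).
#' @param cfg A [train_config()].
#' @return A list with `model`, `history` (tibble: epoch, train_loss,
#'   val_dice, lr) and `best` (best validation macro Dice).
#' @export
train <- function(model, train_set, val_set, cfg = train_config()) {
  if (length(train_set) == 0 || length(val_set) == 0) {
    stop("train and validation sets must be non-empty", call. = FALSE)
  }
  set.seed(cfg$seed)
  opt <- make_adam(model, lr = cfg$lr)
  best_dice <- -Inf
  best_params <- NULL
  best_buffers <- NULL
  since_best <- 0
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(train_set))
    ep_loss <- 0
    nb <- 0
    i <- 1
    while (i <= length(ord)) {
      take <- ord[i:min(i + cfg$batch_size - 1, length(ord))]
      mod_zero_grads(model)
      bl <- 0
      for (j in take) {
        s <- train_set[[j]]
        if (!is.null(cfg$augment) && length(dim(s$x)) == 3L) {
          a <- augment_sample_2d(s$x, s$y, cfg$augment)
          s <- list(x = a$x, y = a$y)
        }
        logits <- mod_forward(model, s$x, train = TRUE)
        lg <- seg_loss_grad(logits, s$y, cfg$loss_weights,
                            class_weights = cfg$class_weights)
        mod_backward(model, lg$grad)
        bl <- bl + lg$loss
      }
      adam_step(opt, grad_scale = 1 / length(take))
      ep_loss <- ep_loss + bl / length(take)
      nb <- nb + 1
      i <- i + cfg$batch_size
    }
    vd <- pooled_macro_dice(model, val_set)
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / nb,
                                 val_dice = vd, lr = opt$lr)
    if (vd > best_dice + 1e-9) {
      best_dice <- vd
      best_params <- mod_params(model)
      best_buffers <- mod_buffers(model)
      since_best <- 0
    } else {
      since_best <- since_best + 1
      if (since_best >= 10) {
        opt$lr <- opt$lr * 0.5
        since_best <- 0
      }
    }
  }
  if (!is.null(best_params)) {
    mod_set_params(model, best_params)
    mod_set_buffers(model, best_buffers)
  }
  list(model = model, history = do.call(rbind, hist), best = best_dice)
}

#' Evaluate a model on a test set
#'
#' Predicts every sample, scores it with the overlap metrics (binary for the
#' segmentation task, one-vs-rest macro over present classes for
#' recognition) and aggregates. Optionally writes the per-sample table as
#' CSV and the aggregate as JSON.
#'
#' @param model A trained model module.
#' @param test_set Non-empty list of samples (`x`, `y`, optional `id`).
#' @param task `"seg"` or `"recog"`.
#' @param csv_path,json_path Optional output paths.
#' @return A list with `per_sample` (tibble: scan_id, class, dsc_pct,
#'   iou_pct, precision_pct, recall_pct) and `aggregate` (named means over
#'   samples of the per-sample macro rows).
#' @export
evaluate <- function(model, test_set, task = c("seg", "recog"),
                     csv_path = NULL, json_path = NULL) {
  task <- match.arg(task)
  if (length(test_set) == 0) stop("test set is empty", call. = FALSE)
  rows <- list()
  macros <- list()
  for (i in seq_along(test_set)) {
    s <- test_set[[i]]
    id <- if (!is.null(s$id)) s$id else sprintf("sample_%03d", i)
    pred <- predict_sample(model, s)
    rep_ <- macro_report(pred, array(as.integer(s$y), dim(pred)))
    rep_$scan_id <- id
    rows[[i]] <- rep_[, c("scan_id", setdiff(names(rep_), "scan_id"))]
    macros[[i]] <- rep_[rep_$class == "macro", ]
  }
  per_sample <- do.call(rbind, rows)
  mt <- do.call(rbind, macros)
  aggregate <- c(dsc_pct = mean(mt$dsc_pct), iou_pct = mean(mt$iou_pct),
                 precision_pct = mean(mt$precision_pct),
                 recall_pct = mean(mt$recall_pct))
  if (!is.null(csv_path)) write.csv(per_sample, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(aggregate), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  list(per_sample = per_sample, aggregate = aggregate)
}

# ---- sample preparation from phantom volumes --------------------------------

# Slice a preprocessed volume/label pair into stage-1 training samples along
# a plane. Keeps slices containing foreground (up to `max_fg`, evenly
# spaced) plus `bg_ratio` times as many background slices (evenly spaced
# over the whole background range, so torso-only and air-only slices are
# both represented) — training must see both classes without being
# dominated by empty slices.
prepare_seg_samples <- function(volume, labels, plane = "sagittal",
                                bg_ratio = 0.25, id = NULL, max_fg = Inf) {
  axis <- plane_axis(plane)
  d <- dim(volume$data)
  mask <- labels$data > 0
  fg <- which(vapply(seq_len(d[axis]), function(i) {
    any(get_slice(mask, axis, i))
  }, logical(1)))
  if (length(fg) > max_fg) {
    fg <- fg[unique(round(seq(1, length(fg), length.out = max_fg)))]
  }
  bg <- setdiff(seq_len(d[axis]), fg)
  n_bg <- min(length(bg), ceiling(bg_ratio * max(length(fg), 1)))
  keep <- sort(c(fg, bg[unique(round(seq(1, length(bg),
                                         length.out = n_bg)))]))
  lapply(keep, function(i) {
    x <- get_slice(volume$data, axis, i)
    dim(x) <- c(dim(x), 1L)
    list(x = x, y = matrix(as.integer(get_slice(mask, axis, i)),
                           nrow = dim(x)[1]),
         id = if (is.null(id)) NULL else sprintf("%s_s%03d", id, i))
  })
}

# Build one stage-2 sample from a preprocessed volume, its spine mask
# (ground truth union or a stage-1 prediction) and the vertebra labels.
prepare_recog_sample <- function(volume, spine_mask, labels, id = NULL) {
  list(x = recog_input(volume, spine_mask),
       y = array(as.integer(labels$data), dim(labels$data)),
       mask = array(as.integer(spine_mask$data > 0), dim(spine_mask$data)),
       id = id)
}
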