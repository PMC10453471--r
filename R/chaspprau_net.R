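# Stage 1: 2D attention residual U-Net with cascaded hierarchical atrous
# spatial pyramid pooling, applied slice-wise for binary spine segmentation.
#
# Architecture per encoder level: residual block -> 2x2 max-pool -> CHASPP;
# a residual bottleneck; per decoder level: nearest upsample x2 -> attention
# gate (skip from that level's residual block, gate from the decoder state)
# -> channel concatenation -> residual block. Dropout sits in the bottleneck
# and decoder blocks; a final 1x1 convolution produces class logits.

#' Stage-1 model configuration
#'
#' @param base_width Channels at the first level (default 16, doubling per
#'   level).
#' @param depth Number of pooling stages (default 3, giving one CHASPP after
#'   each of the three pools and three attention gates).
#' @param chaspp_root,chaspp_branches CHASPP dilation rates (defaults 2 and
#'   `c(1, 2, 3)`).
#' @param dropout Dropout fraction in bottleneck and decoder (default 0.3).
#' @param in_channels Input channels (default 1, the CT slice).
#' @param out_classes Output classes (default 2: background/spine).
#' @param norm Include data-dependent channel normalisation after the
#'   convolutions (default `FALSE`). CT intensities are calibrated, and
#'   per-sample normalisation makes the network blind to absolute intensity:
#'   on spine-free slices it rescales soft tissue into the range bone
#'   occupies on spine slices, producing hallucinated foreground. The
#'   normalisation-free default keeps absolute Hounsfield information.
#' @return A `seg_model_config` list.
#' @export
seg_model_config <- function(base_width = 16, depth = 3, chaspp_root = 2,
                             chaspp_branches = c(1, 2, 3), dropout = 0.3,
                             in_channels = 1, out_classes = 2, norm = FALSE) {
  if (depth < 1) stop("depth must be at least 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  if (base_width < 1) stop("base_width must be positive", call. = FALSE)
  structure(list(base_width = as.integer(base_width), depth = as.integer(depth),
                 chaspp_root = chaspp_root, chaspp_branches = chaspp_branches,
                 dropout = dropout, in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes), norm = norm),
            class = "seg_model_config")
}

#' Build the stage-1 segmentation model
#'
#' @param cfg A [seg_model_config()]. Weights are initialised from the
#'   current RNG state; call `set.seed` first for reproducible models.
#' @return A network module (also of class `spineseg_seg_model`) mapping an
#'   `(H, W, in_channels)` slice to `(H, W, out_classes)` logits; H and W
#'   must be divisible by `2^depth`.
#' @export
build_seg_model <- function(cfg = seg_model_config()) {
  stopifnot(inherits(cfg, "seg_model_config"))
  d <- cfg$depth
  widths <- cfg$base_width * 2^(seq_len(d) - 1)
  bott_w <- cfg$base_width * 2^d
  ch <- list()
  cin <- cfg$in_channels
  nrm <- isTRUE(cfg$norm)
  for (i in seq_len(d)) {
    ch[[paste0("enc_res", i)]] <- nn_residual_block(cin, widths[i], norm = nrm)
    ch[[paste0("pool", i)]] <- layer_maxpool2()
    ch[[paste0("chaspp", i)]] <- nn_chaspp(widths[i], cfg$chaspp_root,
                                           cfg$chaspp_branches,
                                           out_channels = widths[i],
                                           width = widths[i], norm = nrm)
    cin <- widths[i]
  }
  ch$bottleneck <- nn_residual_block(widths[d], bott_w, norm = nrm)
  ch$bott_drop <- layer_dropout(cfg$dropout)
  gate_c <- bott_w
  for (i in rev(seq_len(d))) {
    ch[[paste0("up", i)]] <- layer_upsample2()
    ch[[paste0("att", i)]] <- nn_attention_gate(widths[i], gate_c)
    ch[[paste0("dec_res", i)]] <- nn_residual_block(widths[i] + gate_c,
                                                    widths[i], norm = nrm)
    ch[[paste0("dec_drop", i)]] <- layer_dropout(cfg$dropout)
    gate_c <- widths[i]
  }
  ch$head <- layer_conv2d(widths[1], cfg$out_classes, 1)
  m <- new_module(
    "seg_model", children = ch,
    fwd = function(m, x, train) {
      cfg <- m$cfg
      d <- cfg$depth
      if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
      hw <- dim(x)[1:2]
      if (any(hw %% 2^d != 0)) {
        stop("slice extents must be divisible by ", 2^d, call. = FALSE)
      }
      skips <- vector("list", d)
      h <- x
      for (i in seq_len(d)) {
        h <- mod_forward(m$children[[paste0("enc_res", i)]], h, train)
        skips[[i]] <- h
        h <- mod_forward(m$children[[paste0("pool", i)]], h, train)
        h <- mod_forward(m$children[[paste0("chaspp", i)]], h, train)
      }
      h <- mod_forward(m$children$bottleneck, h, train)
      h <- mod_forward(m$children$bott_drop, h, train)
      for (i in rev(seq_len(d))) {
        h <- mod_forward(m$children[[paste0("up", i)]], h, train)
        a <- mod_forward(m$children[[paste0("att", i)]],
                         list(skip = skips[[i]], gate = h), train)
        h <- abind3(a, h)
        h <- mod_forward(m$children[[paste0("dec_res", i)]], h, train)
        h <- mod_forward(m$children[[paste0("dec_drop", i)]], h, train)
      }
      mod_forward(m$children$head, h, train)
    },
    bwd = function(m, dy) {
      cfg <- m$cfg
      d <- cfg$depth
      dh <- mod_backward(m$children$head, dy)
      dskips <- vector("list", d)
      for (i in seq_len(d)) {
        dh <- mod_backward(m$children[[paste0("dec_drop", i)]], dh)
        dh <- mod_backward(m$children[[paste0("dec_res", i)]], dh)
        wa <- m$att_widths[i]
        da <- dh[, , seq_len(wa), drop = FALSE]
        dg <- dh[, , -seq_len(wa), drop = FALSE]
        datt <- mod_backward(m$children[[paste0("att", i)]], da)
        dskips[[i]] <- datt$skip
        dh <- mod_backward(m$children[[paste0("up", i)]], datt$gate + dg)
      }
      dh <- mod_backward(m$children$bott_drop, dh)
      dh <- mod_backward(m$children$bottleneck, dh)
      for (i in rev(seq_len(d))) {
        dh <- mod_backward(m$children[[paste0("chaspp", i)]], dh)
        dh <- mod_backward(m$children[[paste0("pool", i)]], dh)
        dh <- dh + dskips[[i]]
        dh <- mod_backward(m$children[[paste0("enc_res", i)]], dh)
      }
      dh
    },
    extra = list(cfg = cfg, att_widths = widths)
  )
  class(m) <- c("spineseg_seg_model", class(m))
  m
}

#' Segment one slice
#'
#' Runs the model in evaluation mode and returns per-class probabilities.
#'
#' @param model A built stage-1 model.
#' @param s A 2D slice (H x W) or (H, W, in_channels) array, preprocessed.
#' @return `(H, W, out_classes)` array of probabilities summing to 1 at
#'   every pixel.
#' @export
segment_slice <- function(model, s) {
  stopifnot(inherits(model, "spineseg_seg_model"))
  if (length(dim(s)) == 2L) dim(s) <- c(dim(s), 1L)
  softmax_channels(mod_forward(model, s, train = FALSE))
}

plane_axis <- function(plane) {
  switch(match.arg(plane, c("sagittal", "axial", "coronal")),
         axial = 1L, coronal = 2L, sagittal = 3L)
}

# Extract slice i along `axis` of a 3D (or 4D channelled) array.
get_slice <- function(x, axis, i) {
  nd <- length(dim(x))
  idx <- rep(list(quote(expr = )), nd)
  idx[[axis]] <- i
  s <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  d <- dim(s)[-axis]
  dim(s) <- d
  s
}

set_slice <- function(x, axis, i, value) {
  nd <- length(dim(x))
  idx <- rep(list(quote(expr = )), nd)
  idx[[axis]] <- i
  do.call(`[<-`, c(list(x), idx, list(value)))
}

#' Segment a whole volume slice-wise
#'
#' Applies [segment_slice()] to every slice in the chosen anatomical plane
#' and restacks the per-pixel arg-max into a binary label map aligned with
#' the input. Exact probability ties resolve to the lower class index
#' (background wins).
#'
#' @param model A built stage-1 model.
#' @param v A preprocessed `spine_volume` in canonical orientation.
#' @param plane Slicing plane; default `"sagittal"`, where the spine is
#'   contiguous.
#' @return A binary `spine_labelmap` with the input geometry.
#' @export
segment_volume <- function(model, v, plane = "sagittal") {
  stopifnot(inherits(v, "spine_volume"))
  axis <- plane_axis(plane)
  d <- dim(v$data)
  out <- array(0L, d)
  for (i in seq_len(d[axis])) {
    p <- segment_slice(model, get_slice(v$data, axis, i))
    lab <- argmax_channels(p)
    out <- set_slice(out, axis, i, lab)
  }
  new_labelmap(out, v$spacing, v$affine)
}

# Trailing-axis arg-max with ties resolved to the lowest class index;
# returns 0-based class labels.
argmax_channels <- function(p) {
  d <- dim(p)
  cdim <- d[length(d)]
  pm <- matrix(p, ncol = cdim)
  lab <- max.col(pm, ties.method = "first") - 1L
  dim(lab) <- d[-length(d)]
  lab
}
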