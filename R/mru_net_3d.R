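# Stage 2: 3D multi-view recognition network.
#
# Three independent lightweight 2D encoders (inverted-residual stacks with an
# interleaved residual block, one encoder per anatomical plane) process every
# slice of the input volume in their plane. Per-slice feature maps are
# restacked along the slicing axis into a 3D feature volume, trilinearly
# resampled to a common fusion grid at 1/8 of the input extents, and
# concatenated channel-wise in fixed order (axial, sagittal, coronal). A 3D
# decoder with three upsample-by-2 levels — each fed a multi-scale fused skip
# recomputed from the encoders at 1/4 and 1/2 resolution — produces
# per-voxel class logits at full resolution.
#
# The stage-2 input has two channels: the normalized CT volume and the
# stage-1 binary spine mask; the final predicted labels are zeroed outside
# that mask, enforcing the cascade.

#' Stage-2 model configuration
#'
#' @param stem_width Channels of the stride-2 stem convolution (default 8).
#' @param bottlenecks List of inverted-residual stage specs, each a list
#'   with fields `t` (expansion), `c` (channels), `n` (repeats), `a`
#'   (stride). The default is a width-reduced variant of the standard mobile
#'   stack truncated at overall stride 8 (stem /2, then /4 and /8).
#' @param fused_channels Per-view channels at the 1/8 fusion grid (default
#'   32); the 1/4 and 1/2 skip fusions use half and a quarter of this width.
#' @param decoder_widths Channels of the three 3D decoder levels
#'   (default `c(32, 16, 12)`).
#' @param dropout Dropout fraction in decoder blocks (default 0.3).
#' @param out_classes 1 + maximum vertebra count (default 25: background
#'   plus C1-L5 with an L6 allowance).
#' @param input_channels Input channels (default 2: CT plus stage-1 mask).
#' @return A `recog_model_config` list.
#' @export
recog_model_config <- function(stem_width = 8,
                               bottlenecks = list(
                                 list(t = 1, c = 8, n = 1, a = 1),
                                 list(t = 4, c = 12, n = 2, a = 2),
                                 list(t = 4, c = 16, n = 2, a = 2)),
                               fused_channels = 32,
                               decoder_widths = c(32, 16, 12),
                               dropout = 0.3, out_classes = 25,
                               input_channels = 2) {
  if (out_classes < 2) stop("out_classes must be at least 2", call. = FALSE)
  strides <- vapply(bottlenecks, function(b) b$a, numeric(1))
  if (prod(strides) * 2 != 8) {
    stop("encoder stages must reach overall stride 8 (stem /2 plus two /2 stages)",
         call. = FALSE)
  }
  structure(list(stem_width = as.integer(stem_width), bottlenecks = bottlenecks,
                 fused_channels = as.integer(fused_channels),
                 decoder_widths = as.integer(decoder_widths),
                 dropout = dropout, out_classes = as.integer(out_classes),
                 input_channels = as.integer(input_channels),
                 encoder_downsample = 8L),
            class = "recog_model_config")
}

# Per-view slice encoder: stem (stride 2) -> bottleneck stages (reaching
# stride 8) with a residual block interleaved before the last stage, tapping
# features at strides 2, 4 and 8 and projecting each tap to its fusion width.
# Forward maps an (H, W, C) slice to list(f2, f4, f8).
build_view_encoder <- function(cfg) {
  fc8 <- cfg$fused_channels
  fc4 <- max(2L, cfg$fused_channels %/% 2L)
  fc2 <- max(2L, cfg$fused_channels %/% 4L)
  bn <- cfg$bottlenecks
  ch <- list(
    stem = conv_norm_act(cfg$input_channels, cfg$stem_width, k = 3, stride = 2),
    stage1 = nn_inverted_residual(cfg$stem_width, bn[[1]]),
    stage2 = nn_inverted_residual(bn[[1]]$c, bn[[2]]),
    resblock = nn_residual_block(bn[[2]]$c, bn[[2]]$c),
    stage3 = nn_inverted_residual(bn[[2]]$c, bn[[3]]),
    proj8 = conv_norm_act(bn[[3]]$c, fc8, k = 1),
    proj4 = conv_norm_act(bn[[2]]$c, fc4, k = 1),
    proj2 = conv_norm_act(bn[[1]]$c, fc2, k = 1)
  )
  new_module(
    "view_encoder", children = ch,
    fwd = function(m, x, train) {
      h2 <- mod_forward(m$children$stage1,
                        mod_forward(m$children$stem, x, train), train)
      h4 <- mod_forward(m$children$resblock,
                        mod_forward(m$children$stage2, h2, train), train)
      h8 <- mod_forward(m$children$stage3, h4, train)
      list(f2 = mod_forward(m$children$proj2, h2, train),
           f4 = mod_forward(m$children$proj4, h4, train),
           f8 = mod_forward(m$children$proj8, h8, train))
    },
    bwd = function(m, dy) {
      dh8 <- mod_backward(m$children$proj8, dy$f8)
      dh4 <- mod_backward(m$children$stage3, dh8) +
        mod_backward(m$children$proj4, dy$f4)
      dh2 <- mod_backward(m$children$stage2,
                          mod_backward(m$children$resblock, dh4)) +
        mod_backward(m$children$proj2, dy$f2)
      mod_backward(m$children$stem, mod_backward(m$children$stage1, dh2))
    },
    extra = list(fused = c(fc2 = fc2, fc4 = fc4, fc8 = fc8))
  )
}

# Restack per-slice maps into a 3D feature volume in canonical axis order.
# axis: the slicing axis (1 = axial, 2 = coronal, 3 = sagittal). Each slice
# map is (a, b, C) where (a, b) are the remaining axes in ascending order.
restack_slices <- function(maps, axis) {
  d2 <- dim(maps[[1]])
  n <- length(maps)
  full_dims <- append(d2[1:2], n, after = axis - 1)
  out <- array(0, c(full_dims, d2[3]))
  for (i in seq_len(n)) out <- set_slice(out, axis, i, maps[[i]])
  out
}

#' Build the stage-2 recognition model
#'
#' Assembles the three independent view encoders (no shared weights), the
#' multi-scale fusion, and the 3D decoder ending in a 1x1x1 classification
#' convolution.
#'
#' @param cfg A [recog_model_config()].
#' @return A network module (class `spineseg_recog_model`) mapping a
#'   `(D, H, W, input_channels)` array (extents divisible by 8) to
#'   `(D, H, W, out_classes)` logits.
#' @export
build_recog_model <- function(cfg = recog_model_config()) {
  stopifnot(inherits(cfg, "recog_model_config"))
  dw <- cfg$decoder_widths
  fc8 <- cfg$fused_channels
  fc4 <- max(2L, fc8 %/% 2L); fc2 <- max(2L, fc8 %/% 4L)
  ch <- list(
    enc_axial = build_view_encoder(cfg),
    enc_sagittal = build_view_encoder(cfg),
    enc_coronal = build_view_encoder(cfg),
    dec8 = conv3d_norm_act(3 * fc8, dw[1]),
    drop8 = layer_dropout(cfg$dropout),
    dec4 = conv3d_norm_act(dw[1] + 3 * fc4, dw[2]),
    drop4 = layer_dropout(cfg$dropout),
    dec2 = conv3d_norm_act(dw[2] + 3 * fc2, dw[3]),
    drop2 = layer_dropout(cfg$dropout),
    dec1 = conv3d_norm_act(dw[3], dw[3]),
    head = layer_conv3d(dw[3], cfg$out_classes, k = 1)
  )
  m <- new_module(
    "recog_model", children = ch,
    fwd = function(m, x, train) {
      d <- dim(x)[1:3]
      if (any(d %% 8 != 0)) {
        stop("volume extents must be divisible by 8", call. = FALSE)
      }
      m$in_dims <- d
      views <- list(axial = 1L, sagittal = 3L, coronal = 2L)
      fused <- list()   # per scale, list of per-view stacked+resized features
      m$enc_states <- list()
      m$resizers <- list()
      for (vn in names(views)) {
        axis <- views[[vn]]
        enc <- m$children[[paste0("enc_", vn)]]
        nslices <- d[axis]
        maps <- list(f2 = vector("list", nslices),
                     f4 = vector("list", nslices),
                     f8 = vector("list", nslices))
        states <- if (train) vector("list", nslices) else NULL
        for (i in seq_len(nslices)) {
          sl <- get_slice(x, axis, i)
          f <- mod_forward(enc, sl, train)
          if (train) states[[i]] <- mod_save_state(enc)
          maps$f2[[i]] <- f$f2; maps$f4[[i]] <- f$f4; maps$f8[[i]] <- f$f8
        }
        m$enc_states[[vn]] <- states
        for (sc in c("f8", "f4", "f2")) {
          fac <- c(f8 = 8L, f4 = 4L, f2 = 2L)[[sc]]
          stacked <- restack_slices(maps[[sc]], axis)
          rz <- layer_resize3d(d %/% fac)
          m$resizers[[paste0(vn, "_", sc)]] <- rz
          fused[[sc]][[vn]] <- mod_forward(rz, stacked, train)
        }
      }
      f8 <- do.call(abind4, fused$f8)   # order: axial, sagittal, coronal
      f4 <- do.call(abind4, fused$f4)
      f2 <- do.call(abind4, fused$f2)
      m$skip_widths <- c(f8 = dim(fused$f8$axial)[4],
                         f4 = dim(fused$f4$axial)[4],
                         f2 = dim(fused$f2$axial)[4])
      h <- mod_forward(m$children$drop8,
                       mod_forward(m$children$dec8, f8, train), train)
      m$up4 <- layer_resize3d(d %/% 4L)
      h <- mod_forward(m$up4, h, train)
      h <- abind4(h, f4)
      h <- mod_forward(m$children$drop4,
                       mod_forward(m$children$dec4, h, train), train)
      m$up2 <- layer_resize3d(d %/% 2L)
      h <- mod_forward(m$up2, h, train)
      h <- abind4(h, f2)
      h <- mod_forward(m$children$drop2,
                       mod_forward(m$children$dec2, h, train), train)
      m$up1 <- layer_resize3d(d)
      h <- mod_forward(m$up1, h, train)
      h <- mod_forward(m$children$dec1, h, train)
      mod_forward(m$children$head, h, train)
    },
    bwd = function(m, dy) {
      d <- m$in_dims
      dh <- mod_backward(m$children$head, dy)
      dh <- mod_backward(m$children$dec1, dh)
      dh <- mod_backward(m$up1, dh)
      dh <- mod_backward(m$children$dec2, mod_backward(m$children$drop2, dh))
      w2 <- m$skip_widths[["f2"]]
      # dh is the gradient w.r.t. concat(h_up, f2): decoder part first
      dhu <- dh[, , , seq_len(dim(dh)[4] - 3 * w2), drop = FALSE]
      df2 <- dh[, , , dim(dh)[4] - 3 * w2 + seq_len(3 * w2), drop = FALSE]
      dh <- mod_backward(m$up2, dhu)
      dh <- mod_backward(m$children$dec4, mod_backward(m$children$drop4, dh))
      w4 <- m$skip_widths[["f4"]]
      dhu <- dh[, , , seq_len(dim(dh)[4] - 3 * w4), drop = FALSE]
      df4 <- dh[, , , dim(dh)[4] - 3 * w4 + seq_len(3 * w4), drop = FALSE]
      dh <- mod_backward(m$up4, dhu)
      df8 <- mod_backward(m$children$dec8, mod_backward(m$children$drop8, dh))
      w8 <- m$skip_widths[["f8"]]
      views <- list(axial = 1L, sagittal = 3L, coronal = 2L)
      dgrads <- list(f8 = df8, f4 = df4, f2 = df2)
      widths <- c(f8 = w8, f4 = w4, f2 = w2)
      dx <- array(0, c(d, m$cfg$input_channels))
      for (vi in seq_along(views)) {
        vn <- names(views)[vi]
        axis <- views[[vn]]
        enc <- m$children[[paste0("enc_", vn)]]
        nslices <- d[axis]
        dmaps <- list()
        for (sc in c("f8", "f4", "f2")) {
          w <- widths[[sc]]
          dv <- dgrads[[sc]][, , , (vi - 1) * w + seq_len(w), drop = FALSE]
          dstacked <- mod_backward(m$resizers[[paste0(vn, "_", sc)]], dv)
          dmaps[[sc]] <- dstacked
        }
        for (i in seq_len(nslices)) {
          mod_restore_state(enc, m$enc_states[[vn]][[i]])
          dsl <- mod_backward(enc, list(
            f2 = get_slice(dmaps$f2, axis, i),
            f4 = get_slice(dmaps$f4, axis, i),
            f8 = get_slice(dmaps$f8, axis, i)))
          dx <- set_slice(dx, axis, i, get_slice(dx, axis, i) + dsl)
        }
      }
      m$enc_states <- NULL
      dx
    },
    extra = list(cfg = cfg)
  )
  class(m) <- c("spineseg_recog_model", class(m))
  m
}

#' Encode one view of a volume
#'
#' Runs a single view encoder (evaluation mode) over every slice in the
#' given plane, restacks the per-slice stride-8 feature maps along the
#' slicing axis and trilinearly resamples them to the common fusion grid at
#' 1/8 of the input extents.
#'
#' @param model A built stage-2 model.
#' @param x `(D, H, W, input_channels)` input array, extents divisible by 8.
#' @param axis `"axial"`, `"sagittal"` or `"coronal"`.
#' @return `(D/8, H/8, W/8, fused_channels)` feature volume.
#' @export
encode_view <- function(model, x, axis = c("axial", "sagittal", "coronal")) {
  stopifnot(inherits(model, "spineseg_recog_model"))
  axis <- match.arg(axis)
  ax <- c(axial = 1L, coronal = 2L, sagittal = 3L)[[axis]]
  d <- dim(x)[1:3]
  if (any(d %% 8 != 0)) stop("volume extents must be divisible by 8", call. = FALSE)
  enc <- model$children[[paste0("enc_", axis)]]
  maps <- vector("list", d[ax])
  for (i in seq_len(d[ax])) {
    maps[[i]] <- mod_forward(enc, get_slice(x, ax, i), train = FALSE)$f8
  }
  stacked <- restack_slices(maps, ax)
  mod_forward(layer_resize3d(d %/% 8L), stacked, train = FALSE)
}

#' Fuse per-view feature volumes
#'
#' Channel-wise concatenation in fixed order (axial, sagittal, coronal).
#'
#' @param f_ax,f_sag,f_cor Feature volumes of identical extents and channel
#'   counts.
#' @return Concatenated feature volume with three times the channels.
#' @export
fuse_views <- function(f_ax, f_sag, f_cor) {
  da <- dim(f_ax); ds <- dim(f_sag); dc <- dim(f_cor)
  if (!identical(da, ds) || !identical(da, dc)) {
    stop("view feature extents differ", call. = FALSE)
  }
  abind4(f_ax, f_sag, f_cor)
}

#' Recognize vertebrae in a segmented volume
#'
#' Stacks the normalized CT and the stage-1 binary mask into the two-channel
#' stage-2 input, predicts per-voxel class probabilities, arg-maxes them and
#' zeroes every label outside the stage-1 mask (cascade masking).
#'
#' @param model A built stage-2 model.
#' @param v Preprocessed `spine_volume` (extents divisible by 8).
#' @param spine_mask Aligned binary `spine_labelmap` from stage 1.
#' @param mask_output Zero labels outside `spine_mask` (default `TRUE`).
#' @return A multi-class `spine_labelmap` aligned with `v`.
#' @export
recognize <- function(model, v, spine_mask, mask_output = TRUE) {
  stopifnot(inherits(model, "spineseg_recog_model"),
            inherits(v, "spine_volume"))
  if (!identical(dim(v$data), dim(spine_mask$data))) {
    stop("volume and spine mask are misaligned", call. = FALSE)
  }
  x <- recog_input(v, spine_mask)
  logits <- mod_forward(model, x, train = FALSE)
  lab <- argmax_channels(softmax_channels(logits))
  if (mask_output) lab[spine_mask$data == 0] <- 0L
  new_labelmap(lab, v$spacing, v$affine)
}

# Stack CT and binary mask into the stage-2 input tensor.
recog_input <- function(v, spine_mask) {
  d <- dim(v$data)
  x <- array(0, c(d, 2))
  x[, , , 1] <- v$data
  x[, , , 2] <- as.numeric(spine_mask$data > 0)
  x
}
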