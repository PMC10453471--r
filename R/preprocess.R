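# Preprocessing: smoothing, Hounsfield-unit clamping, normalization and
# resizing to the working grid.
#
# The full pipeline applies, in order: reorient -> smooth (image only) ->
# clamp (image only) -> resize -> normalize (image only). Label maps follow
# the same geometric steps with nearest-neighbour interpolation so their
# label sets never grow.

NORMALIZATION_MODES <- c("clamped_hu", "zero_mean", "unit_range", "symmetric_range")

#' Preprocessing configuration
#'
#' @param clamp_lo,clamp_hi Clamp window in HU (default `[-1000, 800]`,
#'   covering air through dense bone).
#' @param smooth_sigma Gaussian smoothing sigma in mm (0 disables).
#' @param target_inplane Length-2 in-plane working grid (rows, columns of
#'   each axial slice), default `c(256, 256)`.
#' @param target_depth Number of slices after resampling, or `"keep"`.
#' @param mode Normalization mode: `"clamped_hu"` (clamped HU passed through
#'   unchanged), `"zero_mean"` (per-volume mean 0, sd 1), `"unit_range"`
#'   (affine map of the clamp window onto `[0, 1]`), or `"symmetric_range"`
#'   (onto `[-1, 1]`). The range modes use the fixed clamp bounds, not
#'   per-volume extremes, so the mapping is identical across volumes.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(clamp_lo = -1000, clamp_hi = 800,
                              smooth_sigma = 0.75,
                              target_inplane = c(256, 256),
                              target_depth = "keep",
                              mode = "clamped_hu") {
  if (clamp_lo >= clamp_hi) stop("clamp_lo must be below clamp_hi", call. = FALSE)
  if (smooth_sigma < 0) stop("smooth_sigma must be nonnegative", call. = FALSE)
  mode <- match.arg(mode, NORMALIZATION_MODES)
  if (!identical(target_depth, "keep") &&
      (!is.numeric(target_depth) || target_depth < 1)) {
    stop("target_depth must be 'keep' or a positive count", call. = FALSE)
  }
  if (length(target_inplane) != 2 || any(target_inplane < 1)) {
    stop("target_inplane must be two positive extents", call. = FALSE)
  }
  structure(list(clamp_lo = clamp_lo, clamp_hi = clamp_hi,
                 smooth_sigma = smooth_sigma,
                 target_inplane = as.integer(target_inplane),
                 target_depth = target_depth, mode = mode),
            class = "preprocess_config")
}

#' Clamp Hounsfield units
#'
#' @param v A `spine_volume`.
#' @param lo,hi Clamp bounds in HU, `lo < hi`.
#' @return The clamped volume; values already inside the window unchanged.
#' @export
clamp_hu <- function(v, lo = -1000, hi = 800) {
  stopifnot(inherits(v, "spine_volume"))
  if (lo >= hi) stop("clamp: lo must be below hi", call. = FALSE)
  v$data <- pmin(pmax(v$data, lo), hi)
  v
}

#' Gaussian smoothing with physical sigma
#'
#' Separable Gaussian filtering; `sigma` is given in millimetres and
#' converted per axis through the voxel spacing. Kernels are renormalised at
#' the array boundary, so constant volumes are exact fixed points.
#'
#' @param v A `spine_volume`.
#' @param sigma Standard deviation in mm; 0 is the identity.
#' @return The smoothed volume.
#' @export
smooth_volume <- function(v, sigma) {
  stopifnot(inherits(v, "spine_volume"))
  if (sigma < 0) stop("smooth: sigma must be nonnegative", call. = FALSE)
  if (sigma == 0) return(v)
  x <- v$data
  for (a in 1:3) {
    sig_vox <- sigma / v$spacing[a]
    if (sig_vox > 1e-8) {
      x <- apply_along_axis(x, gaussian_matrix(dim(x)[a], sig_vox), a)
    }
  }
  v$data <- x
  v
}

#' Intensity normalization
#'
#' Applies one of the four supported modes (see [preprocess_config()]) to a
#' volume already clamped to the configured window. All modes are monotone,
#' so the voxel intensity ordering is preserved. A zero-variance volume under
#' `"zero_mean"` maps to all zeros.
#'
#' @param v A `spine_volume`.
#' @param mode One of `"clamped_hu"`, `"zero_mean"`, `"unit_range"`,
#'   `"symmetric_range"`.
#' @param clamp_lo,clamp_hi The clamp window the range modes map from.
#' @return The normalized volume.
#' @export
normalize_volume <- function(v, mode = "clamped_hu",
                             clamp_lo = -1000, clamp_hi = 800) {
  stopifnot(inherits(v, "spine_volume"))
  mode <- match.arg(mode, NORMALIZATION_MODES)
  x <- v$data
  v$data <- switch(
    mode,
    clamped_hu = x,
    zero_mean = {
      s <- stats::sd(as.numeric(x))
      if (s < 1e-12) array(0, dim(x)) else (x - mean(x)) / s
    },
    unit_range = (x - clamp_lo) / (clamp_hi - clamp_lo),
    symmetric_range = 2 * (x - clamp_lo) / (clamp_hi - clamp_lo) - 1
  )
  v
}

#' Resize to the working grid
#'
#' Resamples each in-plane slice to `target_inplane` and, unless
#' `target_depth = "keep"`, the slice axis to `target_depth`. Volumes use
#' linear interpolation, label maps nearest-neighbour (no new labels can
#' appear). Spacing and affine are updated to preserve physical extent.
#'
#' @param v A `spine_volume` or `spine_labelmap`.
#' @param cfg A [preprocess_config()].
#' @return The resized object, same class.
#' @export
resize_to_grid <- function(v, cfg = preprocess_config()) {
  stopifnot(inherits(v, "spine_volume"))
  d <- dim(v$data)
  target <- c(if (identical(cfg$target_depth, "keep")) d[1]
              else as.integer(cfg$target_depth),
              cfg$target_inplane)
  if (any(target < 1)) stop("resize: targets must be positive", call. = FALSE)
  if (identical(as.integer(d), as.integer(target))) return(v)
  method <- if (is_labelmap(v)) "nearest" else "linear"
  x <- resize_array(v$data, target, axes = 1:3, method = method)
  scale <- d / target
  spacing <- v$spacing * scale
  # index map old = S %*% new under the half-pixel centre convention
  s <- diag(4)
  for (a in 1:3) {
    s[a, a] <- scale[a]
    s[a, 4] <- 0.5 * scale[a] - 0.5
  }
  affine <- v$affine %*% s
  if (is_labelmap(v)) new_labelmap(x, spacing, affine)
  else new_volume(x, spacing, affine)
}

#' Full preprocessing pipeline
#'
#' Applies reorient, smoothing (image only), clamping (image only), resizing
#' (image and labels) and normalization (image only), keeping the label map
#' geometrically aligned with the image throughout.
#'
#' @param v A `spine_volume`.
#' @param m Optional paired `spine_labelmap` (same grid).
#' @param cfg A [preprocess_config()].
#' @return A list with elements `volume` and `labels` (`NULL` if no label
#'   map was supplied).
#' @export
preprocess_pipeline <- function(v, m = NULL, cfg = preprocess_config()) {
  stopifnot(inherits(v, "spine_volume"))
  if (!is.null(m)) {
    stopifnot(is_labelmap(m))
    if (!identical(dim(m$data), dim(v$data))) {
      stop("volume and label map shapes differ", call. = FALSE)
    }
  }
  v <- reorient_canonical(v)
  if (!is.null(m)) m <- reorient_canonical(m)
  v <- smooth_volume(v, cfg$smooth_sigma)
  v <- clamp_hu(v, cfg$clamp_lo, cfg$clamp_hi)
  v <- resize_to_grid(v, cfg)
  if (!is.null(m)) m <- resize_to_grid(m, cfg)
  v <- normalize_volume(v, cfg$mode, cfg$clamp_lo, cfg$clamp_hi)
  list(volume = v, labels = m)
}
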