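# Joint image/label augmentation: mirror flips, in-plane rotation and
# in-plane scaling. Rotation and scaling act in the axial plane (array axes
# 2 and 3) about the slice centre, with linear interpolation for images and
# nearest-neighbour for label maps; out-of-field voxels are filled with the
# clamp floor (images) or background (labels). The random sampler draws ONE
# parameter set and applies the identical geometric transform to image and
# labels, so the pair stays aligned.

#' Augmentation specification
#'
#' @param scale_range Multiplicative zoom interval (default `c(0.9, 1.1)`).
#' @param rotation_range_deg In-plane rotation interval in degrees
#'   (default `c(-10, 10)`).
#' @param flip_lr Allow left-right mirror flips (default `TRUE`; other axes
#'   are disabled by default because superior-inferior inversion is
#'   anatomically impossible).
#' @param prob Probability that each of scale / rotation / flip is applied.
#' @param fill_image Fill value for image voxels leaving the field of view
#'   (default -1000 HU, i.e. air).
#' @return An `augmentation_spec` list.
#' @export
augmentation_spec <- function(scale_range = c(0.9, 1.1),
                              rotation_range_deg = c(-10, 10),
                              flip_lr = TRUE, prob = 0.5,
                              fill_image = -1000) {
  if (any(scale_range <= 0)) stop("scale_range must be positive", call. = FALSE)
  if (prob < 0 || prob > 1) stop("prob must be in [0, 1]", call. = FALSE)
  structure(list(scale_range = scale_range,
                 rotation_range_deg = rotation_range_deg,
                 flip_lr = flip_lr, prob = prob, fill_image = fill_image),
            class = "augmentation_spec")
}

#' Mirror flip along one array axis
#'
#' Pure permutation of voxels (no interpolation); an involution.
#'
#' @param v A `spine_volume` or `spine_labelmap`.
#' @param axis Array axis to mirror (1, 2 or 3; 3 = left-right under the
#'   canonical convention).
#' @return The flipped object, same class.
#' @export
flip_volume <- function(v, axis = 3) {
  stopifnot(inherits(v, "spine_volume"))
  if (!axis %in% 1:3) stop("invalid flip axis", call. = FALSE)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(v$data)[axis]))
  v$data <- do.call(`[`, c(list(v$data), idx, list(drop = FALSE)))
  v
}

#' In-plane rotation
#'
#' Rotates every axial slice by `angle` degrees about the slice centre.
#'
#' @param v A `spine_volume` or `spine_labelmap`.
#' @param angle Rotation angle in degrees (finite).
#' @param fill Out-of-field fill value (default: -1000 for images, 0 for
#'   label maps).
#' @return The rotated object, same class and grid shape.
#' @export
rotate_volume <- function(v, angle, fill = NULL) {
  stopifnot(inherits(v, "spine_volume"), is.finite(angle))
  lab <- is_labelmap(v)
  if (is.null(fill)) fill <- if (lab) 0 else -1000
  if (angle == 0) return(v)
  v$data <- affine_resample_plane(v$data, angle_deg = angle, factor = 1,
                                  method = if (lab) "nearest" else "linear",
                                  fill = fill)
  if (lab) v$data <- round(v$data)
  v
}

#' In-plane scaling (zoom)
#'
#' Zooms every axial slice about its centre by `factor`; the grid shape is
#' unchanged (crop for factor > 1, pad with `fill` for factor < 1).
#'
#' @inheritParams rotate_volume
#' @param factor Positive zoom factor.
#' @return The scaled object, same class and grid shape.
#' @export
scale_volume <- function(v, factor, fill = NULL) {
  stopifnot(inherits(v, "spine_volume"))
  if (!is.numeric(factor) || factor <= 0) {
    stop("scale factor must be positive", call. = FALSE)
  }
  lab <- is_labelmap(v)
  if (is.null(fill)) fill <- if (lab) 0 else -1000
  if (factor == 1) return(v)
  v$data <- affine_resample_plane(v$data, angle_deg = 0, factor = factor,
                                  method = if (lab) "nearest" else "linear",
                                  fill = fill)
  if (lab) v$data <- round(v$data)
  v
}

#' Random joint augmentation
#'
#' Samples one parameter set from the specification (using the current RNG
#' state, so results are reproducible under `set.seed`) and applies the same
#' geometric transform to the image and its label map. Rotation and scaling
#' are composed into a single resampling pass, so image and labels see the
#' identical map.
#'
#' @param v A `spine_volume`.
#' @param m The aligned `spine_labelmap`.
#' @param spec An [augmentation_spec()].
#' @return A list with elements `volume`, `labels`, and `params` (the drawn
#'   transform parameters).
#' @export
random_augment <- function(v, m, spec = augmentation_spec()) {
  stopifnot(inherits(v, "spine_volume"), is_labelmap(m))
  if (!identical(dim(v$data), dim(m$data))) {
    stop("image and label shapes are misaligned", call. = FALSE)
  }
  angle <- if (runif(1) < spec$prob) {
    runif(1, spec$rotation_range_deg[1], spec$rotation_range_deg[2])
  } else 0
  factor <- if (runif(1) < spec$prob) {
    runif(1, spec$scale_range[1], spec$scale_range[2])
  } else 1
  do_flip <- spec$flip_lr && runif(1) < spec$prob
  if (angle != 0 || factor != 1) {
    v$data <- affine_resample_plane(v$data, angle, factor,
                                    method = "linear", fill = spec$fill_image)
    m$data <- round(affine_resample_plane(m$data, angle, factor,
                                          method = "nearest", fill = 0))
  }
  if (do_flip) {
    v <- flip_volume(v, 3)
    m <- flip_volume(m, 3)
  }
  list(volume = v, labels = m,
       params = list(angle = angle, factor = factor, flip = do_flip))
}
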