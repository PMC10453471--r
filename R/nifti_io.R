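# NIfTI input/output and canonical orientation.
#
# A `spine_volume` holds a rank-3 array of Hounsfield units together with its
# voxel spacing (mm per array axis), anatomical orientation codes and the
# 4x4 voxel-to-world affine (0-based array indices to RAS+ millimetres).
# A `spine_labelmap` is the same container with integer-valued data
# (0 = background, k = vertebra k).
#
# Canonical convention: array axes run (superior -> inferior slices,
# anterior -> posterior rows, left -> right columns). Each axis is coded by
# the anatomical direction toward which its index increases, so the canonical
# code triple is I, P, R.

CANONICAL_CODES <- c("I", "P", "R")

#' Construct a volume
#'
#' @param data 3D numeric array (Hounsfield units).
#' @param spacing Positive voxel spacing in mm, one value per array axis.
#' @param affine 4x4 voxel-to-world matrix mapping 0-based array indices to
#'   RAS+ world mm. Defaults to a diagonal affine built from `spacing`.
#' @return A `spine_volume` object.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L) {
    stop("volume data must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("volume values must be finite", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three positive values", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  stopifnot(identical(dim(affine), c(4L, 4L)))
  v <- structure(
    list(data = data, spacing = as.numeric(spacing),
         orientation = orientation_codes(affine), affine = affine),
    class = "spine_volume"
  )
  v
}

#' Construct a label map
#'
#' @inheritParams new_volume
#' @param data 3D array of nonnegative integer labels.
#' @return A `spine_labelmap` object (also a `spine_volume`).
#' @export
new_labelmap <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (any(data < 0) || any(data != round(data))) {
    stop("label values must be nonnegative integers", call. = FALSE)
  }
  v <- new_volume(data, spacing, affine)
  class(v) <- c("spine_labelmap", class(v))
  v
}

is_labelmap <- function(v) inherits(v, "spine_labelmap")

#' @export
print.spine_volume <- function(x, ...) {
  kind <- if (is_labelmap(x)) "spine_labelmap" else "spine_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm, orientation %s\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(x$orientation, collapse = "")))
  if (is_labelmap(x)) {
    cat("  labels:", paste(sort(unique(as.integer(x$data))), collapse = " "), "\n")
  } else {
    cat(sprintf("  intensity range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

# Anatomical direction codes (one per array axis) from an affine: the letter
# names the direction in which the array index increases.
orientation_codes <- function(affine) {
  r <- affine[1:3, 1:3]
  pos <- c("R", "A", "S"); neg <- c("L", "P", "I")
  codes <- character(3)
  used <- integer(0)
  for (j in 1:3) {
    col <- r[, j]
    if (all(col == 0)) stop("degenerate affine orientation", call. = FALSE)
    k <- which.max(abs(col))
    if (k %in% used) stop("ambiguous affine orientation", call. = FALSE)
    used <- c(used, k)
    codes[j] <- if (col[k] > 0) pos[k] else neg[k]
  }
  codes
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`). Intensities are returned
#' unmodified; spacing and affine come from the header.
#'
#' @param path Path to an existing 3D NIfTI file.
#' @return A [new_volume()] object.
#' @export
read_volume <- function(path) {
  v <- read_nifti_impl(path)
  new_volume(v$data, v$spacing, v$affine)
}

#' Read a NIfTI label map
#'
#' @param path Path to an existing 3D NIfTI file with integer labels.
#' @return A [new_labelmap()] object.
#' @export
read_labelmap <- function(path) {
  v <- read_nifti_impl(path)
  new_labelmap(round(v$data), v$spacing, v$affine)
}

read_nifti_impl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ",
                                           conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), " dimensions", call. = FALSE)
  }
  affine <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(affine) <- list(dim = c(4L, 4L))
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  spacing[spacing == 0] <- 1
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))  # plain array, no image class
  list(data = data, spacing = spacing, affine = affine)
}

#' Write a volume or label map to NIfTI
#'
#' Volumes are written with a floating-point on-disk type, label maps with an
#' integer type. The affine is stored in both sform and qform.
#'
#' @param v A `spine_volume` or `spine_labelmap`.
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "spine_volume"))
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  }
  dtype <- if (is_labelmap(v)) "int16" else "float64"
  img <- RNifti::asNifti(v$data, datatype = dtype)
  aff <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Reorient a volume to the canonical axis convention
#'
#' Permutes and flips array axes (no interpolation) so that axis 1 runs
#' superior to inferior, axis 2 anterior to posterior and axis 3 left to
#' right, updating spacing and affine accordingly. Idempotent; the multiset
#' of voxel values is preserved, and each voxel keeps its world coordinates.
#'
#' @param v A `spine_volume` or `spine_labelmap`.
#' @return The reoriented object, same class.
#' @export
reorient_canonical <- function(v) {
  stopifnot(inherits(v, "spine_volume"))
  codes <- orientation_codes(v$affine)
  axis_of <- function(code) switch(code, R = , L = 3L, A = , P = 2L,
                                   S = , I = 1L,
                                   stop("unknown orientation code: ", code,
                                        call. = FALSE))
  world_axis <- vapply(codes, axis_of, integer(1))
  perm <- order(world_axis)  # new axis i takes the old axis mapping to slot i
  flip <- codes[perm] != CANONICAL_CODES
  if (identical(perm, 1:3) && !any(flip)) return(v)

  x <- aperm(v$data, perm)
  for (a in which(flip)) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[a]] <- rev(seq_len(dim(x)[a]))
    x <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  # index map: old_index = M %*% new_index (homogeneous, 0-based)
  m <- matrix(0, 4, 4); m[4, 4] <- 1
  dims_old <- dim(v$data)
  for (i in 1:3) {
    j <- perm[i]
    if (flip[i]) {
      m[j, i] <- -1
      m[j, 4] <- dims_old[j] - 1
    } else {
      m[j, i] <- 1
    }
  }
  affine <- v$affine %*% m
  spacing <- v$spacing[perm]
  if (is_labelmap(v)) new_labelmap(x, spacing, affine)
  else new_volume(x, spacing, affine)
}

# World coordinates (RAS mm) of 0-based voxel indices (n x 3 matrix or
# length-3 vector) under a volume's affine.
voxel_to_world <- function(v, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  h <- cbind(idx, 1) %*% t(v$affine)
  h[, 1:3, drop = FALSE]
}
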