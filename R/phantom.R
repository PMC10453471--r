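# Synthetic spine CT phantoms.
#
# Each phantom is a Hounsfield-unit volume holding a soft-tissue torso in
# air, with a curved cranio-caudal stack of ellipsoidal vertebra-like bodies
# at bone intensity separated by disc gaps, plus a matching integer label map
# (0 background, k = body k, numbered superior to inferior) and the exact
# mass centroid of every body in world millimetres. This mirrors the
# annotation structure of the public vertebra-challenge datasets (per-voxel
# masks plus per-vertebra centroids) so the full two-stage pipeline can be
# exercised end to end without external downloads.
#
# Vertebral bodies take their in-plane radius from `body_radius_mm` and an
# axial half-height of 0.55 times that radius (bodies are axially shorter
# than they are wide); the stack is centred on the slice axis and its
# centreline bows in the anterior-posterior direction along half a sine wave
# of amplitude `curvature_amp_mm`.

#' Phantom specification
#'
#' @param grid Array extents (slices, rows, columns), default `c(64, 96, 96)`.
#' @param spacing Voxel spacing in mm, default 2 mm isotropic.
#' @param n_vertebrae Number of vertebra-like bodies (default 6).
#' @param body_radius_mm In-plane body radius interval, default 8-12 mm.
#' @param disc_gap_mm Inter-body gap interval, default 3-5 mm.
#' @param curvature_amp_mm Amplitude of the sinusoidal centreline bow
#'   (default 6 mm).
#' @param hu_bone,hu_soft,hu_air Intensities of bone, soft tissue and air
#'   (defaults 700, 40, -1000 HU; bone sits inside the standard clamp window
#'   so clamping is non-destructive).
#' @param noise_sd Additive Gaussian noise sd in HU (default 25).
#' @param seed Optional integer seed making generation self-contained.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(64, 96, 96), spacing = c(2, 2, 2),
                         n_vertebrae = 6, body_radius_mm = c(8, 12),
                         disc_gap_mm = c(3, 5), curvature_amp_mm = 6,
                         hu_bone = 700, hu_soft = 40, hu_air = -1000,
                         noise_sd = 25, seed = NULL) {
  if (n_vertebrae < 1) stop("n_vertebrae must be at least 1", call. = FALSE)
  if (!(hu_air < hu_soft && hu_soft < hu_bone)) {
    stop("need hu_air < hu_soft < hu_bone", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 n_vertebrae = as.integer(n_vertebrae),
                 body_radius_mm = body_radius_mm, disc_gap_mm = disc_gap_mm,
                 curvature_amp_mm = curvature_amp_mm, hu_bone = hu_bone,
                 hu_soft = hu_soft, hu_air = hu_air, noise_sd = noise_sd,
                 seed = seed),
            class = "phantom_spec")
}

# Canonical-orientation affine for a phantom grid (axis codes I, P, R).
phantom_affine <- function(spacing) {
  a <- matrix(0, 4, 4)
  a[1, 3] <- spacing[3]
  a[2, 2] <- -spacing[2]
  a[3, 1] <- -spacing[1]
  a[4, 4] <- 1
  a
}

#' Generate one phantom
#'
#' Uses `spec$seed` when given, otherwise the current RNG state; identical
#' seeds give identical samples.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a `spine_volume`), `labels`
#'   (a `spine_labelmap`) and `centroids` (tibble: label, x_mm, y_mm, z_mm,
#'   the exact label-mass centres in world coordinates).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  g <- spec$grid
  sp <- spec$spacing
  ext_mm <- g * sp
  n <- spec$n_vertebrae

  radii <- runif(n, spec$body_radius_mm[1], spec$body_radius_mm[2])
  gaps <- if (n > 1) runif(n - 1, spec$disc_gap_mm[1], spec$disc_gap_mm[2])
          else numeric(0)
  half_heights <- 0.55 * radii
  total_len <- sum(2 * half_heights) + sum(gaps)
  if (total_len > 0.95 * ext_mm[1]) {
    stop("vertebral stack does not fit the grid (",
         round(total_len, 1), " mm needed, ", round(ext_mm[1], 1),
         " mm available)", call. = FALSE)
  }

  # voxel-centre coordinates along each axis, in mm
  zc <- (seq_len(g[1]) - 1) * sp[1]
  yc <- (seq_len(g[2]) - 1) * sp[2]
  xc <- (seq_len(g[3]) - 1) * sp[3]
  ymid <- ext_mm[2] / 2; xmid <- ext_mm[3] / 2

  # torso: elliptical soft-tissue cylinder in air, sized so the vertebral
  # bodies occupy a realistic few percent of the torso volume
  ry <- 0.26 * ext_mm[2]; rx <- 0.23 * ext_mm[3]
  plane <- outer(((yc - ymid) / ry)^2, ((xc - xmid) / rx)^2, `+`) <= 1
  vol <- array(spec$hu_air, g)
  for (k in seq_len(g[1])) vol[k, , ][plane] <- spec$hu_soft

  labels <- array(0L, g)
  z0 <- (ext_mm[1] - total_len) / 2
  cursor <- z0
  centres <- matrix(0, n, 3)  # (z, y, x) mm in index space
  for (k in seq_len(n)) {
    czk <- cursor + half_heights[k]
    frac <- (czk - z0) / total_len
    cyk <- ymid + spec$curvature_amp_mm * sin(pi * frac)
    cxk <- xmid
    centres[k, ] <- c(czk, cyk, cxk)
    zmask <- which(abs(zc - czk) <= half_heights[k])
    for (zi in zmask) {
      zterm <- ((zc[zi] - czk) / half_heights[k])^2
      if (zterm > 1) next
      body <- outer(((yc - cyk) / radii[k])^2, ((xc - cxk) / radii[k])^2,
                    `+`) <= 1 - zterm
      sl <- labels[zi, , ]
      sl[body] <- k
      labels[zi, , ] <- sl
      vs <- vol[zi, , ]
      vs[body] <- spec$hu_bone
      vol[zi, , ] <- vs
    }
    cursor <- cursor + 2 * half_heights[k] + if (k < n) gaps[k] else 0
  }
  if (any(tabulate(labels[labels > 0], n) == 0)) {
    stop("a vertebral body occupies no voxels; enlarge the grid or bodies",
         call. = FALSE)
  }
  if (spec$noise_sd > 0) {
    vol <- vol + array(rnorm(length(vol), sd = spec$noise_sd), g)
  }

  aff <- phantom_affine(sp)
  volume <- new_volume(vol, sp, aff)
  labelmap <- new_labelmap(labels, sp, aff)
  cents <- lapply(seq_len(n), function(k) {
    idx <- which(labels == k, arr.ind = TRUE) - 1  # 0-based
    w <- voxel_to_world(labelmap, colMeans(idx))
    tibble::tibble(label = k, x_mm = w[1], y_mm = w[2], z_mm = w[3])
  })
  list(volume = volume, labels = labelmap, centroids = do.call(rbind, cents))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantoms as NIfTI image/label pairs with a JSON centroid
#' sidecar each, plus a CSV manifest. Per-sample seeds are derived
#' deterministically from the master seed, so regeneration is byte-stable.
#'
#' @param n Number of samples (>= 1).
#' @param spec A [phantom_spec()]; its `seed` field is ignored in favour of
#'   the derived per-sample seeds.
#' @param seed Master integer seed.
#' @param outdir Output directory (created if missing).
#' @return The manifest tibble (sample_id, image_path, label_path,
#'   centroid_path, seed), also written to `manifest.csv`.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1,
                             outdir = ".") {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- derive_seed(seed, i)
    spec_i <- spec
    spec_i$seed <- s
    ph <- generate_phantom(spec_i)
    id <- sprintf("phantom_%03d", i)
    image_path <- file.path(outdir, paste0(id, "_ct.nii.gz"))
    label_path <- file.path(outdir, paste0(id, "_seg.nii.gz"))
    centroid_path <- file.path(outdir, paste0(id, "_centroids.json"))
    write_volume(ph$volume, image_path)
    write_volume(ph$labels, label_path)
    jsonlite::write_json(ph$centroids, centroid_path, digits = NA)
    rows[[i]] <- tibble::tibble(sample_id = id, image_path = image_path,
                                label_path = label_path,
                                centroid_path = centroid_path, seed = s)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  manifest
}

# Deterministic 31-bit per-sample seed from a master seed.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}
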