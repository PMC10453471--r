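# Shared dense-array utilities: separable resampling, Gaussian smoothing and
# in-plane affine resampling. These back both the preprocessing module and the
# resampling layers inside the networks (where their adjoints provide the
# backward pass: each 1D resampling is a matrix product, so the gradient is
# the transposed matrix applied to the upstream gradient).

# Linear interpolation matrix mapping n_in samples onto n_out samples.
# Voxel centres follow the half-pixel convention: output centre i (0-based)
# sits at input coordinate (i + 0.5) * n_in/n_out - 0.5. Rows sum to one.
interp_matrix <- function(n_in, n_out, method = c("linear", "nearest")) {
  method <- match.arg(method)
  w <- matrix(0, n_out, n_in)
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1)
  if (method == "nearest") {
    idx <- pmin(floor(pos + 0.5), n_in - 1)
    w[cbind(seq_len(n_out), idx + 1)] <- 1
  } else {
    i0 <- pmin(floor(pos), n_in - 2)
    if (n_in == 1L) {
      w[, 1] <- 1
    } else {
      f <- pos - i0
      w[cbind(seq_len(n_out), i0 + 1)] <- w[cbind(seq_len(n_out), i0 + 1)] + (1 - f)
      w[cbind(seq_len(n_out), i0 + 2)] <- w[cbind(seq_len(n_out), i0 + 2)] + f
    }
  }
  w
}

# Apply matrix `m` along axis `axis` of array `x` (any rank).
apply_along_axis <- function(x, m, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  y <- m %*% matrix(xp, nrow = dp[1])
  dim(y) <- c(nrow(m), dp[-1])
  aperm(y, order(perm))
}

# Resize selected axes of an array to the given target extents.
resize_array <- function(x, target, axes = seq_along(target),
                         method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(x)
  for (i in seq_along(axes)) {
    a <- axes[i]
    if (d[a] == target[i]) next
    x <- apply_along_axis(x, interp_matrix(d[a], target[i], method), a)
    d <- dim(x)
  }
  x
}

# Row-normalised Gaussian filter matrix for one axis (sigma in voxels).
# Row normalisation renormalises the kernel at the boundaries, so constant
# signals are exact fixed points.
gaussian_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  offs <- -r:r
  k <- exp(-0.5 * (offs / sigma_vox)^2)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    w[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  w
}

# In-plane affine resampling of the trailing two axes of a 2D or 3D array.
# The inverse map sends each output pixel (about the plane centre) through
# rotation by -angle and scaling by 1/factor back into the input plane.
# Used by both rotation and scaling augmentations so the two compose exactly.
affine_resample_plane <- function(x, angle_deg = 0, factor = 1,
                                  method = c("linear", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(x)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L), factor > 0, is.finite(angle_deg))
  h <- d[nd - 1]; w <- d[nd]
  th <- -angle_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- rep(seq_len(h) - cy, times = w)
  gx <- rep(seq_len(w) - cx, each = h)
  sy <- (cs * gy - sn * gx) / factor + cy
  sx <- (sn * gy + cs * gx) / factor + cx
  sample_plane <- function(p) {
    if (method == "nearest") {
      iy <- round(sy); ix <- round(sx)
      ok <- iy >= 1 & iy <= h & ix >= 1 & ix <= w
      v <- rep(fill, h * w)
      v[ok] <- p[cbind(iy[ok], ix[ok])]
    } else {
      y0 <- floor(sy); x0 <- floor(sx)
      fy <- sy - y0; fx <- sx - x0
      v <- rep(fill, h * w)
      gather <- function(iy, ix) {
        ok <- iy >= 1 & iy <= h & ix >= 1 & ix <= w
        out <- rep(fill, length(iy))
        out[ok] <- p[cbind(iy[ok], ix[ok])]
        out
      }
      inb <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
      v <- (1 - fy) * (1 - fx) * gather(y0, x0) +
           fy * (1 - fx) * gather(y0 + 1, x0) +
           (1 - fy) * fx * gather(y0, x0 + 1) +
           fy * fx * gather(y0 + 1, x0 + 1)
      v[!inb] <- fill
    }
    matrix(v, h, w)
  }
  if (nd == 2L) return(sample_plane(x))
  out <- x
  for (k in seq_len(d[1])) out[k, , ] <- sample_plane(matrix(x[k, , ], h, w))
  out
}

# One-hot encode an integer array along a new trailing class axis.
one_hot <- function(labels, n_classes) {
  d <- dim(labels)
  y <- array(0, c(d, n_classes))
  flat <- as.integer(labels)
  n <- length(flat)
  idx <- seq_len(n) + as.numeric(flat) * n
  y[idx] <- 1
  dim(y) <- c(d, n_classes)
  y
}
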