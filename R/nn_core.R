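# Minimal define-by-construction neural-network framework.
#
# A module is a mutable environment holding parameters (`p`), accumulated
# gradients (`g`), non-trainable buffers (`buf`), child modules and a pair of
# closures implementing the forward pass (which caches whatever the backward
# pass needs) and the backward pass (which accumulates parameter gradients and
# returns the gradient with respect to the module input). Composite blocks
# wire children together explicitly; every backward pass is hand-derived and
# verified against finite differences in the test-suite.
#
# Tensor layout: 2D feature maps are (H, W, C) arrays; 3D feature maps are
# (D, H, W, C) arrays. There is no batch axis — mini-batches are handled by
# gradient accumulation across samples, which keeps normalisation per-sample
# and the whole pipeline deterministic in single-threaded CPU execution.

new_module <- function(type, params = list(), buffers = list(),
                       children = list(), fwd, bwd, extra = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$p <- params
  e$g <- lapply(params, function(x) { x[] <- 0; x })
  e$buf <- buffers
  e$children <- children
  e$fwd_fn <- fwd
  e$bwd_fn <- bwd
  e$frozen <- FALSE
  e$cache <- NULL
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  class(e) <- c(paste0("spineseg_", type), "spineseg_module")
  e
}

#' Run a module forward
#'
#' @param m A network module.
#' @param x Input array in the module's expected layout.
#' @param train Logical; `TRUE` enables training behaviour (dropout active,
#'   normalisation statistics taken from the current sample and folded into
#'   running buffers).
#' @return The module output array.
#' @export
mod_forward <- function(m, x, train = FALSE) m$fwd_fn(m, x, train)

#' Run a module backward
#'
#' Propagates the upstream gradient through the module, accumulating parameter
#' gradients in place. Must follow a forward pass with `train = TRUE`.
#'
#' @param m A network module.
#' @param dy Gradient of the loss with respect to the module output.
#' @return Gradient with respect to the module input.
#' @export
mod_backward <- function(m, dy) m$bwd_fn(m, dy)

child_name <- function(children, i) {
  nm <- names(children)[i]
  if (is.null(nm) || !nzchar(nm)) paste0("ch", i) else nm
}

#' Collect module parameters
#'
#' Returns the trainable parameters of a module (recursively over children)
#' as a flat named list. Frozen modules contribute nothing.
#'
#' @param m A network module.
#' @param prefix Internal name prefix.
#' @return Named list of numeric arrays.
#' @export
mod_params <- function(m, prefix = "") {
  out <- list()
  if (!isTRUE(m$frozen)) {
    for (nm in names(m$p)) out[[paste0(prefix, nm)]] <- m$p[[nm]]
    for (i in seq_along(m$children)) {
      ch <- m$children[[i]]
      out <- c(out, mod_params(ch, paste0(prefix, child_name(m$children, i), ".")))
    }
  }
  out
}

mod_grads <- function(m, prefix = "") {
  out <- list()
  if (!isTRUE(m$frozen)) {
    for (nm in names(m$g)) out[[paste0(prefix, nm)]] <- m$g[[nm]]
    for (i in seq_along(m$children)) {
      ch <- m$children[[i]]
      out <- c(out, mod_grads(ch, paste0(prefix, child_name(m$children, i), ".")))
    }
  }
  out
}

#' Overwrite module parameters from a flat named list
#'
#' @param m A network module.
#' @param values Named list as produced by [mod_params()].
#' @param prefix Internal name prefix.
#' @return The module, invisibly.
#' @export
mod_set_params <- function(m, values, prefix = "") {
  for (nm in names(m$p)) {
    key <- paste0(prefix, nm)
    if (!is.null(values[[key]])) m$p[[nm]] <- values[[key]]
  }
  for (i in seq_along(m$children)) {
    mod_set_params(m$children[[i]], values,
                   paste0(prefix, child_name(m$children, i), "."))
  }
  invisible(m)
}

# Non-trainable buffers (running normalisation statistics), collected and
# restored the same way as parameters; needed for checkpointing.
mod_buffers <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$buf)) out[[paste0(prefix, nm)]] <- m$buf[[nm]]
  for (i in seq_along(m$children)) {
    ch <- m$children[[i]]
    out <- c(out, mod_buffers(ch, paste0(prefix, child_name(m$children, i), ".")))
  }
  out
}

mod_set_buffers <- function(m, values, prefix = "") {
  for (nm in names(m$buf)) {
    key <- paste0(prefix, nm)
    if (!is.null(values[[key]])) m$buf[[nm]] <- values[[key]]
  }
  for (i in seq_along(m$children)) {
    mod_set_buffers(m$children[[i]], values,
                    paste0(prefix, child_name(m$children, i), "."))
  }
  invisible(m)
}

mod_zero_grads <- function(m) {
  m$g <- lapply(m$g, function(x) { x[] <- 0; x })
  for (ch in m$children) mod_zero_grads(ch)
  invisible(m)
}

#' Count trainable parameters
#'
#' Number of independently trainable scalars in a model; frozen sub-modules
#' are excluded, non-trainable buffers (running normalisation statistics)
#' never count. The count does not depend on training/evaluation mode.
#'
#' @param model A network module.
#' @return Integer scalar.
#' @export
count_parameters <- function(model) {
  sum(vapply(mod_params(model), length, numeric(1)))
}

acc_grad <- function(m, nm, d) m$g[[nm]] <- m$g[[nm]] + d

# Snapshot / restore the mutable forward state (caches and per-call fields)
# of a module tree. Needed when one module is applied to many inputs inside
# a single forward pass (weight sharing across slices) and the backward pass
# must revisit each application with the matching cache. Parameters,
# gradients and running buffers are deliberately not part of the snapshot.
MOD_STATE_SKIP <- c("p", "g", "buf", "children", "fwd_fn", "bwd_fn",
                    "type", "frozen")

mod_save_state <- function(m) {
  nms <- setdiff(ls(m, all.names = TRUE), MOD_STATE_SKIP)
  list(fields = mget(nms, envir = m),
       children = lapply(m$children, mod_save_state))
}

mod_restore_state <- function(m, st) {
  for (nm in names(st$fields)) assign(nm, st$fields[[nm]], envir = m)
  for (i in seq_along(m$children)) {
    mod_restore_state(m$children[[i]], st$children[[i]])
  }
  invisible(m)
}

# ---- primitive layers -------------------------------------------------------

ensure_chan <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1, 1)
  x
}

# He-style initialisation for a fan_in x cout weight matrix.
init_w <- function(fan_in, cout, gain = 2) {
  matrix(rnorm(fan_in * cout, sd = sqrt(gain / fan_in)), fan_in, cout)
}

layer_conv2d <- function(cin, cout, k = 3, stride = 1, dilation = 1) {
  new_module(
    "conv2d",
    params = list(w = init_w(k * k * cin, cout), b = rep(0, cout)),
    fwd = function(m, x, train) {
      m$cache <- x
      cpp_conv2d_fwd(x, m$p$w, m$p$b, m$k, m$k, m$stride, m$dilation)
    },
    bwd = function(m, dy) {
      r <- cpp_conv2d_bwd(m$cache, m$p$w, dy, m$k, m$k, m$stride, m$dilation)
      acc_grad(m, "w", r$dw)
      acc_grad(m, "b", as.numeric(r$db))
      r$dx
    },
    extra = list(k = k, stride = stride, dilation = dilation,
                 cin = cin, cout = cout)
  )
}

layer_dwconv2d <- function(channels, k = 3, stride = 1, dilation = 1) {
  new_module(
    "dwconv2d",
    params = list(w = matrix(rnorm(k * k * channels, sd = sqrt(2 / (k * k))),
                             k * k, channels),
                  b = rep(0, channels)),
    fwd = function(m, x, train) {
      m$cache <- x
      cpp_dwconv2d_fwd(x, m$p$w, m$p$b, m$k, m$stride, m$dilation)
    },
    bwd = function(m, dy) {
      r <- cpp_dwconv2d_bwd(m$cache, m$p$w, dy, m$k, m$stride, m$dilation)
      acc_grad(m, "w", r$dw)
      acc_grad(m, "b", as.numeric(r$db))
      r$dx
    },
    extra = list(k = k, stride = stride, dilation = dilation)
  )
}

layer_conv3d <- function(cin, cout, k = 3) {
  new_module(
    "conv3d",
    params = list(w = init_w(k^3 * cin, cout), b = rep(0, cout)),
    fwd = function(m, x, train) {
      m$cache <- x
      cpp_conv3d_fwd(x, m$p$w, m$p$b, m$k)
    },
    bwd = function(m, dy) {
      r <- cpp_conv3d_bwd(m$cache, m$p$w, dy, m$k)
      acc_grad(m, "w", r$dw)
      acc_grad(m, "b", as.numeric(r$db))
      r$dx
    },
    extra = list(k = k)
  )
}

# Channel normalisation computed over the spatial extent of the current
# sample (instance-style), identically in training and evaluation. With
# batch-free gradient accumulation this keeps the normalisation statistics a
# pure function of the input, so evaluation sees exactly the distribution
# training saw and the whole network stays deterministic.
layer_norm_ch <- function(channels, eps = 1e-5) {
  new_module(
    "norm",
    params = list(gamma = rep(1, channels), beta = rep(0, channels)),
    fwd = function(m, x, train) {
      d <- dim(x)
      cdim <- d[length(d)]
      xm <- matrix(x, ncol = cdim)
      mu <- colMeans(xm)
      v <- colMeans(xm^2) - mu^2
      v[v < 0] <- 0
      invstd <- 1 / sqrt(v + m$eps)
      xhat <- (xm - rep(mu, each = nrow(xm))) * rep(invstd, each = nrow(xm))
      y <- xhat * rep(m$p$gamma, each = nrow(xm)) +
        rep(m$p$beta, each = nrow(xm))
      m$cache <- list(xhat = xhat, invstd = invstd, dims = d)
      dim(y) <- d
      y
    },
    bwd = function(m, dy) {
      cc <- m$cache
      n <- nrow(cc$xhat)
      dym <- matrix(dy, ncol = length(m$p$gamma))
      dgamma <- colSums(dym * cc$xhat)
      dbeta <- colSums(dym)
      acc_grad(m, "gamma", dgamma)
      acc_grad(m, "beta", dbeta)
      dxhat <- dym * rep(m$p$gamma, each = n)
      dx <- (dxhat - rep(colMeans(dxhat), each = n) -
               cc$xhat * rep(colMeans(dxhat * cc$xhat), each = n)) *
        rep(cc$invstd, each = n)
      dim(dx) <- cc$dims
      dx
    },
    extra = list(eps = eps)
  )
}

layer_relu <- function() {
  new_module(
    "relu", fwd = function(m, x, train) {
      m$cache <- x > 0
      x * m$cache
    },
    bwd = function(m, dy) dy * m$cache
  )
}

layer_sigmoid <- function() {
  new_module(
    "sigmoid", fwd = function(m, x, train) {
      y <- 1 / (1 + exp(-x))
      m$cache <- y
      y
    },
    bwd = function(m, dy) dy * m$cache * (1 - m$cache)
  )
}

layer_dropout <- function(p) {
  new_module(
    "dropout", fwd = function(m, x, train) {
      if (!train || m$prob <= 0) {
        m$cache <- NULL
        return(x)
      }
      mask <- array((runif(length(x)) >= m$prob) / (1 - m$prob), dim(x))
      m$cache <- mask
      x * mask
    },
    bwd = function(m, dy) if (is.null(m$cache)) dy else dy * m$cache,
    extra = list(prob = p)
  )
}

# 2x2 max pooling with stride 2 (2D maps; extents must be even).
# Ties resolve to the first window position in scan order.
layer_maxpool2 <- function() {
  new_module(
    "maxpool2",
    fwd = function(m, x, train) {
      d <- dim(x)
      stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
      i1 <- seq(1, d[1], 2); i2 <- seq(1, d[2], 2)
      sub <- list(x[i1, i2, , drop = FALSE], x[i1 + 1, i2, , drop = FALSE],
                  x[i1, i2 + 1, , drop = FALSE], x[i1 + 1, i2 + 1, , drop = FALSE])
      y <- sub[[1]]; which_max <- array(1L, dim(y))
      for (k in 2:4) {
        upd <- sub[[k]] > y
        y[upd] <- sub[[k]][upd]
        which_max[upd] <- k
      }
      m$cache <- list(which = which_max, dims = d)
      y
    },
    bwd = function(m, dy) {
      cc <- m$cache
      dx <- array(0, cc$dims)
      i1 <- seq(1, cc$dims[1], 2); i2 <- seq(1, cc$dims[2], 2)
      for (k in 1:4) {
        msk <- cc$which == k
        g <- dy * msk
        r1 <- i1 + (k - 1) %% 2
        r2 <- i2 + (k - 1) %/% 2
        dx[r1, r2, ] <- dx[r1, r2, , drop = FALSE] + g
      }
      dx
    }
  )
}

# Nearest-neighbour 2x upsampling of 2D maps.
layer_upsample2 <- function() {
  new_module(
    "upsample2",
    fwd = function(m, x, train) {
      d <- dim(x)
      m$cache <- d
      x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
    },
    bwd = function(m, dy) {
      d <- m$cache
      i1 <- seq(1, 2 * d[1], 2); i2 <- seq(1, 2 * d[2], 2)
      dy[i1, i2, , drop = FALSE] + dy[i1 + 1, i2, , drop = FALSE] +
        dy[i1, i2 + 1, , drop = FALSE] + dy[i1 + 1, i2 + 1, , drop = FALSE]
    }
  )
}

# Trilinear resampling of the three leading (spatial) axes of a (D,H,W,C)
# array to fixed target extents; the backward pass applies the transposed
# interpolation matrices.
layer_resize3d <- function(target) {
  new_module(
    "resize3d",
    fwd = function(m, x, train) {
      d <- dim(x)
      m$cache <- d
      m$mats <- lapply(1:3, function(a) {
        if (d[a] == m$target[a]) NULL else interp_matrix(d[a], m$target[a])
      })
      for (a in 1:3) if (!is.null(m$mats[[a]])) {
        x <- apply_along_axis(x, m$mats[[a]], a)
      }
      x
    },
    bwd = function(m, dy) {
      for (a in 3:1) if (!is.null(m$mats[[a]])) {
        dy <- apply_along_axis(dy, t(m$mats[[a]]), a)
      }
      dy
    },
    extra = list(target = target)
  )
}

seq_module <- function(children, type = "seq") {
  new_module(
    type, children = children,
    fwd = function(m, x, train) {
      for (ch in m$children) x <- mod_forward(ch, x, train)
      x
    },
    bwd = function(m, dy) {
      for (ch in rev(m$children)) dy <- mod_backward(ch, dy)
      dy
    }
  )
}

# conv -> channel-norm -> optional relu, the standard unit used throughout.
conv_norm_act <- function(cin, cout, k = 3, stride = 1, dilation = 1,
                          act = TRUE, norm = TRUE) {
  ch <- list(conv = layer_conv2d(cin, cout, k, stride, dilation))
  if (norm) ch$norm <- layer_norm_ch(cout)
  if (act) ch$act <- layer_relu()
  seq_module(ch, "convunit")
}

conv3d_norm_act <- function(cin, cout, k = 3, act = TRUE, norm = TRUE) {
  ch <- list(conv = layer_conv3d(cin, cout, k))
  if (norm) ch$norm <- layer_norm_ch(cout)
  if (act) ch$act <- layer_relu()
  seq_module(ch, "convunit3d")
}

# ---- softmax and losses -----------------------------------------------------

# Numerically stable softmax over the trailing (class) axis.
softmax_channels <- function(x) {
  d <- dim(x)
  cdim <- d[length(d)]
  xm <- matrix(x, ncol = cdim)
  xm <- xm - apply(xm, 1, max)
  e <- exp(xm)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

#' Composite segmentation loss
#'
#' Weighted sum of a soft-Dice term (one minus the mean soft Dice over
#' classes) and mean per-voxel cross-entropy, computed on class probabilities.
#' The loss is nonnegative and approaches zero as the prediction approaches
#' the one-hot truth.
#'
#' @param prob Array of class probabilities with trailing class axis.
#' @param truth Integer array of class labels in `0..C-1`, same spatial shape.
#' @param weights Length-2 numeric: weights of the Dice and cross-entropy
#'   terms (default `c(0.5, 0.5)`).
#' @return Scalar loss, with attributes `dice_term` and `ce_term`.
#' @export
segmentation_loss <- function(prob, truth, weights = c(0.5, 0.5)) {
  d <- dim(prob)
  n_classes <- d[length(d)]
  if (!identical(dim(truth), d[-length(d)]) &&
      !(is.null(dim(truth)) && length(truth) == prod(d[-length(d)]))) {
    stop("probability and truth shapes are misaligned", call. = FALSE)
  }
  y <- one_hot(truth, n_classes)
  lt <- loss_terms(prob, y)
  out <- weights[1] * lt$dice + weights[2] * lt$ce
  attr(out, "dice_term") <- lt$dice
  attr(out, "ce_term") <- lt$ce
  out
}

# Inverse-frequency class weights for the cross-entropy term, normalised so
# that the weighted mean over voxels of the sample equals one.
balanced_class_weights <- function(ym) {
  freq <- colMeans(ym)
  w <- 1 / pmax(freq, 1e-4)
  w / sum(w * freq)
}

loss_terms <- function(prob, y, eps = 1e-6, class_weights = NULL) {
  d <- dim(prob)
  cdim <- d[length(d)]
  pm <- matrix(prob, ncol = cdim)
  ym <- matrix(y, ncol = cdim)
  inter <- colSums(pm * ym)
  psum <- colSums(pm)
  ysum <- colSums(ym)
  dice_c <- (2 * inter + eps) / (psum + ysum + eps)
  cw <- if (identical(class_weights, "balanced")) balanced_class_weights(ym)
        else rep(1, cdim)
  ce <- -sum((ym * log(pmax(pm, 1e-12))) %*% cw) / nrow(pm)
  list(dice = 1 - mean(dice_c), ce = ce, cw = cw,
       inter = inter, psum = psum, ysum = ysum, dice_c = dice_c)
}

# Loss and gradient with respect to the *logits* feeding the softmax.
seg_loss_grad <- function(logits, truth, weights = c(0.5, 0.5), eps = 1e-6,
                          class_weights = NULL) {
  d <- dim(logits)
  cdim <- d[length(d)]
  prob <- softmax_channels(logits)
  y <- one_hot(truth, cdim)
  lt <- loss_terms(prob, y, eps, class_weights)
  n <- prod(d[-length(d)])
  pm <- matrix(prob, ncol = cdim)
  ym <- matrix(y, ncol = cdim)
  # d(1 - mean dice)/dp, per class then per voxel
  denom <- lt$psum + lt$ysum + eps
  num <- 2 * lt$inter + eps
  ddice_dp <- -(2 * outer(rep(1, n), 1 / denom) * ym -
                  outer(rep(1, n), num / denom^2)) / cdim
  dce_dp <- -(ym * rep(lt$cw, each = n)) / pmax(pm, 1e-12) / n
  dLdp <- weights[1] * ddice_dp + weights[2] * dce_dp
  # chain through softmax: dz = p * (dLdp - rowSums(dLdp * p))
  dz <- pm * (dLdp - rowSums(dLdp * pm))
  dim(dz) <- d
  loss <- weights[1] * lt$dice + weights[2] * lt$ce
  list(loss = loss, grad = dz, dice_term = lt$dice, ce_term = lt$ce,
       prob = prob)
}

# ---- optimiser --------------------------------------------------------------

# Adam with optional gradient scaling (for accumulation over a mini-batch).
make_adam <- function(model, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$model <- model
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0
  p0 <- mod_params(model)
  e$m <- lapply(p0, function(x) { x[] <- 0; x })
  e$v <- lapply(p0, function(x) { x[] <- 0; x })
  class(e) <- "spineseg_adam"
  e
}

adam_step <- function(opt, grad_scale = 1) {
  p <- mod_params(opt$model)
  g <- mod_grads(opt$model)
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(p)) {
    gi <- g[[nm]] * grad_scale
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * gi
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * gi^2
    p[[nm]] <- p[[nm]] - opt$lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  mod_set_params(opt$model, p)
  mod_zero_grads(opt$model)
  invisible(opt)
}
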