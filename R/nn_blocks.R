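# Reusable computational blocks.
#
# All blocks preserve spatial extents except the inverted residual bottleneck
# with stride 2, which halves them (ceiling semantics). Channel normalisation
# after every convolution is on by default and counted in parameter totals;
# it can be disabled (`norm = FALSE`) to obtain the bare convolutional block.

#' Residual block
#'
#' Two 3x3 convolution units plus a shortcut: identity when the channel
#' counts match, otherwise a 1x1 projection. The block output is
#' `relu(conv_path(x) + shortcut(x))` and spatial extents are preserved.
#'
#' @param cin,cout Input/output channel counts.
#' @param norm Include channel normalisation after each convolution.
#' @return A network module.
#' @export
nn_residual_block <- function(cin, cout, norm = TRUE) {
  ch <- list(
    unit1 = conv_norm_act(cin, cout, norm = norm),
    conv2 = layer_conv2d(cout, cout, 3)
  )
  if (norm) ch$norm2 <- layer_norm_ch(cout)
  if (cin != cout) ch$proj <- layer_conv2d(cin, cout, 1)
  ch$act <- layer_relu()
  new_module(
    "residual_block", children = ch,
    fwd = function(m, x, train) {
      h <- mod_forward(m$children$unit1, x, train)
      h <- mod_forward(m$children$conv2, h, train)
      if (!is.null(m$children$norm2)) h <- mod_forward(m$children$norm2, h, train)
      s <- if (is.null(m$children$proj)) x else mod_forward(m$children$proj, x, train)
      mod_forward(m$children$act, h + s, train)
    },
    bwd = function(m, dy) {
      d <- mod_backward(m$children$act, dy)
      dh <- d
      if (!is.null(m$children$norm2)) dh <- mod_backward(m$children$norm2, dh)
      dh <- mod_backward(m$children$conv2, dh)
      dx <- mod_backward(m$children$unit1, dh)
      ds <- if (is.null(m$children$proj)) d else mod_backward(m$children$proj, d)
      dx + ds
    }
  )
}

#' Attention gate for skip connections
#'
#' Per spatial position: a query is projected from the decoder-side gating
#' signal, a key and a value from the encoder skip. The raw score is the
#' query-key dot product, the attention weight is its logistic transform
#' (strictly inside (0,1)), and the output is the weight times the value.
#' If the gate extents differ from the skip extents the gate is first
#' resampled (nearest-neighbour) to match.
#'
#' @param skip_c,gate_c Channel counts of the skip and gate inputs.
#' @param inter_c Internal projection width (defaults to half the skip width).
#' @return A module whose forward takes `list(skip =, gate =)` and returns a
#'   map with the skip's spatial extents and channels.
#' @export
nn_attention_gate <- function(skip_c, gate_c, inter_c = max(1L, skip_c %/% 2L)) {
  ch <- list(
    proj_q = layer_conv2d(gate_c, inter_c, 1),
    proj_k = layer_conv2d(skip_c, inter_c, 1),
    proj_v = layer_conv2d(skip_c, skip_c, 1)
  )
  new_module(
    "attention_gate", children = ch,
    fwd = function(m, x, train) {
      skip <- x$skip; gate <- x$gate
      ds <- dim(skip); dg <- dim(gate)
      m$resized <- !identical(ds[1:2], dg[1:2])
      if (m$resized) {
        if (any(ds[1:2] %% dg[1:2] != 0) && any(dg[1:2] %% ds[1:2] != 0)) {
          stop("attention gate: incompatible skip/gate extents", call. = FALSE)
        }
        m$gate_dims <- dg
        gate <- resize_array(gate, ds[1:2], axes = 1:2, method = "nearest")
      }
      q <- mod_forward(m$children$proj_q, gate, train)
      k <- mod_forward(m$children$proj_k, skip, train)
      v <- mod_forward(m$children$proj_v, skip, train)
      # dot product per position, scaled by 1/sqrt(d) and clamped so the
      # logistic stays strictly inside (0, 1) in double precision
      e <- rowSums(matrix(q * k, ncol = dim(q)[3])) / sqrt(dim(q)[3])
      dim(e) <- dim(q)[1:2]
      sat <- abs(e) > 30
      e[e > 30] <- 30
      e[e < -30] <- -30
      alpha <- 1 / (1 + exp(-e))
      m$cache <- list(q = q, k = k, v = v, alpha = alpha, sat = sat)
      av <- array(rep(alpha, dim(v)[3]), dim(v))
      av * v
    },
    bwd = function(m, dy) {
      cc <- m$cache
      nc <- dim(cc$v)[3]
      aexp <- array(rep(cc$alpha, nc), dim(cc$v))
      dv <- dy * aexp
      dalpha <- rowSums(matrix(dy * cc$v, ncol = nc))
      dim(dalpha) <- dim(cc$alpha)
      de <- dalpha * cc$alpha * (1 - cc$alpha)
      de[cc$sat] <- 0
      ni <- dim(cc$q)[3]
      de <- de / sqrt(ni)
      deexp <- array(rep(de, ni), dim(cc$q))
      dq <- deexp * cc$k
      dk <- deexp * cc$q
      dskip <- mod_backward(m$children$proj_k, dk) +
        mod_backward(m$children$proj_v, dv)
      dgate <- mod_backward(m$children$proj_q, dq)
      if (isTRUE(m$resized)) {
        dgate <- resize_adjoint_nearest(dgate, m$gate_dims)
      }
      list(skip = dskip, gate = dgate)
    }
  )
}

# Adjoint of nearest-neighbour 2D resize used by the attention gate.
resize_adjoint_nearest <- function(dy, orig_dims) {
  for (a in 1:2) {
    w <- interp_matrix(orig_dims[a], dim(dy)[a], "nearest")
    dy <- apply_along_axis(dy, t(w), a)
  }
  dy
}

#' Atrous spatial pyramid pooling (ASPP)
#'
#' Parallel 3x3 dilated convolutions, one per rate, plus a 1x1 branch;
#' branch outputs are concatenated channel-wise and projected to
#' `out_channels` with a 1x1 convolution. Spatial extents are preserved.
#'
#' @param cin Input channels.
#' @param rates Positive dilation rates, one branch each.
#' @param out_channels Output channels after projection.
#' @param branch_width Channels per branch (default `out_channels`).
#' @param norm Include channel normalisation.
#' @return A network module.
#' @export
nn_aspp <- function(cin, rates = c(1, 2, 4, 8), out_channels = cin,
                    branch_width = out_channels, norm = TRUE) {
  if (length(rates) == 0) stop("aspp: rates must be non-empty", call. = FALSE)
  if (any(rates < 1)) stop("aspp: rates must be positive", call. = FALSE)
  branches <- lapply(rates, function(r) {
    conv_norm_act(cin, branch_width, k = 3, dilation = r, norm = norm)
  })
  names(branches) <- paste0("rate", rates)
  branches$point <- conv_norm_act(cin, branch_width, k = 1, norm = norm)
  ch <- list(
    proj = conv_norm_act((length(rates) + 1) * branch_width, out_channels,
                         k = 1, norm = norm)
  )
  ch <- c(branches, ch)
  new_module(
    "aspp", children = ch,
    fwd = function(m, x, train) {
      bs <- lapply(m$children[setdiff(names(m$children), "proj")],
                   function(b) mod_forward(b, x, train))
      m$widths <- vapply(bs, function(b) dim(b)[3], numeric(1))
      cat_ <- do.call(abind3, bs)
      mod_forward(m$children$proj, cat_, train)
    },
    bwd = function(m, dy) {
      dcat <- mod_backward(m$children$proj, dy)
      dx <- 0
      off <- 0
      nms <- setdiff(names(m$children), "proj")
      for (i in seq_along(nms)) {
        w <- m$widths[i]
        dbi <- dcat[, , off + seq_len(w), drop = FALSE]
        dx <- dx + mod_backward(m$children[[nms[i]]], dbi)
        off <- off + w
      }
      dx
    }
  )
}

# Channel-axis concatenation of (H, W, C) arrays.
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  ctot <- sum(vapply(xs, function(x) dim(x)[3], numeric(1)))
  out <- array(0, c(d[1], d[2], ctot))
  off <- 0
  for (x in xs) {
    w <- dim(x)[3]
    out[, , off + seq_len(w)] <- x
    off <- off + w
  }
  out
}

abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  ctot <- sum(vapply(xs, function(x) dim(x)[4], numeric(1)))
  out <- array(0, c(d[1:3], ctot))
  off <- 0
  for (x in xs) {
    w <- dim(x)[4]
    out[, , , off + seq_len(w)] <- x
    off <- off + w
  }
  out
}

#' Cascaded hierarchical ASPP (CHASPP)
#'
#' Two-level hierarchy: a root 3x3 dilated convolution feeds three parallel
#' 3x3 dilated branches; branch outputs are concatenated and projected to
#' `out_channels`. Composing root and branch dilations densifies the sampling
#' inside the composed receptive field relative to a single dilated kernel.
#'
#' @param cin Input channels.
#' @param root_rate Dilation of the root convolution.
#' @param branch_rates Three positive dilation rates.
#' @param out_channels Output channels.
#' @param width Internal width (root and branch channels; default
#'   `out_channels`).
#' @param norm Include channel normalisation.
#' @return A network module.
#' @export
nn_chaspp <- function(cin, root_rate = 2, branch_rates = c(1, 2, 3),
                      out_channels = cin, width = out_channels, norm = TRUE) {
  if (any(c(root_rate, branch_rates) < 1)) {
    stop("chaspp: dilation rates must be positive", call. = FALSE)
  }
  branches <- lapply(branch_rates, function(r) {
    conv_norm_act(width, width, k = 3, dilation = r, norm = norm)
  })
  names(branches) <- paste0("branch", seq_along(branch_rates))
  ch <- c(list(root = conv_norm_act(cin, width, k = 3, dilation = root_rate,
                                    norm = norm)),
          branches,
          list(proj = conv_norm_act(length(branch_rates) * width, out_channels,
                                    k = 1, norm = norm)))
  new_module(
    "chaspp", children = ch,
    fwd = function(m, x, train) {
      r <- mod_forward(m$children$root, x, train)
      nms <- grep("^branch", names(m$children), value = TRUE)
      bs <- lapply(m$children[nms], function(b) mod_forward(b, r, train))
      m$widths <- vapply(bs, function(b) dim(b)[3], numeric(1))
      mod_forward(m$children$proj, do.call(abind3, bs), train)
    },
    bwd = function(m, dy) {
      dcat <- mod_backward(m$children$proj, dy)
      nms <- grep("^branch", names(m$children), value = TRUE)
      dr <- 0
      off <- 0
      for (i in seq_along(nms)) {
        w <- m$widths[i]
        dr <- dr + mod_backward(m$children[[nms[i]]],
                                dcat[, , off + seq_len(w), drop = FALSE])
        off <- off + w
      }
      mod_backward(m$children$root, dr)
    }
  )
}

#' Inverted residual bottleneck
#'
#' The mobile bottleneck unit: 1x1 expansion to `t * cin` channels, 3x3
#' depthwise convolution (stride `a` on the first repeat only), then a linear
#' 1x1 projection to `c` channels. A residual shortcut is added whenever the
#' stride is 1 and input and output channels agree. Repeated `n` times.
#'
#' @param cin Input channels.
#' @param spec List with fields `t` (expansion), `c` (output channels),
#'   `n` (repeats), `a` (stride, 1 or 2), as in the standard mobile
#'   architecture table.
#' @param norm Include channel normalisation.
#' @return A network module.
#' @export
nn_inverted_residual <- function(cin, spec, norm = TRUE) {
  stopifnot(spec$t >= 1, spec$c >= 1, spec$n >= 1, spec$a %in% c(1, 2))
  reps <- list()
  cur <- cin
  for (i in seq_len(spec$n)) {
    stride <- if (i == 1) spec$a else 1
    hid <- cur * spec$t
    unit <- list(
      expand = if (spec$t > 1) conv_norm_act(cur, hid, k = 1, norm = norm) else NULL,
      dw = layer_dwconv2d(hid, k = 3, stride = stride)
    )
    if (norm) unit$dwnorm <- layer_norm_ch(hid)
    unit$dwact <- layer_relu()
    unit$proj <- layer_conv2d(hid, spec$c, 1)
    if (norm) unit$projnorm <- layer_norm_ch(spec$c)
    unit <- unit[!vapply(unit, is.null, logical(1))]
    use_shortcut <- stride == 1 && cur == spec$c
    reps[[i]] <- new_module(
      "invres_unit", children = unit,
      fwd = function(m, x, train) {
        h <- x
        if (!is.null(m$children$expand)) h <- mod_forward(m$children$expand, h, train)
        h <- mod_forward(m$children$dw, h, train)
        if (!is.null(m$children$dwnorm)) h <- mod_forward(m$children$dwnorm, h, train)
        h <- mod_forward(m$children$dwact, h, train)
        h <- mod_forward(m$children$proj, h, train)
        if (!is.null(m$children$projnorm)) h <- mod_forward(m$children$projnorm, h, train)
        if (m$shortcut) h + x else h
      },
      bwd = function(m, dy) {
        dh <- dy
        if (!is.null(m$children$projnorm)) dh <- mod_backward(m$children$projnorm, dh)
        dh <- mod_backward(m$children$proj, dh)
        dh <- mod_backward(m$children$dwact, dh)
        if (!is.null(m$children$dwnorm)) dh <- mod_backward(m$children$dwnorm, dh)
        dh <- mod_backward(m$children$dw, dh)
        if (!is.null(m$children$expand)) dh <- mod_backward(m$children$expand, dh)
        if (m$shortcut) dh + dy else dh
      },
      extra = list(shortcut = use_shortcut)
    )
    cur <- spec$c
  }
  names(reps) <- paste0("rep", seq_along(reps))
  seq_module(reps, "inverted_residual")
}
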