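# Shared fixtures: all data are generated in code at test time.

# A small, fast phantom used across module tests.
tiny_phantom_spec <- function(seed = 7, noise_sd = 25) {
  phantom_spec(grid = c(32, 48, 48), spacing = c(2, 2, 2), n_vertebrae = 3,
               body_radius_mm = c(7, 9), disc_gap_mm = c(3, 4),
               curvature_amp_mm = 4, noise_sd = noise_sd, seed = seed)
}

# Central finite-difference gradient of f at x (vector in, scalar out).
numeric_gradient <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Gradient check for the attention gate (list-structured input).
expect_module_gradients_attention <- function(m, skip, gate, tol = 1e-6) {
  xin <- list(skip = skip, gate = gate)
  y <- spineseg:::mod_forward(m, xin, train = TRUE)
  dy <- array(rnorm(length(y)), dim(y))
  spineseg:::mod_zero_grads(m)
  y <- spineseg:::mod_forward(m, xin, train = TRUE)
  dx <- spineseg:::mod_backward(m, dy)
  f <- function(sv, gv) {
    sum(spineseg:::mod_forward(m, list(skip = array(sv, dim(skip)),
                                       gate = array(gv, dim(gate))),
                               train = TRUE) * dy)
  }
  ns <- numeric_gradient(function(v) f(v, as.numeric(gate)), as.numeric(skip))
  ng <- numeric_gradient(function(v) f(as.numeric(skip), v), as.numeric(gate))
  expect_lt(max(abs(ns - as.numeric(dx$skip))), tol)
  expect_lt(max(abs(ng - as.numeric(dx$gate))), tol)
  invisible(NULL)
}

# Check a module's input gradient and all parameter gradients against finite
# differences under a fixed upstream gradient.
expect_module_gradients <- function(m, xdim, tol = 1e-6, param_tol = tol) {
  x <- array(rnorm(prod(xdim)), xdim)
  y <- spineseg:::mod_forward(m, x, train = TRUE)
  dy <- array(rnorm(length(y)), dim(y))
  spineseg:::mod_zero_grads(m)
  y <- spineseg:::mod_forward(m, x, train = TRUE)
  dx <- spineseg:::mod_backward(m, dy)
  f <- function(xv) {
    sum(spineseg:::mod_forward(m, array(xv, xdim), train = TRUE) * dy)
  }
  ng <- numeric_gradient(f, as.numeric(x))
  expect_lt(max(abs(ng - as.numeric(dx))), tol)
  p <- mod_params(m)
  g <- spineseg:::mod_grads(m)
  for (nm in names(p)) {
    fp <- function(v) {
      p2 <- p
      p2[[nm]][] <- v
      mod_set_params(m, p2)
      out <- sum(spineseg:::mod_forward(m, x, train = TRUE) * dy)
      mod_set_params(m, p)
      out
    }
    npg <- numeric_gradient(fp, as.numeric(p[[nm]]))
    expect_lt(max(abs(npg - as.numeric(g[[nm]]))), param_tol)
  }
  invisible(NULL)
}
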