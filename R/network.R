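#' Velocity network configuration
#'
#' Architecture hyperparameters of the stationary-velocity-field network
#' F = FA-NN -> FPE -> DF-NN. Defaults are the full-size registration
#' configuration: a feature-augmentation net with 3 layers of width 64, a
#' Fourier positional encoder with `n_e = 3` octaves (output width
#' `(2 n_e + 1) * fa_width` = 448), and a diffeomorphic-flow net with 5
#' layers of width 256 plus a linear 3-output head. All hidden layers use
#' Leaky-ReLU with slope 0.2. The latent dimension `n_z` must be divisible
#' by `g_z^3`.
#'
#' @param fa_layers,fa_width FA-NN depth and width.
#' @param df_layers,df_width DF-NN depth and width.
#' @param n_e number of Fourier octaves.
#' @param leaky_slope negative slope of the Leaky-ReLU.
#' @param n_z latent code dimension.
#' @param g_z latent grid side (position-aware conditioning).
#' @param K number of integration steps of the flow ODE.
#' @return a `net_config` list; `code_channels` holds `n_z / g_z^3`.
#' @export
netConfig <- function(fa_layers = 3L, fa_width = 64L, df_layers = 5L,
                      df_width = 256L, n_e = 3L, leaky_slope = 0.2,
                      n_z = 256L, g_z = 2L, K = 10L) {
  if (n_z %% g_z^3 != 0L)
    stop("n_z must be divisible by g_z^3")
  structure(list(fa_layers = as.integer(fa_layers),
                 fa_width = as.integer(fa_width),
                 df_layers = as.integer(df_layers),
                 df_width = as.integer(df_width),
                 n_e = as.integer(n_e), leaky_slope = leaky_slope,
                 n_z = as.integer(n_z), g_z = as.integer(g_z),
                 K = as.integer(K),
                 code_channels = as.integer(n_z / g_z^3),
                 fpe_width = as.integer((2L * n_e + 1L) * fa_width)),
            class = "net_config")
}

#' Reshape a latent code onto the conditioning grid (and back)
#'
#' Deterministic row-major reshape of a length-`n_z` code into a
#' `g_z x g_z x g_z x (n_z / g_z^3)` grid, stored as a `g_z^3 x channels`
#' matrix whose row `r` holds the channel vector of grid node
#' `(i, j, k)` with `r - 1 = (i g_z + j) g_z + k` (0-based, k fastest).
#' Node `(i, j, k)` sits at coordinates `(i, j, k) / (g_z - 1)`, i.e. at the
#' corners of the unit cube for `g_z = 2`.
#'
#' @param z numeric code of length `n_z`.
#' @param g_z grid side.
#' @return `reshapeCode`: a `g_z^3 x channels` matrix with attribute `g_z`;
#'   `unreshapeCode`: the original code vector.
#' @export
reshapeCode <- function(z, g_z = 2L) {
  n_z <- length(z)
  if (n_z %% g_z^3 != 0L) stop("length(z) must be divisible by g_z^3")
  grid <- matrix(as.numeric(z), nrow = g_z^3, byrow = TRUE)
  attr(grid, "g_z") <- as.integer(g_z)
  grid
}

#' @rdname reshapeCode
#' @param grid a grid matrix from `reshapeCode`.
#' @export
unreshapeCode <- function(grid) as.vector(t(grid))

# Trilinear interpolation of the code grid at clamped points.
# Returns Zbar (P x C) and the cache needed for the backward pass.
lerpForward <- function(x, grid) {
  g <- attr(grid, "g_z")
  p <- nrow(x)
  cc <- ncol(grid)
  if (g == 1L) {
    zbar <- matrix(grid[1L, ], p, cc, byrow = TRUE)
    return(list(zbar = zbar, g = g))
  }
  xc <- pmin(pmax(x, 0), 1)
  pos <- xc * (g - 1L)
  i0 <- pmin(floor(pos), g - 2L)        # P x 3 lower cell corner (0-based)
  fr <- pos - i0                        # P x 3 in [0,1]
  # corner weights / indices: corner c encoded by bits (bx, by, bz)
  wt <- matrix(0, p, 8L)
  idx <- matrix(0L, p, 8L)
  dw <- array(0, c(p, 8L, 3L))          # d wt / d x (before clamping)
  inside <- (x >= 0 & x <= 1) * (g - 1L) # clamp kills the derivative
  for (c0 in 0:7) {
    bx <- c0 %% 2L; by <- (c0 %/% 2L) %% 2L; bz <- c0 %/% 4L
    wx <- if (bx) fr[, 1L] else 1 - fr[, 1L]
    wy <- if (by) fr[, 2L] else 1 - fr[, 2L]
    wz <- if (bz) fr[, 3L] else 1 - fr[, 3L]
    wt[, c0 + 1L] <- wx * wy * wz
    sx <- if (bx) 1 else -1; sy <- if (by) 1 else -1
    sz <- if (bz) 1 else -1
    dw[, c0 + 1L, 1L] <- sx * wy * wz * inside[, 1L]
    dw[, c0 + 1L, 2L] <- wx * sy * wz * inside[, 2L]
    dw[, c0 + 1L, 3L] <- wx * wy * sz * inside[, 3L]
    idx[, c0 + 1L] <- ((i0[, 1L] + bx) * g + (i0[, 2L] + by)) * g +
      (i0[, 3L] + bz) + 1L
  }
  zbar <- matrix(0, p, cc)
  for (c0 in 1:8)
    zbar <- zbar + wt[, c0] * grid[idx[, c0], , drop = FALSE]
  list(zbar = zbar, wt = wt, idx = idx, dw = dw, g = g)
}

# Backward of lerpForward: dzbar (P x C) -> list(dx = P x 3, dgrid).
lerpBackward <- function(cache, grid, dzbar) {
  g <- cache$g
  p <- nrow(dzbar)
  dgrid <- matrix(0, nrow(grid), ncol(grid))
  if (g == 1L) {
    dgrid[1L, ] <- colSums(dzbar)
    return(list(dx = matrix(0, p, 3L), dgrid = dgrid))
  }
  dx <- matrix(0, p, 3L)
  for (c0 in 1:8) {
    contrib <- rowSums(dzbar * grid[cache$idx[, c0], , drop = FALSE])
    for (a in 1:3) dx[, a] <- dx[, a] + cache$dw[, c0, a] * contrib
    acc <- rowsum(cache$wt[, c0] * dzbar, group = cache$idx[, c0])
    rows <- as.integer(rownames(acc))
    dgrid[rows, ] <- dgrid[rows, ] + acc
  }
  list(dx = dx, dgrid = dgrid)
}

#' Position-aware code lookup
#'
#' Trilinear interpolation of a code grid at points of the unit cube
#' (coordinates are clamped to `[0, 1]`). Exact at the grid nodes and linear
#' along each axis.
#'
#' @param x P x 3 matrix (or length-3 vector) of query points.
#' @param grid a code grid from [reshapeCode()].
#' @return P x channels matrix of position-aware codes.
#' @export
lerpCode <- function(x, grid) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  lerpForward(as.matrix(x), grid)$zbar
}

#' Fourier positional encoding
#'
#' Per input feature `u`, emits `[u, sin(2^0 pi u), cos(2^0 pi u), ...,
#' sin(2^(n_e - 1) pi u), cos(2^(n_e - 1) pi u)]` (base-2 logarithmic
#' frequency sampling), for a total width `(2 n_e + 1)` times the input
#' width. `n_e = 0` is the identity.
#'
#' @param u P x W input matrix (or a vector, taken as one row).
#' @param n_e number of octaves.
#' @return P x `(2 n_e + 1) W` encoded matrix.
#' @export
fourierEncode <- function(u, n_e = 3L) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  u <- as.matrix(u)
  if (n_e == 0L) return(u)
  w <- ncol(u)
  out <- matrix(0, nrow(u), (2L * n_e + 1L) * w)
  out[, seq_len(w)] <- u
  for (e in seq_len(n_e)) {
    arg <- 2^(e - 1L) * pi * u
    out[, (2L * e - 1L) * w + seq_len(w)] <- sin(arg)
    out[, 2L * e * w + seq_len(w)] <- cos(arg)
  }
  out
}

fourierBackward <- function(u, n_e, dout) {
  w <- ncol(u)
  du <- dout[, seq_len(w), drop = FALSE]
  if (n_e == 0L) return(du)
  for (e in seq_len(n_e)) {
    f <- 2^(e - 1L) * pi
    arg <- f * u
    ds <- dout[, (2L * e - 1L) * w + seq_len(w), drop = FALSE]
    dc <- dout[, 2L * e * w + seq_len(w), drop = FALSE]
    du <- du + f * (cos(arg) * ds - sin(arg) * dc)
  }
  du
}

# ---- parameter container ----------------------------------------------------

kaimingInit <- function(fan_in, fan_out, slope) {
  sd <- sqrt(2 / ((1 + slope^2) * fan_in))
  matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
}

#' Initialize a velocity-field model
#'
#' Kaiming-normal initialization of all hidden layers; the DF-NN output head
#' is zero-initialized so the untrained flow is exactly the identity map.
#'
#' @param config a [netConfig()].
#' @return an object of class `velocity_model` with `config` and the flat
#'   named parameter list `params`.
#' @export
initVelocityModel <- function(config = netConfig()) {
  cfg <- config
  sl <- cfg$leaky_slope
  params <- list()
  din <- 3L + cfg$code_channels
  for (l in seq_len(cfg$fa_layers)) {
    params[[sprintf("fa%d.W", l)]] <- kaimingInit(din, cfg$fa_width, sl)
    params[[sprintf("fa%d.b", l)]] <- numeric(cfg$fa_width)
    din <- cfg$fa_width
  }
  din <- cfg$fpe_width + cfg$code_channels
  for (l in seq_len(cfg$df_layers)) {
    params[[sprintf("df%d.W", l)]] <- kaimingInit(din, cfg$df_width, sl)
    params[[sprintf("df%d.b", l)]] <- numeric(cfg$df_width)
    din <- cfg$df_width
  }
  params[["head.W"]] <- matrix(0, din, 3L)
  params[["head.b"]] <- numeric(3L)
  structure(list(config = cfg, params = params), class = "velocity_model")
}

#' @export
print.velocity_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf(
    "velocity_model: FA %dx%d | FPE n_e=%d (width %d) | DF %dx%d | %d parameters\n",
    x$config$fa_layers, x$config$fa_width, x$config$n_e, x$config$fpe_width,
    x$config$df_layers, x$config$df_width, np))
  invisible(x)
}

#' Number of trainable network parameters
#' @param model a `velocity_model`.
#' @return integer parameter count (latent codes excluded).
#' @export
countParameters <- function(model)
  sum(vapply(model$params, length, integer(1L)))

leaky <- function(a, slope) pmax(a, 0) + slope * pmin(a, 0)
# activation derivative, computed once in the forward pass and cached
actGrad <- function(a, slope) {
  g <- (a > 0) * (1 - slope)
  g + slope
}
addBias <- function(m, b) m + rep(b, each = nrow(m))

# Forward velocity evaluation with full cache for reverse-mode. The dense
# layer stack runs in compiled code (src/mlp.cpp); the position-aware code
# lookup stays here.
velocityForward <- function(x, grid, model) {
  cfg <- model$config
  lc <- lerpForward(x, grid)
  out <- cpp_mlp_forward(x, lc$zbar, model$params, cfg$fa_layers,
                         cfg$df_layers, cfg$n_e, cfg$leaky_slope)
  out$lc <- lc
  list(v = out$v, cache = out)
}

# Reverse pass: dv (P x 3) -> gradients wrt x, grid and every parameter.
# dparams is accumulated into `acc` (an environment with acc$g named list,
# ordered exactly like model$params) to avoid copying across steps.
velocityBackward <- function(cache, grid, model, dv, acc) {
  cfg <- model$config
  out <- cpp_mlp_backward(dv, cache, model$params, cfg$fa_layers,
                          cfg$df_layers, cfg$n_e, cfg$leaky_slope,
                          cfg$code_channels)
  g <- acc$g
  dp <- out$dparams
  for (i in seq_along(g)) g[[i]] <- g[[i]] + dp[[i]]
  acc$g <- g
  lb <- lerpBackward(cache$lc, grid, out$dzbar)
  list(dx = out$dx + lb$dx, dgrid = lb$dgrid)
}

zeroGrads <- function(model) {
  g <- lapply(model$params, function(p) p * 0)
  e <- new.env(parent = emptyenv())
  e$g <- g
  e
}

#' Evaluate the stationary velocity field
#'
#' `v(x; Theta, z)`: the network output at points `x` conditioned on the
#' position-aware interpolation of the shape code.
#'
#' @param x P x 3 matrix (or length-3 vector) of points.
#' @param code latent code vector of length `n_z`, or a grid from
#'   [reshapeCode()].
#' @param model a `velocity_model`.
#' @return P x 3 matrix of velocities.
#' @export
velocity <- function(x, code, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  grid <- if (is.matrix(code) && !is.null(attr(code, "g_z"))) code
          else reshapeCode(code, model$config$g_z)
  velocityForward(as.matrix(x), grid, model)$v
}
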