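#' Latent space model
#'
#' Fits the empirical latent-space model used for generative sampling: the
#' unbiased (n - 1 denominator) covariance of the training codes, their
#' mean, and a 2-D PCA basis with explained-variance shares.
#'
#' @param codes `n_z x N_s` code matrix (columns are shapes) or a list of
#'   code vectors.
#' @return an object of class `latent_space_model` with `codes`, `mean`,
#'   `sigma` (covariance), `pca_basis` (`n_z x 2`, orthonormal),
#'   `explained` (length-2 variance shares).
#' @export
fitLatentSpace <- function(codes) {
  if (is.list(codes)) codes <- do.call(cbind, codes)
  codes <- as.matrix(codes)
  ns <- ncol(codes)
  if (ns < 2L) stop("need at least 2 codes to estimate a covariance")
  mu <- rowMeans(codes)
  xc <- t(codes - mu)                       # N_s x n_z, centered
  sigma <- crossprod(xc) / (ns - 1)
  sv <- svd(xc, nu = 0, nv = 2L)
  varTot <- sum(xc^2) / (ns - 1)
  expl <- (sv$d[1:2]^2 / (ns - 1)) / varTot
  structure(list(codes = codes, mean = mu, sigma = sigma,
                 pca_basis = sv$v, explained = expl),
            class = "latent_space_model")
}

#' @export
print.latent_space_model <- function(x, ...) {
  cat(sprintf(
    "latent_space_model: %d codes of dim %d; PC1+PC2 explain %.1f%% variance\n",
    ncol(x$codes), nrow(x$codes), 100 * sum(x$explained)))
  invisible(x)
}

#' Project codes onto the 2-D PCA subspace
#' @param latent_model a `latent_space_model`.
#' @param codes code matrix (`n_z x n`); defaults to the training codes.
#' @return n x 2 matrix of PC scores (centered on the training mean).
#' @export
projectCodes <- function(latent_model, codes = latent_model$codes) {
  crossprod(latent_model$pca_basis, as.matrix(codes) - latent_model$mean)
}

#' Sample latent codes from the fitted Gaussian
#'
#' Draws from `N(0, Sigma_z)` (zero-centered, matching the code-norm
#' shrinkage toward the origin) through the eigendecomposition square root;
#' numerically negative eigenvalues are clipped at zero.
#'
#' @param latent_model a `latent_space_model`.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return `n_z x n` matrix of sampled codes.
#' @export
sampleCodes <- function(latent_model, n, seed = 1L) {
  set.seed(seed)
  ev <- eigen(latent_model$sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  nz <- nrow(latent_model$sigma)
  root <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  root %*% matrix(stats::rnorm(nz * n), nz, n)
}

#' Interpolate between two latent codes
#'
#' Linear interpolation or spherical linear interpolation (SLERP) along the
#' great arc; SLERP falls back to linear (with a warning) for near-zero or
#' near-antipodal codes, where the arc is degenerate.
#'
#' @param z_a,z_b endpoint codes.
#' @param t interpolation parameter in `[0, 1]`.
#' @param mode `"linear"` or `"slerp"`.
#' @return interpolated code vector.
#' @export
interpolateCodes <- function(z_a, z_b, t, mode = c("linear", "slerp")) {
  mode <- match.arg(mode)
  stopifnot(t >= 0, t <= 1)
  if (t == 0) return(z_a)
  if (t == 1) return(z_b)
  if (mode == "linear") return((1 - t) * z_a + t * z_b)
  na <- sqrt(sum(z_a^2)); nb <- sqrt(sum(z_b^2))
  if (na < 1e-12 || nb < 1e-12) {
    warning("slerp undefined for near-zero code; falling back to linear")
    return((1 - t) * z_a + t * z_b)
  }
  cosw <- sum(z_a * z_b) / (na * nb)
  if (cosw < -1 + 1e-9) {
    warning("slerp undefined for near-antipodal codes; falling back to linear")
    return((1 - t) * z_a + t * z_b)
  }
  w <- acos(pmin(pmax(cosw, -1), 1))
  if (w < 1e-12) return((1 - t) * z_a + t * z_b)
  (sin((1 - t) * w) / sin(w)) * z_a + (sin(t * w) / sin(w)) * z_b
}

#' Perturb a code at a given signal-to-noise ratio
#'
#' Adds isotropic Gaussian noise rescaled so that
#' `||noise|| = snr_fraction * ||z||` exactly (SNR read as the
#' noise-to-signal Euclidean-norm ratio; recorded choice, the source of the
#' convention being ambiguous).
#'
#' @param z code vector.
#' @param snr_fraction nonnegative noise fraction (0.01 = 1% SNR).
#' @param seed RNG seed.
#' @return perturbed code.
#' @export
perturbCodeSnr <- function(z, snr_fraction, seed = 1L) {
  stopifnot(snr_fraction >= 0)
  if (snr_fraction == 0) return(z)
  set.seed(seed)
  e <- stats::rnorm(length(z))
  z + e * (snr_fraction * sqrt(sum(z^2)) / sqrt(sum(e^2)))
}

#' Decode a latent code into a synthetic anatomy
#'
#' Applies the backward-in-time flow (modified Euler, as in training) to the
#' template geometry under the given code; the synthetic cloud carries the
#' template's weights.
#'
#' @param code latent code vector.
#' @param template template `weighted_point_cloud`.
#' @param model trained `velocity_model`.
#' @param K integration steps (default: model config).
#' @return a `weighted_point_cloud`.
#' @export
generateShape <- function(code, template, model, K = NULL) {
  traj <- inverseMapExplicit(template$points, model, code, K = K)
  out <- cloudLike(trajectoryEndpoint(traj), template)
  out$label <- sprintf("synthetic(%s)", template$label)
  out
}
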