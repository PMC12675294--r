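#' Flow integration of the diffeomorphic ODE
#'
#' The deformation is the unit-time flow of the stationary velocity field:
#' `forwardMap` integrates with K explicit forward-Euler steps
#' (`x_(k+1) = x_k + v(x_k)/K`), `inverseMapExplicit` runs the modified
#' (explicit) Euler approximation of the backward-in-time ODE
#' (`x_(k-1) = x_k - v(x_k - v(x_k)/K)/K`), and `inverseMapImplicit` solves
#' the implicit backward-Euler step `x_(k-1) = x_k - v(x_(k-1))/K` by fixed
#' point iteration, which inverts the forward scheme exactly (to solver
#' tolerance). All K+1 states are retained as geodesic frames; per-step
#' velocities are logged for the kinetic-energy regularizer.
#'
#' @param points M x 3 matrix or `weighted_point_cloud` (points in the unit
#'   cube; they are not re-clamped during integration, which would break
#'   invertibility).
#' @param model a `velocity_model`.
#' @param code latent code vector (or grid from [reshapeCode()]).
#' @param K number of steps (default: the model's configured K).
#' @return A `flow_trajectory`: list with `states` (list of K+1 point
#'   matrices, `states[[k+1]]` at pseudo-time k/K), `velocities` (list of K
#'   logged per-step fields), `direction`, `K`, and for the implicit scheme
#'   `inner_iterations`. Forward trajectories start at the input
#'   (`states[[1]]`); backward trajectories end at it (`states[[K+1]]`) and
#'   their endpoint is `states[[1]]`.
#' @name flow
NULL

trajPoints <- function(points) {
  if (inherits(points, "weighted_point_cloud")) points$points
  else as.matrix(points)
}

asGrid <- function(code, model) {
  if (is.matrix(code) && !is.null(attr(code, "g_z"))) code
  else reshapeCode(code, model$config$g_z)
}

checkFinite <- function(v, k, scheme) {
  if (!all(is.finite(v)))
    stop(sprintf("non-finite velocity at %s step %d", scheme, k))
}

#' @rdname flow
#' @param keep_cache internal: retain per-step network caches for training.
#' @export
forwardMap <- function(points, model, code, K = NULL, keep_cache = FALSE) {
  x <- trajPoints(points)
  K <- as.integer(K %||% model$config$K)
  grid <- asGrid(code, model)
  states <- vector("list", K + 1L)
  vels <- vector("list", K)
  caches <- if (keep_cache) vector("list", K)
  states[[1L]] <- x
  for (k in seq_len(K)) {
    vf <- velocityForward(x, grid, model)
    checkFinite(vf$v, k, "forward-Euler")
    vels[[k]] <- vf$v
    if (keep_cache) caches[[k]] <- vf$cache
    x <- x + vf$v / K
    states[[k + 1L]] <- x
  }
  structure(list(states = states, velocities = vels, caches = caches,
                 direction = "forward", K = K),
            class = "flow_trajectory")
}

#' @rdname flow
#' @export
inverseMapExplicit <- function(points, model, code, K = NULL,
                               keep_cache = FALSE) {
  x <- trajPoints(points)
  K <- as.integer(K %||% model$config$K)
  grid <- asGrid(code, model)
  states <- vector("list", K + 1L)
  vels <- vector("list", K)
  caches <- if (keep_cache) vector("list", K)
  states[[K + 1L]] <- x
  for (k in K:1) {
    inner <- velocityForward(x, grid, model)
    checkFinite(inner$v, k, "modified-Euler (inner)")
    y <- x - inner$v / K
    outer <- velocityForward(y, grid, model)
    checkFinite(outer$v, k, "modified-Euler (outer)")
    vels[[k]] <- outer$v
    if (keep_cache) caches[[k]] <- list(inner = inner$cache,
                                        outer = outer$cache)
    x <- x - outer$v / K
    states[[k]] <- x
  }
  structure(list(states = states, velocities = vels, caches = caches,
                 direction = "backward", K = K),
            class = "flow_trajectory")
}

#' @rdname flow
#' @param tol infinity-norm tolerance of the per-step fixed-point solve.
#' @param max_inner cap on fixed-point iterations per step.
#' @export
inverseMapImplicit <- function(points, model, code, K = NULL, tol = 1e-10,
                               max_inner = 500L) {
  x <- trajPoints(points)
  K <- as.integer(K %||% model$config$K)
  grid <- asGrid(code, model)
  states <- vector("list", K + 1L)
  vels <- vector("list", K)
  innerIts <- integer(K)
  states[[K + 1L]] <- x
  for (k in K:1) {
    # warm start at the modified-Euler estimate
    u <- x - velocityForward(x - velocityForward(x, grid, model)$v / K,
                             grid, model)$v / K
    ok <- FALSE
    for (it in seq_len(max_inner)) {
      v <- velocityForward(u, grid, model)$v
      checkFinite(v, k, "implicit-Euler")
      uNew <- x - v / K
      res <- max(abs(uNew - u))
      u <- uNew
      if (res < tol) { ok <- TRUE; innerIts[k] <- it; break }
    }
    if (!ok) {
      resid <- max(abs(u + velocityForward(u, grid, model)$v / K - x))
      stop(sprintf(
        "implicit inverse step %d did not converge in %d iterations (residual %.3e)",
        k, max_inner, resid))
    }
    vels[[k]] <- velocityForward(u, grid, model)$v
    x <- u
    states[[k]] <- x
  }
  structure(list(states = states, velocities = vels, caches = NULL,
                 direction = "backward", K = K,
                 inner_iterations = innerIts),
            class = "flow_trajectory")
}

#' @export
print.flow_trajectory <- function(x, ...) {
  cat(sprintf("flow_trajectory (%s): K = %d, %d points\n",
              x$direction, x$K, nrow(x$states[[1L]])))
  invisible(x)
}

#' Endpoint of a trajectory
#'
#' The mapped point set: the last state of a forward trajectory, the first
#' state (pseudo-time 0) of a backward one.
#' @param trajectory a `flow_trajectory`.
#' @return M x 3 matrix.
#' @export
trajectoryEndpoint <- function(trajectory) {
  if (trajectory$direction == "forward")
    trajectory$states[[trajectory$K + 1L]]
  else trajectory$states[[1L]]
}

#' Extract geodesic frames from a trajectory
#'
#' Intermediate integration states as point clouds carrying the source
#' weights (and label), for morphing visualizations.
#'
#' @param trajectory a `flow_trajectory`.
#' @param indices integer pseudo-time indices in `0:K` (default all).
#' @param cloud the cloud whose weights/normals/label the frames inherit.
#' @return list of `weighted_point_cloud`s.
#' @export
geodesicFrames <- function(trajectory, indices = NULL, cloud = NULL) {
  K <- trajectory$K
  indices <- indices %||% 0:K
  if (any(indices < 0L | indices > K))
    stop(sprintf("frame index out of range 0..%d", K))
  lapply(indices, function(k) {
    pts <- trajectory$states[[k + 1L]]
    if (is.null(cloud)) weightedPointCloud(pts)
    else weightedPointCloud(pts, cloud$weights, cloud$normals,
                            label = sprintf("%s@%d/%d", cloud$label, k, K))
  })
}

# ---- reverse-mode through the unrolled integrators --------------------------
# dEnd: gradient at the trajectory endpoint; dvel: optional list of per-step
# gradients wrt the logged velocities (kinetic-energy term). Parameter
# gradients are accumulated into `acc`; returns dgrid (and dx0 wrt inputs).
forwardMapBackward <- function(traj, grid, model, dEnd, dvel = NULL, acc) {
  K <- traj$K
  dgrid <- grid * 0
  dx <- dEnd
  for (k in K:1) {
    dvk <- dx / K
    if (!is.null(dvel)) dvk <- dvk + dvel[[k]]
    vb <- velocityBackward(traj$caches[[k]], grid, model, dvk, acc)
    dx <- dx + vb$dx
    dgrid <- dgrid + vb$dgrid
  }
  list(dx0 = dx, dgrid = dgrid)
}

inverseMapBackward <- function(traj, grid, model, dEnd, dvel = NULL, acc) {
  K <- traj$K
  dgrid <- grid * 0
  dx <- dEnd                              # gradient wrt states[[1]] (k = 0)
  for (k in seq_len(K)) {
    # x_{k-1} = x_k - vOuter(y_k)/K,  y_k = x_k - vInner(x_k)/K
    dvOuter <- -dx / K
    if (!is.null(dvel)) dvOuter <- dvOuter + dvel[[k]]
    vbO <- velocityBackward(traj$caches[[k]]$outer, grid, model, dvOuter,
                            acc)
    dgrid <- dgrid + vbO$dgrid
    dy <- vbO$dx
    dvInner <- -dy / K
    vbI <- velocityBackward(traj$caches[[k]]$inner, grid, model, dvInner,
                            acc)
    dgrid <- dgrid + vbI$dgrid
    dx <- dx + dy + vbI$dx
  }
  list(dxK = dx, dgrid = dgrid)
}
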