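#' Synthetic vessel specification
#'
#' Parametric description of a tubular fixture: a centerline given by
#' control points (interpolated by cubic splines), a radius profile along
#' arc length, mesh resolution, optional capped ends, and optional branch
#' stubs. Branch stubs are built as separate closed tubes emanating from the
#' trunk surface (junctions are deliberately not merged), so every cohort
#' member shares the same point-cloud topology and branch membership of
#' points is known by construction.
#'
#' @param centerline Q x 3 matrix of control points (cm).
#' @param radius scalar, length-Q vector (interpolated), or function of the
#'   curve parameter in `[0, 1]`.
#' @param n_circ,n_long circumferential and longitudinal cell resolution.
#' @param caps close the tube ends (`FALSE` reproduces open inlets/outlets).
#' @param branches optional list of `vessel_spec`s for branch stubs.
#' @return a `vessel_spec` list.
#' @export
vesselSpec <- function(centerline, radius, n_circ = 16L, n_long = 24L,
                       caps = TRUE, branches = list()) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L || nrow(centerline) < 2L)
    stop("centerline must be a Q x 3 matrix with Q >= 2")
  if (!is.function(radius) && any(radius <= 0))
    stop("radius must be positive")
  structure(list(centerline = centerline, radius = radius,
                 n_circ = as.integer(n_circ), n_long = as.integer(n_long),
                 caps = caps, branches = branches),
            class = "vessel_spec")
}

splineCurve <- function(ctrl, s) {
  q <- nrow(ctrl)
  s0 <- seq(0, 1, length.out = q)
  sapply(1:3, function(d)
    stats::spline(s0, ctrl[, d], xout = s, method = "natural")$y)
}

radiusProfile <- function(radius, s, q) {
  if (is.function(radius)) return(radius(s))
  if (length(radius) == 1L) return(rep(radius, length(s)))
  stats::spline(seq(0, 1, length.out = length(radius)), radius, xout = s,
                method = "natural")$y
}

# Single closed tube mesh around a spline centerline, rotation-minimizing
# frames, optional end caps; orientation fixed outward via signed volume.
buildTube <- function(spec) {
  nl <- spec$n_long; nc <- spec$n_circ
  s <- seq(0, 1, length.out = nl + 1L)
  ctr <- splineCurve(spec$centerline, s)
  rad <- radiusProfile(spec$radius, s, nrow(spec$centerline))
  if (any(rad <= 0)) stop("radius must stay positive along the centerline")
  tang <- rbind(ctr[2L, ] - ctr[1L, ],
                (ctr[3:(nl + 1L), , drop = FALSE] -
                   ctr[1:(nl - 1L), , drop = FALSE]) / 2,
                ctr[nl + 1L, ] - ctr[nl, ])
  tang <- tang / sqrt(rowSums(tang^2))
  # rough self-intersection guard: samples far apart along the curve but
  # closer than the tube diameter in space
  d2 <- crossDist2(ctr, ctr)
  arc <- c(0, cumsum(sqrt(rowSums(diff(ctr)^2))))
  far <- abs(outer(arc, arc, "-")) > 4 * max(rad)
  if (any(d2[far] < (2 * max(rad))^2))
    stop("self-intersecting centerline at given radius")
  # rotation-minimizing normal propagation
  n0 <- c(0, 0, 1)
  if (abs(sum(n0 * tang[1L, ])) > 0.9) n0 <- c(0, 1, 0)
  n0 <- n0 - sum(n0 * tang[1L, ]) * tang[1L, ]
  n0 <- n0 / sqrt(sum(n0^2))
  normals <- matrix(0, nl + 1L, 3L)
  normals[1L, ] <- n0
  for (k in 2:(nl + 1L)) {
    n <- normals[k - 1L, ] - sum(normals[k - 1L, ] * tang[k, ]) * tang[k, ]
    normals[k, ] <- n / sqrt(sum(n^2))
  }
  binorm <- cbind(tang[, 2L] * normals[, 3L] - tang[, 3L] * normals[, 2L],
                  tang[, 3L] * normals[, 1L] - tang[, 1L] * normals[, 3L],
                  tang[, 1L] * normals[, 2L] - tang[, 2L] * normals[, 1L])
  theta <- 2 * pi * (seq_len(nc) - 1L) / nc
  verts <- matrix(0, (nl + 1L) * nc, 3L)
  for (k in seq_len(nl + 1L)) {
    ring <- ctr[rep(k, nc), ] +
      rad[k] * (cos(theta) %o% normals[k, ] + sin(theta) %o% binorm[k, ])
    verts[(k - 1L) * nc + seq_len(nc), ] <- ring
  }
  vid <- function(k, j) (k - 1L) * nc + ((j - 1L) %% nc) + 1L
  tris <- vector("list", nl)
  for (k in seq_len(nl)) {
    j <- seq_len(nc)
    tris[[k]] <- rbind(cbind(vid(k, j), vid(k, j + 1L), vid(k + 1L, j + 1L)),
                       cbind(vid(k, j), vid(k + 1L, j + 1L), vid(k + 1L, j)))
  }
  tris <- do.call(rbind, tris)
  if (spec$caps) {
    c0 <- nrow(verts) + 1L
    c1 <- nrow(verts) + 2L
    verts <- rbind(verts, ctr[1L, ], ctr[nl + 1L, ])
    j <- seq_len(nc)
    tris <- rbind(tris,
                  cbind(rep(c0, nc), vid(1L, j + 1L), vid(1L, j)),
                  cbind(rep(c1, nc), vid(nl + 1L, j), vid(nl + 1L, j + 1L)))
  }
  mesh <- surfaceMesh(verts, tris)
  # orient outward: positive signed volume under the divergence theorem
  g <- triangleGeometry(mesh)
  a <- verts[tris[, 1L], , drop = FALSE]
  vol <- sum(rowSums(a * (g$normals * g$areas))) / 3
  if (vol < 0) mesh <- surfaceMesh(verts, tris[, c(1L, 3L, 2L)])
  mesh
}

#' Build a synthetic vessel mesh
#'
#' Deterministic closed triangulated tube (with optional branch-stub
#' components) from a [vesselSpec()]. Vertices and triangles of all
#' components are concatenated; `attr(, "component")` records the component
#' of each triangle (1 = trunk).
#'
#' @param spec a `vessel_spec`.
#' @param seed unused for the deterministic build; kept so cohort samplers
#'   can pass it through uniformly.
#' @return a closed `surface_mesh`.
#' @export
makeTube <- function(spec, seed = NULL) {
  meshes <- c(list(buildTube(spec)),
              lapply(spec$branches, function(b) buildTube(b)))
  verts <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  off <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices),
                             integer(1L))))
  tris <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$triangles + off[i]))
  mesh <- surfaceMesh(verts, tris)
  attr(mesh, "component") <- rep(seq_along(meshes),
                                 vapply(meshes, function(m)
                                   nrow(m$triangles), integer(1L)))
  mesh
}

#' Aorta-like base specification for fixtures
#'
#' A curved trunk (arch-like bend, tapering radius) with up to three branch
#' stubs near the top of the arch; deliberately simple, no attempt to mimic
#' patient statistics.
#'
#' @param radius trunk inlet radius (cm).
#' @param length trunk extent scale (cm).
#' @param arch bend strength in `[0, 1.5]`.
#' @param n_branches 0 to 3 branch stubs.
#' @param n_circ,n_long trunk resolution (branches use half).
#' @return a `vessel_spec`.
#' @export
aortaSpec <- function(radius = 0.65, length = 6, arch = 1,
                      n_branches = 2L, n_circ = 14L, n_long = 22L) {
  s <- seq(0, 1, length.out = 7L)
  ctr <- cbind(length * 0.5 * sin(pi * s * arch),
               length * 0.12 * sin(2 * pi * s) * arch,
               length * (s - 0.5))
  rad <- radius * (1 - 0.35 * s)          # tapering trunk
  branches <- list()
  if (n_branches > 0L) {
    for (b in seq_len(min(n_branches, 3L))) {
      sb <- 0.35 + 0.15 * (b - 1L)
      base <- splineCurve(ctr, sb)
      dir <- c(0.3 * (b - 2L), 0.9, 0.35)
      dir <- dir / sqrt(sum(dir^2))
      bc <- rbind(base + 0.1 * dir, base + (0.9 + 0.2 * b) * dir)
      branches[[b]] <- vesselSpec(bc, radius * 0.3, n_circ = 8L,
                                  n_long = 8L, caps = TRUE)
    }
  }
  vesselSpec(ctr, rad, n_circ = n_circ, n_long = n_long, caps = TRUE,
             branches = branches)
}

#' Generate a cohort of topologically identical vessel meshes
#'
#' Smooth random perturbations of a base specification: per-shape factors on
#' radius, arch curvature and branch direction, drawn at `variation_scale`
#' relative magnitude. `variation_scale = 0` returns identical shapes.
#'
#' @param base_spec a `vessel_spec` (e.g. from [aortaSpec()]).
#' @param n cohort size.
#' @param variation_scale relative perturbation magnitude (e.g. 0.1).
#' @param seed RNG seed (cohort is reproducible given spec + seed).
#' @return list of `surface_mesh`es.
#' @export
makeCohort <- function(base_spec, n, variation_scale = 0.1, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f <- function() 1 + variation_scale * stats::rnorm(1L)
    sp <- base_spec
    sp$centerline <- sp$centerline *
      matrix(rep(c(f(), f(), f()), each = nrow(sp$centerline)), ncol = 3L)
    # smooth low-frequency centerline wiggle
    q <- nrow(sp$centerline)
    s0 <- seq(0, 1, length.out = q)
    amp <- variation_scale * mean(abs(sp$centerline)) * 0.5
    for (d in 1:3)
      sp$centerline[, d] <- sp$centerline[, d] +
        amp * stats::rnorm(1L) * sin(pi * s0 + stats::runif(1L, 0, pi))
    if (!is.function(sp$radius)) sp$radius <- sp$radius * f()
    sp$branches <- lapply(sp$branches, function(b) {
      b$centerline <- sweep(b$centerline, 2L,
                            variation_scale * 0.2 *
                              stats::rnorm(3L) * mean(b$radius), "+")
      b$radius <- b$radius * f()
      b
    })
    makeTube(sp)
  })
}

#' Analytic invertible warp of the unit cube
#'
#' Closed-form smooth displacement field
#' `u_d(x) = amplitude_d * sin(2 pi freq[d, ] . x + phase_d)` whose
#' displacement-gradient norm is provably below 1, so `x + u(x)` is a
#' diffeomorphism and the inverse is computable by fixed-point iteration.
#' Used as ground truth for registration-recovery experiments.
#'
#' @param amplitude length-3 vector of component amplitudes.
#' @param freq 3 x 3 matrix of frequency row-vectors (cycles per unit).
#' @param phase length-3 phase vector.
#' @return an `analytic_warp`.
#' @export
analyticWarp <- function(amplitude = rep(0.02, 3),
                         freq = diag(3) + 0.5, phase = c(0, 1, 2)) {
  amplitude <- rep_len(amplitude, 3L)
  lip <- sum(abs(amplitude) * 2 * pi * sqrt(rowSums(freq^2)))
  if (lip >= 1)
    stop(sprintf("amplitude bound violated: displacement gradient norm %.3f >= 1",
                 lip))
  structure(list(amplitude = amplitude, freq = freq, phase = phase,
                 lipschitz = lip),
            class = "analytic_warp")
}

warpDisplacement <- function(warp, x) {
  u <- matrix(0, nrow(x), 3L)
  for (d in 1:3)
    u[, d] <- warp$amplitude[d] *
      sin(2 * pi * (x %*% warp$freq[d, ]) + warp$phase[d])
  u
}

#' Apply or invert an analytic warp
#'
#' `applyWarp` maps `x -> x + u(x)`; `invertWarp` solves `y + u(y) = x` by
#' fixed-point iteration (a contraction, since the displacement gradient is
#' below 1), so `invertWarp(applyWarp(x))` recovers `x` to tight tolerance.
#'
#' @param warp an `analytic_warp`.
#' @param cloud a `weighted_point_cloud` or M x 3 matrix.
#' @param tol fixed-point tolerance for the inverse.
#' @return the same type as `cloud`, warped.
#' @export
applyWarp <- function(warp, cloud) {
  pts <- if (inherits(cloud, "weighted_point_cloud")) cloud$points
         else as.matrix(cloud)
  out <- pts + warpDisplacement(warp, pts)
  if (inherits(cloud, "weighted_point_cloud")) {
    cloud$points <- out
    cloud
  } else out
}

#' @rdname applyWarp
#' @export
invertWarp <- function(warp, cloud, tol = 1e-12) {
  x <- if (inherits(cloud, "weighted_point_cloud")) cloud$points
       else as.matrix(cloud)
  y <- x
  for (it in seq_len(200L)) {
    yNew <- x - warpDisplacement(warp, y)
    if (max(abs(yNew - y)) < tol) { y <- yNew; break }
    y <- yNew
  }
  if (inherits(cloud, "weighted_point_cloud")) {
    cloud$points <- y
    cloud
  } else y
}
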