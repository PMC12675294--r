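#' Weighted point cloud
#'
#' The working representation of a surface: points with positive weights that
#' sum to one (cell areas after normalization) and, optionally, outward unit
#' normals. Coordinates are in cm before unit-cube normalization and in
#' \eqn{\Omega = [0,1]^3} after it.
#'
#' @param points numeric matrix, M x 3.
#' @param weights positive numeric vector of length M summing to 1; if `NULL`,
#'   uniform weights `1/M` are used.
#' @param normals optional M x 3 matrix of unit vectors.
#' @param label free-text shape identifier.
#' @return An object of class `weighted_point_cloud`.
#' @export
weightedPointCloud <- function(points, weights = NULL, normals = NULL,
                               label = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an M x 3 matrix")
  m <- nrow(points)
  if (m < 1L) stop("empty point cloud")
  if (is.null(weights)) weights <- rep(1 / m, m)
  weights <- as.numeric(weights)
  if (length(weights) != m) stop("weights/points length mismatch")
  if (any(weights <= 0)) stop("all weights must be positive")
  s <- sum(weights)
  if (abs(s - 1) > 1e-8) weights <- weights / s
  if (abs(sum(weights) - 1) > 1e-12) weights <- weights / sum(weights)
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == c(m, 3L))) stop("normals must be M x 3")
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-9)) normals <- normals / nn
  }
  structure(list(points = points, weights = weights, normals = normals,
                 label = as.character(label)),
            class = "weighted_point_cloud")
}

#' @export
print.weighted_point_cloud <- function(x, ...) {
  cat(sprintf("weighted_point_cloud '%s': %d points, %s normals\n",
              x$label, nrow(x$points),
              if (is.null(x$normals)) "no" else "with"))
  rg <- apply(x$points, 2L, range)
  cat(sprintf("  bbox: [%.4g, %.4g] x [%.4g, %.4g] x [%.4g, %.4g]\n",
              rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
  invisible(x)
}

nPoints <- function(cloud) nrow(cloud$points)

#' Convert a triangulated mesh into a weighted point cloud
#'
#' One point per triangle at its centroid; the weight is the triangle area
#' normalized over the surface, and the normal is the per-triangle outward
#' unit normal.
#'
#' @param mesh a `surface_mesh`.
#' @param label shape identifier carried into the cloud.
#' @return a `weighted_point_cloud` with `nrow(mesh$triangles)` points.
#' @export
meshToCloud <- function(mesh, label = "") {
  if (!inherits(mesh, "surface_mesh")) stop("mesh must be a surface_mesh")
  g <- triangleGeometry(mesh)
  bad <- which(g$areas <= .Machine$double.eps * max(g$areas, 1))
  if (length(bad) > 0L)
    stop(sprintf("degenerate geometry: zero-area triangle(s) at index %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  weightedPointCloud(g$centroids, g$areas / sum(g$areas), g$normals,
                     label = label)
}

#' Estimate outward normals for a bare point cloud
#'
#' Local-PCA normal estimation for clouds loaded without a mesh: the normal at
#' each point is the smallest principal axis of its k nearest neighbours,
#' oriented outward by a viewpoint heuristic (away from the cloud centroid).
#'
#' @param cloud a `weighted_point_cloud`.
#' @param k neighbourhood size.
#' @return the cloud with a `normals` matrix filled in.
#' @export
estimateNormals <- function(cloud, k = 10L) {
  x <- cloud$points
  m <- nrow(x)
  k <- min(as.integer(k), m)
  d2 <- crossDist2(x, x)
  ctr <- colMeans(x)
  normals <- matrix(0, m, 3L)
  for (i in seq_len(m)) {
    nb <- order(d2[i, ])[seq_len(k)]
    xc <- sweep(x[nb, , drop = FALSE], 2L, colMeans(x[nb, , drop = FALSE]))
    ev <- eigen(crossprod(xc), symmetric = TRUE)
    n <- ev$vectors[, 3L]
    if (sum(n * (x[i, ] - ctr)) < 0) n <- -n
    normals[i, ] <- n
  }
  cloud$normals <- normals / sqrt(rowSums(normals^2))
  cloud
}

# Squared Euclidean cross-distance matrix (M x M'), clipped at 0.
crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
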