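#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated surface in physical units (cm).
#' Triangles are assumed to be consistently wound so that the right-hand rule
#' gives outward normals.
#'
#' @param vertices numeric matrix, V x 3, vertex coordinates in cm.
#' @param triangles integer matrix, F x 3, 1-based vertex indices.
#' @param check if `TRUE`, validate indices and triangle areas.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles` and the logical flag `closed` (every edge shared by exactly
#'   two triangles).
#' @export
surfaceMesh <- function(vertices, triangles, check = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (check) {
    if (nrow(triangles) < 1L) stop("mesh must have at least one triangle")
    idx <- range(triangles)
    if (idx[1L] < 1L || idx[2L] > nrow(vertices))
      stop("triangle indices out of range")
  }
  m <- structure(list(vertices = vertices, triangles = triangles),
                 class = "surface_mesh")
  m$closed <- meshIsClosed(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (isTRUE(x$closed)) "closed" else "open"))
  invisible(x)
}

# Edge-manifold closedness: every undirected edge borders exactly 2 triangles.
meshIsClosed <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

# Per-triangle geometry from the cross product; the one place areas, normals
# and centroids are defined, reused by both the cloud constructor and tests.
triangleGeometry <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 2L], , drop = FALSE]
  c_ <- v[tr[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm2 <- sqrt(rowSums(cr^2))
  list(centroids = (a + b + c_) / 3,
       areas = nrm2 / 2,
       normals = cr / pmax(nrm2, .Machine$double.xmin))
}

#' Euler characteristic of a mesh
#'
#' V - E + F with undirected edges; 2 for sphere-topology surfaces.
#' @param mesh a `surface_mesh`.
#' @return integer Euler characteristic.
#' @export
eulerCharacteristic <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  key <- unique(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  nv <- length(unique(as.vector(tr)))
  nv - length(key) + nrow(tr)
}
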