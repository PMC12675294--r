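#' Fit a shared unit-cube normalization over a cohort of clouds
#'
#' Per-axis affine map (anisotropic rescaling) sending the union of all input
#' points into `[margin, 1 - margin]^3`. One transform is fitted for the whole
#' cohort (template plus sources) so every shape lives in the same coordinate
#' system; physical-unit (cm) errors are recovered through the inverse map.
#'
#' @param clouds a `weighted_point_cloud` or a list of them.
#' @param margin fraction of the cube kept free on each side (default 0.05, so
#'   integrated trajectories rarely exit the cube).
#' @return An object of class `unit_cube_transform` with per-axis `scale` and
#'   `translation`: mapped = scale * x + translation.
#' @export
fitUnitCube <- function(clouds, margin = 0.05) {
  if (inherits(clouds, "weighted_point_cloud")) clouds <- list(clouds)
  if (length(clouds) < 1L) stop("empty cloud list")
  if (margin < 0 || margin >= 0.5) stop("margin must be in [0, 0.5)")
  pts <- do.call(rbind, lapply(clouds, function(cl) cl$points))
  lo <- apply(pts, 2L, min)
  hi <- apply(pts, 2L, max)
  extent <- hi - lo
  scale <- numeric(3L)
  translation <- numeric(3L)
  for (a in 1:3) {
    if (extent[a] <= 0) {
      warning(sprintf("degenerate extent on axis %d; centring only", a))
      scale[a] <- 1
      translation[a] <- 0.5 - lo[a]
    } else {
      scale[a] <- (1 - 2 * margin) / extent[a]
      translation[a] <- margin - scale[a] * lo[a]
    }
  }
  structure(list(scale = scale, translation = translation, margin = margin),
            class = "unit_cube_transform")
}

#' Apply or invert a unit-cube transform
#'
#' @param transform a `unit_cube_transform`.
#' @param x a `weighted_point_cloud` or an M x 3 matrix.
#' @return the same type as `x`, mapped into (or back out of) the unit cube.
#' @export
applyUnitCube <- function(transform, x) {
  mapPts <- function(p)
    sweep(sweep(p, 2L, transform$scale, "*"), 2L, transform$translation, "+")
  if (inherits(x, "weighted_point_cloud")) {
    x$points <- mapPts(x$points)
    x
  } else mapPts(as.matrix(x))
}

#' @rdname applyUnitCube
#' @export
invertUnitCube <- function(transform, x) {
  mapPts <- function(p)
    sweep(sweep(p, 2L, transform$translation, "-"), 2L, transform$scale, "/")
  if (inherits(x, "weighted_point_cloud")) {
    x$points <- mapPts(x$points)
    x
  } else mapPts(as.matrix(x))
}

#' @export
print.unit_cube_transform <- function(x, ...) {
  cat("unit_cube_transform\n  scale:      ",
      paste(signif(x$scale, 6), collapse = " "),
      "\n  translation:", paste(signif(x$translation, 6), collapse = " "),
      "\n")
  invisible(x)
}
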