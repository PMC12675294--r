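#' Thin-plate spline warp in three dimensions
#'
#' Radial-basis warp with the 3-D biharmonic kernel U(r) = r plus an affine
#' part. With `stiffness = 0` the warp interpolates the control displacements
#' exactly; positive stiffness trades interpolation for smoothness. Affine
#' maps of the controls are reproduced exactly by the polynomial part.
#'
#' @param control_src P x 3 source control points (>= 4, non-coplanar).
#' @param control_dst P x 3 destination control points.
#' @param query Q x 3 points to warp.
#' @param stiffness nonnegative regularization added to the kernel diagonal.
#' @return Q x 3 matrix of warped query points.
#' @export
tpsWarp <- function(control_src, control_dst, query, stiffness = 0) {
  src <- as.matrix(control_src); dst <- as.matrix(control_dst)
  query <- as.matrix(query)
  p <- nrow(src)
  if (p < 4L) stop("need at least 4 control points")
  if (nrow(dst) != p) stop("control point sets must match in size")
  K <- sqrt(crossDist2(src, src)) + diag(stiffness, p)
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(dst, matrix(0, 4L, 3L))
  coef <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system: coplanar or duplicated control points"))
  Wc <- coef[seq_len(p), , drop = FALSE]
  Ac <- coef[p + 1:4, , drop = FALSE]
  U <- sqrt(crossDist2(query, src))
  U %*% Wc + cbind(1, query) %*% Ac
}
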