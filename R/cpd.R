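#' Rigid coherent point drift alignment
#'
#' Rigid CPD (EM over a Gaussian mixture with isotropic variance and a uniform
#' outlier component) estimating rotation, isotropic scale and translation
#' that align `source` onto `target`. Used as the pre-registration step before
#' unit-cube embedding, and by the generic cohort-augmentation helper.
#'
#' @param source,target `weighted_point_cloud`s (weights are ignored; CPD
#'   treats the points as an unweighted GMM).
#' @param max_iter maximum EM iterations.
#' @param tol stop when the relative change of the objective falls below this.
#' @param outlier_weight uniform-outlier mixture weight in `[0, 1)`.
#' @param estimate_scale if `FALSE`, scale is fixed at 1.
#' @return A list of class `cpd_result`: `transform` (a `rigid_transform`
#'   with `rotation`, `scale`, `translation`), `aligned` (the transformed
#'   source cloud), `converged`, `iterations`, `sigma2`.
#' @export
cpdRigid <- function(source, target, max_iter = 100L, tol = 1e-8,
                     outlier_weight = 0.1, estimate_scale = TRUE) {
  Y <- source$points                     # GMM centroids (moving)
  X <- target$points                     # data (fixed)
  m <- nrow(Y); n <- nrow(X); d <- 3L
  if (m < 1L || n < 1L) stop("empty point cloud")
  w <- outlier_weight
  R <- diag(3); s <- 1; t <- colMeans(X) - colMeans(Y)
  sigma2 <- sum(crossDist2(X, Y)) / (d * m * n)
  qOld <- Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    TY <- sweep(s * tcrossprod(Y, R), 2L, t, "+")
    d2 <- crossDist2(X, TY)              # n x m
    num <- exp(-d2 / (2 * sigma2))
    cst <- (2 * pi * sigma2)^(d / 2) * w / max(1 - w, 1e-12) * m / n
    den <- rowSums(num) + cst
    P <- num / den                       # n x m posterior
    np <- sum(P)
    if (np < .Machine$double.eps) break
    mux <- as.numeric(crossprod(X, rowSums(P))) / np
    muy <- as.numeric(crossprod(Y, colSums(P))) / np
    Xh <- sweep(X, 2L, mux); Yh <- sweep(Y, 2L, muy)
    A <- crossprod(Xh, P %*% Yh)         # 3 x 3
    sv <- svd(A)
    C <- diag(c(1, 1, sign(det(tcrossprod(sv$u, sv$v)))))
    R <- sv$u %*% C %*% t(sv$v)
    trAR <- sum(diag(crossprod(A, R)))
    yPy <- sum(colSums(P) * rowSums(Yh^2))
    xPx <- sum(rowSums(P) * rowSums(Xh^2))
    if (estimate_scale) s <- trAR / yPy
    t <- mux - s * as.numeric(R %*% muy)
    sigma2New <- (xPx - s * trAR) / (np * d)
    if (sigma2New <= 0) sigma2New <- tol
    q <- (xPx - 2 * s * trAR + s^2 * yPy) / (2 * sigma2) +
      np * d / 2 * log(sigma2)
    sigma2 <- sigma2New
    if (is.finite(qOld) && abs(qOld - q) < tol * (abs(q) + tol)) {
      converged <- TRUE
      qOld <- q
      break
    }
    qOld <- q
  }
  transform <- structure(list(rotation = R, scale = s, translation = t),
                         class = "rigid_transform")
  aligned <- source
  aligned$points <- applyRigid(transform, Y)
  list(transform = transform, aligned = aligned, converged = converged,
       iterations = it, sigma2 = sigma2)
}

#' Apply a rigid (similarity) transform to points
#' @param transform a `rigid_transform`.
#' @param points M x 3 matrix.
#' @return transformed M x 3 matrix.
#' @export
applyRigid <- function(transform, points) {
  sweep(transform$scale * tcrossprod(points, transform$rotation),
        2L, transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1))
  cat(sprintf("rigid_transform: rotation %.3f rad, scale %.5f, translation (%s)\n",
              ang, x$scale, paste(signif(x$translation, 5), collapse = ", ")))
  invisible(x)
}
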