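#' Reflection-similarity Procrustes alignment
#'
#' Superimposes `query` onto `target` over translation, rotation, reflection
#' and (optionally) scaling — the reflection-similarity shape equivalence —
#' by the closed-form SVD solution, and reports the residual RMSE
#' \eqn{\sqrt{\min_T \sum_i \| x_i - T(y_i)\|^2 / n}}. The convention is
#' asymmetric: the target is held fixed and the query is transformed onto it
#' (the referent-scheme usage for scheme comparisons).
#'
#' @param target A `reconstruction` or n-by-d coordinate matrix (held fixed).
#' @param query A `reconstruction` or n-by-d coordinate matrix in matched
#'   point (bin) order.
#' @param allow_scaling Include a global scale in the transform; default
#'   `TRUE`.
#' @return An object of class `procrustes_result`: list with `rmse`,
#'   `rotation` (d-by-d orthogonal, reflections allowed), `scale`,
#'   `translation`, and `fitted` (the transformed query). The transform maps
#'   query rows y to `scale * y %*% rotation + translation`.
#' @examples
#' X <- matrix(rnorm(30), 10, 3)
#' R <- qr.Q(qr(matrix(rnorm(9), 3)))
#' procrustes_align(X, 2.5 * X %*% R + 1)$rmse   # ~0
#' @export
procrustes_align <- function(target, query, allow_scaling = TRUE) {
  X <- if (inherits(target, "reconstruction")) target$coords else as.matrix(target)
  Y <- if (inherits(query, "reconstruction")) query$coords else as.matrix(query)
  if (!identical(dim(X), dim(Y)))
    stop("target and query must have the same number of points and dimensions")
  n <- nrow(X)
  if (n < 2L) stop("need at least two points")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx)
  Yc <- sweep(Y, 2L, my)
  ssY <- sum(Yc^2)
  if (ssY == 0) stop("degenerate query: all points identical")
  s <- svd(crossprod(Yc, Xc))          # t(Yc) %*% Xc = U D V'
  R <- s$u %*% t(s$v)                  # Yc %*% R aligns to Xc; reflection allowed
  scale <- if (allow_scaling) sum(s$d) / ssY else 1
  fitted_c <- scale * Yc %*% R
  rmse <- sqrt(sum((Xc - fitted_c)^2) / n)
  translation <- mx - as.numeric(scale * my %*% R)
  structure(
    list(rmse = rmse, rotation = R, scale = scale, translation = translation,
         fitted = sweep(fitted_c, 2L, mx, `+`)),
    class = "procrustes_result"
  )
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> rmse %.6g, scale %.4g, det(rotation) %.0f\n",
              x$rmse, x$scale, det(x$rotation)))
  invisible(x)
}
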