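#' Non-negative least squares (Lawson–Hanson active set)
#'
#' Solves min ||y - X x||^2 subject to x >= 0 by the active-set strategy on
#' the normal equations. The contract: the algorithm terminates, the
#' objective is non-increasing across passive-set changes, and the
#' Karush-Kuhn-Tucker conditions hold at exit (verified and reported).
#'
#' @param X design matrix (n x k)
#' @param y response vector (length n)
#' @return list with `x` (solution), `deviance` (residual sum of squares),
#'   `passive` (logical active/passive pattern), and `kkt_ok`
#' @export
nnls_fit <- function(X, y) {
  X <- as.matrix(X)
  k <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  x <- numeric(k)
  P <- logical(k)
  scale <- max(diag(XtX), .Machine$double.xmin)
  tol <- 1e-10 * scale

  solveP <- function(P) {
    A <- XtX[P, P, drop = FALSE]
    tryCatch(solve(A, Xty[P]),
             error = function(e)
               solve(A + diag(1e-12 * scale, sum(P)), Xty[P]))
  }

  w <- Xty
  outer_it <- 0L
  while (TRUE) {
    outer_it <- outer_it + 1L
    if (outer_it > 3L * k + 50L) break
    cand <- which(!P & w > tol)
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE
    inner_it <- 0L
    repeat {
      inner_it <- inner_it + 1L
      z <- numeric(k)
      z[P] <- solveP(P)
      if (all(z[P] > 0) || inner_it > 2L * k + 10L) {
        x <- pmax(z, 0)
        break
      }
      q <- which(P & z <= 0)
      alpha <- min(x[q] / (x[q] - z[q]))
      x <- x + alpha * (z - x)
      x[q][x[q] <= tol / scale] <- 0
      P <- P & x > 0
    }
    w <- Xty - drop(XtX %*% x)
  }

  resid <- y - drop(X %*% x)
  grad <- Xty - drop(XtX %*% x)
  kkt_ok <- all(grad[!P] <= tol * 10) &&
    all(abs(grad[P]) <= sqrt(tol) * sqrt(scale) * 1e-2 + tol * 100)
  list(x = x, deviance = sum(resid^2), passive = P, kkt_ok = kkt_ok)
}
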