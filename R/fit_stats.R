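# Quality-of-fit statistics reported alongside the distribution: overall and
# per-scan rmsd, runs-test Z of the residual sign sequence, and a histogram
# statistic comparing the residual distribution to a Gaussian.

#' Overall and per-scan rmsd statistics
#'
#' @param residuals list of per-scan residual vectors (scan order)
#' @return list of class `sv_fitstats` with `RMSD`, `RMSD_points`,
#'   `RMSD_SSR` and a `per_scan` data.frame (scan, n, rmsd); the identities
#'   RMSD = sqrt(SSR/points) and sum of per-scan SSRs = SSR hold by
#'   construction
#' @export
rmsd_stats <- function(residuals) {
  if (!length(residuals)) sv_value_error("no residuals")
  ssr_scan <- vapply(residuals, function(r) sum(r^2), numeric(1))
  n_scan <- vapply(residuals, length, integer(1))
  ssr <- sum(ssr_scan)
  n <- sum(n_scan)
  structure(list(
    RMSD = sqrt(ssr / n),
    RMSD_points = n,
    RMSD_SSR = ssr,
    per_scan = data.frame(scan = seq_along(residuals), n = n_scan,
                          rmsd = sqrt(ssr_scan / n_scan))
  ), class = "sv_fitstats")
}

#' Wald–Wolfowitz runs test of the residual sign sequence
#'
#' Z = (R - mu)/sigma with mu = 2 n+ n-/n + 1 and
#' sigma^2 = 2 n+ n- (2 n+ n- - n) / (n^2 (n - 1)), computed on the signs of
#' the residual sequence ordered scan by scan, ascending radius within each
#' scan. Zeros are excluded. A single-sign sequence yields an undefined
#' (flagged) result rather than an error.
#'
#' @param residuals ordered residual vector (scan-major, radius-ascending)
#' @return list with `z`, `defined`, `runs`, `n_pos`, `n_neg`
#' @export
runs_test_z <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n_pos <- sum(s > 0); n_neg <- sum(s < 0)
  n <- n_pos + n_neg
  if (n_pos == 0 || n_neg == 0 || n < 2)
    return(list(z = NA_real_, defined = FALSE,
                runs = if (n > 0) 1L else 0L, n_pos = n_pos, n_neg = n_neg))
  runs <- 1L + sum(diff(s) != 0)
  mu <- 2 * n_pos * n_neg / n + 1
  sig2 <- 2 * n_pos * n_neg * (2 * n_pos * n_neg - n) / (n^2 * (n - 1))
  list(z = (runs - mu) / sqrt(sig2), defined = TRUE, runs = runs,
       n_pos = n_pos, n_neg = n_neg)
}

#' Histogram Gaussianity statistic H
#'
#' Residuals are standardized, binned by Scott's rule, and the unit-area
#' histogram is compared with the standard normal density at the bin
#' centers; H is the root-mean-square deviation. H is non-negative,
#' scale-invariant, and zero only for exact agreement. This definition is a
#' documented stand-in with the qualitative meaning "0 = Gaussian-like"; it
#' is not claimed to be numerically identical to the statistic of other
#' SV-AUC software. Requires at least 30 residuals.
#'
#' @param residuals pooled residual vector
#' @return list with `h` and `defined`
#' @export
histogram_h <- function(residuals) {
  n <- length(residuals)
  if (n < 30) return(list(h = NA_real_, defined = FALSE))
  s <- sd(residuals)
  if (!is.finite(s) || s == 0) return(list(h = NA_real_, defined = FALSE))
  z <- (residuals - mean(residuals)) / s
  w <- 3.49 * n^(-1 / 3)          # Scott's rule on the standardized scale
  breaks <- seq(floor(min(z) / w) * w, max(z) + w, by = w)
  counts <- hist(z, breaks = breaks, plot = FALSE)$counts
  dens <- counts / (n * w)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  list(h = sqrt(mean((dens - dnorm(centers))^2)), defined = TRUE)
}
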