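#' Regularization specification
#'
#' @param kind `"maxent"` (maximum entropy) or `"Tikhonov"`
#'   (Tikhonov-Phillips, second differences)
#' @param p_value F-statistics p-value scaling the tolerated SSR increase,
#'   between 0.5 and 1.0
#' @param suppress_baseline Bayesian suppression of the correlation between
#'   baselines and the smallest grid s-value (strong prior toward zero at
#'   the first node)
#' @return object of class `sv_regspec`
#' @export
regularization_spec <- function(kind = c("maxent", "Tikhonov"),
                                p_value = 0.68, suppress_baseline = FALSE) {
  kind <- match.arg(kind)
  if (p_value < 0.5 || p_value > 1.0)
    sv_value_error("regularization p-value must be between 0.5 and 1.0")
  structure(list(kind = kind, p_value = p_value,
                 suppress_baseline = isTRUE(suppress_baseline)),
            class = "sv_regspec")
}

# trapezoidal node weights of an ascending grid
sv_grid_weights <- function(values) {
  K <- length(values)
  if (K == 1) return(1)
  w <- numeric(K)
  w[1] <- (values[2] - values[1]) / 2
  w[K] <- (values[K] - values[K - 1]) / 2
  if (K > 2) w[2:(K - 1)] <- (values[3:K] - values[1:(K - 2)]) / 2
  w
}

# systematic-noise design: TI offsets (one per distinct radius), RI offsets
# (one per scan), and a spatio-temporally uniform baseline
sv_noise_design <- function(row_index, ti, ri, baseline) {
  n <- nrow(row_index)
  radii_lv <- sort(unique(row_index$radius))
  scans_lv <- sort(unique(row_index$scan))
  blocks <- list(); roles <- list()
  if (ti) {
    M <- matrix(0, n, length(radii_lv))
    M[cbind(seq_len(n), match(row_index$radius, radii_lv))] <- 1
    blocks$ti <- M
  }
  if (ri) {
    M <- matrix(0, n, length(scans_lv))
    M[cbind(seq_len(n), match(row_index$scan, scans_lv))] <- 1
    blocks$ri <- M
  }
  if (baseline) blocks$baseline <- matrix(1, n, 1)
  if (!length(blocks))
    return(list(N = NULL, roles = NULL, radii = radii_lv, scans = scans_lv))
  N <- do.call(cbind, blocks)
  sizes <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(sizes)
  roles <- Map(function(a, b) a:b, ends - sizes + 1L, ends)
  names(roles) <- names(blocks)
  list(N = N, roles = roles, radii = radii_lv, scans = scans_lv)
}

#' Regularized non-negative inversion for c(s) / ls-g*(s)
#'
#' Solves min || y - X c - TI(r) - RI(t) - b ||^2 subject to c >= 0, where X
#' holds the unit-loading kernel columns of the design matrix, TI/RI/b are
#' the optional systematic-noise terms (included per flags), and c is the
#' distribution (signal density per svedberg; internally the kernel columns
#' are scaled by the trapezoidal node weights so the unknowns are densities).
#'
#' The systematic noise is eliminated algebraically: data and kernels are
#' projected onto the orthogonal complement of the noise subspace (pivoted
#' QR), the non-negative solve runs on the projected system, and the noise
#' components are recovered by least squares on the residual.
#'
#' The regularization weight lambda is chosen as the largest value whose
#' (data-part) SSR does not exceed SSR(lambda->0) times the variance-ratio
#' F(p; nu, nu), nu = points - model parameters, located by bisection on
#' log lambda to 0.1% of the target SSR. Tikhonov penalizes second
#' differences of c; maximum entropy penalizes sum c_i log(c_i / cbar)
#' (cbar = total signal / grid span) via iterated reweighting. With
#' `suppress_baseline`, a strong additional prior (x1000 weight) pins the
#' smallest grid node toward zero.
#'
#' @param scanset an `sv_scanset` (restricted to the fit range) whose rows
#'   match the design matrix
#' @param design an `sv_design` from [build_design_matrix()]
#' @param reg an [regularization_spec()], or `NULL` for the unregularized fit
#' @param ti,ri,baseline noise-component flags
#' @param projector optional precomputed `qr()` of the noise design (reused
#'   across repeated fits on the same scan set)
#' @return an object of class `sv_distfit`
#' @export
fit_linear <- function(scanset, design, reg = NULL,
                       ti = TRUE, ri = TRUE, baseline = FALSE,
                       projector = NULL) {
  y <- unlist(lapply(scanset$scans, `[[`, "signal"))
  if (length(y) != nrow(design$columns))
    sv_value_error("design matrix rows (%d) do not match data points (%d)",
                   nrow(design$columns), length(y))
  grid <- design$grid
  K <- length(grid$values)
  wts <- sv_grid_weights(grid$values)
  Xe <- sweep(design$columns, 2, wts, "*")

  nd <- sv_noise_design(design$row_index, ti, ri, baseline)
  if (!is.null(nd$N)) {
    qN <- if (!is.null(projector)) projector else qr(nd$N)
    Py <- qr.resid(qN, y)
    PXe <- qr.resid(qN, Xe)
    rankN <- qN$rank
  } else {
    qN <- NULL; Py <- y; PXe <- Xe; rankN <- 0L
  }
  Npts <- length(y)

  kappa <- getOption("svengine.baseline_prior_weight", 1e3)
  supp <- !is.null(reg) && isTRUE(reg$suppress_baseline)
  e1 <- matrix(0, 1, K); e1[1, 1] <- 1

  fit0 <- nnls_fit(PXe, Py)
  ssr0 <- fit0$deviance
  degenerate <- max(abs(Py)) < 1e-12 || sum(fit0$x * wts) <= 0

  solve_tikhonov <- function(lam) {
    L <- matrix(0, max(K - 2, 0), K)
    if (K > 2)
      for (i in seq_len(K - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
    Xa <- rbind(PXe, sqrt(lam) * L)
    ya <- c(Py, rep(0, nrow(L)))
    if (supp) { Xa <- rbind(Xa, sqrt(lam) * kappa * e1); ya <- c(ya, 0) }
    f <- nnls_fit(Xa, ya)
    r <- Py - drop(PXe %*% f$x)
    list(x = f$x, ssr = sum(r^2))
  }

  solve_maxent <- function(lam, cbar, xstart) {
    floor_c <- cbar * 1e-6
    x <- pmax(xstart, cbar * 1e-3)
    for (it in seq_len(80)) {
      xs <- pmax(x, floor_c)
      wgt <- sqrt(lam / (2 * xs))
      tgt <- -xs * log(xs / cbar)
      Xa <- rbind(PXe, diag(wgt, K))
      ya <- c(Py, wgt * tgt)
      if (supp) { Xa <- rbind(Xa, sqrt(lam) * kappa * e1); ya <- c(ya, 0) }
      f <- nnls_fit(Xa, ya)
      xn <- f$x
      delta <- max(abs(xn - x))
      x <- xn
      if (delta <= 1e-3 * (max(x) + 1e-15)) {
        r <- Py - drop(PXe %*% x)
        return(list(x = x, ssr = sum(r^2)))
      }
    }
    sv_solver_error("maximum-entropy reweighting did not converge in 80 iterations")
  }

  lambda_used <- 0
  x <- fit0$x
  if (degenerate) {
    if (max(abs(Py)) < 1e-12) {
      warning("no signal left after noise elimination; returning zero distribution",
              call. = FALSE)
      x <- numeric(K)
    }
  } else if (!is.null(reg)) {
    nu <- Npts - (K + rankN)
    if (nu < 1) {
      warning("no residual degrees of freedom; skipping regularization",
              call. = FALSE)
    } else {
      Fr <- qf(reg$p_value, nu, nu)
      target <- ssr0 * Fr
      # normalized lambda scale: penalty curvature comparable to data curvature
      data_curv <- mean(colSums(PXe^2))
      if (reg$kind == "Tikhonov") {
        sc <- data_curv / 6        # mean diagonal of L'L for (1,-2,1) rows
        g <- function(lp) solve_tikhonov(lp * sc)
      } else {
        tot0 <- sum(fit0$x * wts)
        cbar <- tot0 / (max(grid$values) - min(grid$values))
        sc <- data_curv * 2 * cbar
        g <- function(lp) solve_maxent(lp * sc, cbar, fit0$x)
      }
      lo <- 1e-6; hi <- 1e6
      f_lo <- g(lo)
      if (f_lo$ssr > target) {
        warning("regularization target SSR unreachable; using minimal weight",
                call. = FALSE)
        x <- f_lo$x; lambda_used <- lo * sc
      } else {
        f_hi <- g(hi)
        if (f_hi$ssr <= target) {
          warning("regularization target SSR not exceeded at maximal weight",
                  call. = FALSE)
          x <- f_hi$x; lambda_used <- hi * sc
        } else {
          best <- f_lo
          for (it in seq_len(60)) {
            mid <- sqrt(lo * hi)
            f_mid <- g(mid)
            if (f_mid$ssr <= target) { lo <- mid; best <- f_mid } else hi <- mid
            if (abs(best$ssr - target) <= 1e-3 * target) break
          }
          x <- best$x; lambda_used <- lo * sc
        }
      }
    }
  }

  # recover systematic noise by least squares on the distribution residual
  d <- y - drop(Xe %*% x)
  ti_vals <- rep(0, length(nd$radii))
  ri_vals <- rep(0, length(nd$scans))
  b0 <- 0
  if (!is.null(nd$N)) {
    beta <- qr.coef(qN, d)
    beta[is.na(beta)] <- 0
    if (!is.null(nd$roles$ti)) ti_vals <- beta[nd$roles$ti]
    if (!is.null(nd$roles$ri)) ri_vals <- beta[nd$roles$ri]
    if (!is.null(nd$roles$baseline)) b0 <- beta[nd$roles$baseline]
    # identifiability convention for the collinear constant component
    if (ri && (ti || baseline)) {
      mri <- mean(ri_vals); ri_vals <- ri_vals - mri
      if (baseline) b0 <- b0 + mri else ti_vals <- ti_vals + mri
    }
    if (ti && baseline) {
      mti <- mean(ti_vals); ti_vals <- ti_vals - mti; b0 <- b0 + mti
    }
  }

  noise_fit <- rep(b0, Npts)
  if (length(nd$radii))
    noise_fit <- noise_fit + ti_vals[match(design$row_index$radius, nd$radii)]
  if (length(nd$scans))
    noise_fit <- noise_fit + ri_vals[match(design$row_index$scan, nd$scans)]

  fitted <- drop(Xe %*% x) + noise_fit
  residuals <- y - fitted
  times <- vapply(scanset$scans, `[[`, numeric(1), "time_s")

  structure(list(
    grid = grid,
    c = x,
    amounts = x * wts,
    weights = wts,
    ti_noise = data.frame(radius = nd$radii, value = ti_vals),
    ri_noise = data.frame(scan = nd$scans, time = times[nd$scans],
                          value = ri_vals),
    baseline = b0,
    ssr = sum(residuals^2),
    unregularized_ssr = ssr0,
    lambda = lambda_used,
    fitted = fitted,
    residuals = residuals,
    row_index = design$row_index,
    flags = list(ti = ti, ri = ri, baseline = baseline),
    n_points = Npts,
    rank_noise = rankN,
    model = design$model,
    reg = reg
  ), class = "sv_distfit")
}

#' Fold fitted noise into file-ready tables
#'
#' @param result an `sv_distfit`
#' @param scanset the fitted `sv_scanset` (scan times for the RI table)
#' @return list with `ti` (radius, value) and `ri` (time, value) data frames
#' @export
fold_noise <- function(result, scanset) {
  times <- vapply(scanset$scans, `[[`, numeric(1), "time_s")
  list(
    ti = data.frame(radius = result$ti_noise$radius,
                    value = result$ti_noise$value),
    ri = data.frame(time = times[result$ri_noise$scan],
                    value = result$ri_noise$value)
  )
}

# exact integral of the piecewise-linear density over [lo, hi];
# moment = 1 integrates s * c(s) (trapezoid on the product)
sv_pl_integral <- function(xs, ys, lo, hi, moment = 0) {
  yl <- approx(xs, ys, xout = lo, rule = 2)$y
  yh <- approx(xs, ys, xout = hi, rule = 2)$y
  sel <- xs > lo & xs < hi
  xx <- c(lo, xs[sel], hi)
  yy <- c(yl, ys[sel], yh)
  if (moment == 1) yy <- yy * xx
  sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' Integrate a distribution over an s-window
#'
#' Trapezoidal integration of the fitted distribution over
#' `[s_lo, s_hi]`, returning the integrated signal, its percentage of the
#' total integrated signal, and the signal-weighted mean sedimentation
#' coefficient s_w of the window.
#'
#' @param result an `sv_distfit` (or any list with `grid` and `c`)
#' @param s_lo,s_hi window limits, svedberg, `s_lo < s_hi`, overlapping the
#'   grid span
#' @return list with `fraction` (percent), `sw` (svedberg, `NA` when the
#'   window holds no mass, see `defined`), `load` (signal), `defined`
#' @export
integrate_distribution <- function(result, s_lo, s_hi) {
  g <- result$grid$values
  cc <- result$c
  if (!(s_lo < s_hi)) sv_value_error("integration window requires s_lo < s_hi")
  lo <- max(s_lo, min(g)); hi <- min(s_hi, max(g))
  if (!(lo < hi)) sv_value_error("integration window is outside the grid span")
  load <- sv_pl_integral(g, cc, lo, hi)
  total <- sv_pl_integral(g, cc, min(g), max(g))
  frac <- if (total > 0) 100 * load / total else 0
  sw <- if (load > 0) sv_pl_integral(g, cc, lo, hi, moment = 1) / load
        else NA_real_
  list(fraction = frac, sw = sw, load = load, defined = load > 0)
}
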