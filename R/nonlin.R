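# Outer nonlinear regression over meniscus, bottom and frictional ratio.
# Both optimizers enforce bounds by projection and treat objective failures
# at a trial point as a large penalty rather than an error.

sv_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sv_safe_eval <- function(objective, x) {
  v <- tryCatch(objective(x), error = function(e) Inf)
  if (!is.finite(v)) Inf else v
}

#' Nelder–Mead minimization with seeded initialization and bound projection
#'
#' The initial simplex is built by a seeded random perturbation (within 2%
#' of each parameter's bound span) of the starting point, so repeat runs
#' with the same seed are bit-identical. All trial points are projected onto
#' the bounds. Convergence: relative improvement of the best vertex below
#' `tol` over `stall` consecutive iterations, or `maxit` iterations. A
#' degenerate simplex triggers one restart before non-convergence is
#' reported.
#'
#' @param objective function of the parameter vector returning a scalar SSR
#' @param x0 starting parameter vector
#' @param lower,upper bounds (same length as `x0`)
#' @param seed integer seed for the initial randomization
#' @param maxit iteration cap
#' @param tol relative improvement threshold
#' @param stall iterations over which improvement is measured
#' @return list with `par`, `value`, and `trace` (steps, converged, text)
#' @export
simplex_minimize <- function(objective, x0, lower, upper, seed = 1L,
                             maxit = 200L, tol = 1e-6, stall = 5L) {
  n <- length(x0)
  clamp <- function(x) pmin(pmax(x, lower), upper)
  x0 <- clamp(x0)
  span <- upper - lower
  span[span <= 0] <- pmax(abs(x0[span <= 0]), 1)

  init_simplex <- function() {
    V <- vector("list", n + 1)
    V[[1]] <- x0
    for (i in seq_len(n)) {
      xi <- x0
      xi[i] <- xi[i] + runif(1, -1, 1) * 0.02 * span[i]
      V[[i + 1]] <- clamp(xi)
    }
    V
  }

  run_nm <- function(V) {
    fv <- vapply(V, function(x) sv_safe_eval(objective, x), numeric(1))
    steps <- list()
    hist_best <- numeric()
    converged <- FALSE
    it <- 0L
    while (it < maxit) {
      it <- it + 1L
      ord <- order(fv)
      V <- V[ord]; fv <- fv[ord]
      steps[[length(steps) + 1]] <- list(par = V[[1]], ssr = fv[1])
      hist_best <- c(hist_best, fv[1])
      nh <- length(hist_best)
      if (nh > stall &&
          (hist_best[nh - stall] - hist_best[nh]) <=
            tol * max(abs(hist_best[nh]), 1e-300)) {
        converged <- TRUE
        break
      }
      if (max(vapply(V[-1], function(x) max(abs(x - V[[1]])), numeric(1))) <
          1e-12 * max(1, max(abs(V[[1]]))))
        break  # degenerate simplex
      centroid <- Reduce(`+`, V[-(n + 1)]) / n
      xr <- clamp(centroid + (centroid - V[[n + 1]]))
      fr <- sv_safe_eval(objective, xr)
      if (fr < fv[1]) {
        xe <- clamp(centroid + 2 * (centroid - V[[n + 1]]))
        fe <- sv_safe_eval(objective, xe)
        if (fe < fr) { V[[n + 1]] <- xe; fv[n + 1] <- fe }
        else { V[[n + 1]] <- xr; fv[n + 1] <- fr }
      } else if (fr < fv[n]) {
        V[[n + 1]] <- xr; fv[n + 1] <- fr
      } else {
        xc <- clamp(centroid + 0.5 * (V[[n + 1]] - centroid))
        fc <- sv_safe_eval(objective, xc)
        if (fc < fv[n + 1]) { V[[n + 1]] <- xc; fv[n + 1] <- fc }
        else {
          for (i in 2:(n + 1)) {
            V[[i]] <- clamp(V[[1]] + 0.5 * (V[[i]] - V[[1]]))
            fv[i] <- sv_safe_eval(objective, V[[i]])
          }
        }
      }
    }
    list(V = V, fv = fv, steps = steps, converged = converged, iters = it)
  }

  res <- sv_with_seed(seed, {
    r1 <- run_nm(init_simplex())
    if (!r1$converged) {
      r2 <- run_nm(init_simplex())   # one restart on non-convergence
      if (r2$fv[1] < r1$fv[1]) r2 else r1
    } else r1
  })

  ord <- order(res$fv)
  best <- res$V[[ord[1]]]; fbest <- res$fv[ord[1]]
  txt <- sprintf("Simplex: %d iterations, converged=%s, final SSR %.6e",
                 res$iters, res$converged, fbest)
  list(par = best, value = fbest,
       trace = list(steps = res$steps, converged = res$converged, text = txt))
}

#' Levenberg–Marquardt minimization with bound projection
#'
#' Damped Gauss–Newton on the residual vector, with forward-difference
#' Jacobians (relative step `1e-4` of the bound span), multiplicative
#' damping adaptation, and bound projection of every trial point. Converges
#' when the relative SSR improvement falls below `tol` over `stall`
#' accepted steps, or when the predicted decrease is negligible (a start at
#' the optimum is then reported as converged with zero accepted steps).
#'
#' @param resid_fn function returning the residual vector at a parameter
#'   vector
#' @param x0 starting parameter vector
#' @param lower,upper bounds
#' @param maxit iteration cap
#' @param tol relative improvement threshold
#' @param stall iterations over which improvement is measured
#' @return list with `par`, `value` (SSR), and `trace`
#' @export
lm_minimize <- function(resid_fn, x0, lower, upper,
                        maxit = 200L, tol = 1e-6, stall = 5L) {
  n <- length(x0)
  clamp <- function(x) pmin(pmax(x, lower), upper)
  span <- upper - lower
  span[span <= 0] <- pmax(abs(x0[span <= 0]), 1)
  h <- 1e-4 * span

  safe_resid <- function(x) {
    r <- tryCatch(resid_fn(x), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) NULL else r
  }

  x <- clamp(x0)
  r <- safe_resid(x)
  if (is.null(r)) sv_value_error("objective not finite at the starting point")
  ssr <- sum(r^2)
  steps <- list(list(par = x, ssr = ssr))
  hist_ssr <- ssr
  mu <- 1e-3
  converged <- FALSE
  accepted <- 0L
  it <- 0L

  while (it < maxit) {
    it <- it + 1L
    J <- matrix(0, length(r), n)
    ok <- TRUE
    for (i in seq_len(n)) {
      hi <- h[i]
      xi <- x
      if (xi[i] + hi > upper[i]) hi <- -hi  # step inward at the upper bound
      xi[i] <- xi[i] + hi
      ri <- safe_resid(clamp(xi))
      if (is.null(ri)) { ok <- FALSE; break }
      J[, i] <- (ri - r) / hi
    }
    if (!ok) break
    g <- drop(crossprod(J, r))
    H <- crossprod(J)
    dH <- diag(H)
    dH[dH <= 0] <- max(dH, 1e-300)
    improved <- FALSE
    for (try in seq_len(10)) {
      A <- H + mu * diag(dH, n)
      delta <- tryCatch(-solve(A, g), error = function(e) NULL)
      if (is.null(delta)) { mu <- mu * 5; next }
      pred <- -(sum(g * delta) + 0.5 * sum(delta * drop(H %*% delta)))
      trial <- clamp(x + delta)
      rt <- safe_resid(trial)
      if (!is.null(rt) && sum(rt^2) < ssr) {
        x <- trial; r <- rt; ssr <- sum(rt^2)
        mu <- max(mu / 3, 1e-12)
        improved <- TRUE
        accepted <- accepted + 1L
        steps[[length(steps) + 1]] <- list(par = x, ssr = ssr)
        hist_ssr <- c(hist_ssr, ssr)
        break
      }
      if (pred <= 1e-10 * (ssr + 1e-300)) {  # at a (projected) optimum
        converged <- TRUE
        break
      }
      mu <- mu * 5
    }
    if (converged) break
    if (!improved) { converged <- accepted > 0L || max(abs(g)) == 0; break }
    nh <- length(hist_ssr)
    if (nh > stall &&
        (hist_ssr[nh - stall] - hist_ssr[nh]) <=
          tol * max(hist_ssr[nh], 1e-300)) {
      converged <- TRUE
      break
    }
  }

  txt <- sprintf(
    "Levenberg-Marquardt: %d iterations (%d accepted), converged=%s, final SSR %.6e",
    it, accepted, converged, ssr)
  list(par = x, value = ssr,
       trace = list(steps = steps, converged = converged, text = txt))
}

#' Outer nonlinear regression of meniscus, bottom and frictional ratio
#'
#' Wraps the linear distribution fit as the objective of a bounded
#' nonlinear regression over whichever of meniscus, bottom and frictional
#' ratio are flagged for fitting in the request. With no flags set a single
#' linear fit at the initial parameters is performed (Run behavior; setting
#' AutoFit additionally runs the optimizer). During the optimization the
#' objective is the unregularized SSR; the returned distribution is the
#' regularized fit at the best-fit parameters.
#'
#' @param req a validated `sv_request`
#' @param scanset an `sv_scanset` restricted to the fit range
#' @param grid an `sv_sgrid`
#' @param cond a [solution_conditions()] object
#' @param seed integer seed for the Simplex initial randomization
#' @param n_radial radial nodes of the Lamm kernels
#' @return list with `par` (named Meniscus/Bottom/FrictionalRatio), `dist`
#'   (the final `sv_distfit`), and `trace`
#' @export
optimize_parameters <- function(req, scanset, grid, cond, seed = 1L,
                                n_radial = 180L) {
  fit_flags <- c(meniscus = isTRUE(req$MeniscusFitted),
                 bottom = isTRUE(req$BottomFitted),
                 ffr = isTRUE(req$FrictionalRatioFitted) &&
                       identical(req$Model, "cofs"))
  full <- c(meniscus = req$Meniscus, bottom = req$Bottom,
            ffr = req$StartingFrictionalRatio)
  lowers <- c(meniscus = req$MeniscusLowerLimit, bottom = req$BottomLowerLimit,
              ffr = 1.0)
  uppers <- c(meniscus = req$MeniscusUpperLimit, bottom = req$BottomUpperLimit,
              ffr = 10.0)

  ti <- isTRUE(req$TINoiseFitted); ri <- isTRUE(req$RINoiseFitted)
  bl <- isTRUE(req$BaselineFitted)
  nd <- sv_noise_design(data.frame(
    scan = rep(seq_along(scanset$scans),
               vapply(scanset$scans, function(s) length(s$radii), integer(1))),
    radius = unlist(lapply(scanset$scans, `[[`, "radii"))), ti, ri, bl)
  projector <- if (!is.null(nd$N)) qr(nd$N) else NULL

  eval_at <- function(theta) {
    p <- full
    p[names(theta)] <- theta
    design <- build_design_matrix(grid, req$Model, p[["ffr"]], cond,
                                  cell_geometry(p[["meniscus"]], p[["bottom"]]),
                                  rpm = scanset$scans[[1]]$rpm,
                                  scanset = scanset, n_radial = n_radial)
    fit_linear(scanset, design, reg = NULL, ti = ti, ri = ri, baseline = bl,
               projector = projector)
  }

  active <- names(fit_flags)[fit_flags]
  if (length(active)) {
    x0 <- full[active]
    lo <- lowers[active]; up <- uppers[active]
    if (identical(req$FittingAlgorithm, "Levenberg-Marquardt")) {
      opt <- lm_minimize(function(th) {
        names(th) <- active
        eval_at(th)$residuals
      }, x0, lo, up)
    } else {
      opt <- simplex_minimize(function(th) {
        names(th) <- active
        fit <- tryCatch(eval_at(th), error = function(e) NULL)
        if (is.null(fit)) Inf else fit$ssr
      }, x0, lo, up, seed = seed)
    }
    full[active] <- pmin(pmax(opt$par, lo), up)
    trace <- opt$trace
  } else {
    trace <- list(steps = list(), converged = TRUE,
                  text = "Run: single linear fit, no nonlinear parameters")
  }

  geom <- cell_geometry(full[["meniscus"]], full[["bottom"]])
  design <- build_design_matrix(grid, req$Model, full[["ffr"]], cond, geom,
                                rpm = scanset$scans[[1]]$rpm,
                                scanset = scanset, n_radial = n_radial)
  reg <- regularization_spec(req$RegularizationType, req$RegularizationPvalue,
                             req$SuppressBaselineCorrelation)
  dist <- fit_linear(scanset, design, reg = reg, ti = ti, ri = ri,
                     baseline = bl, projector = projector)
  if (!length(active))
    trace$text <- sprintf("%s, SSR %.6e", trace$text, dist$unregularized_ssr)

  list(par = c(Meniscus = full[["meniscus"]], Bottom = full[["bottom"]],
               FrictionalRatio = full[["ffr"]]),
       dist = dist, trace = trace)
}
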