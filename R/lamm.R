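# Finite-element discretization of the Lamm equation
#   dc/dt = (1/r) d/dr [ r ( D dc/dr - s w^2 r c ) ]
# on [meniscus, bottom] with zero-flux boundaries. Hat functions on a
# log-spaced radial grid; weak form gives  B dc/dt = -(D A1 - s w^2 A2) c
# with B_jk = Int phi_j phi_k r dr, A1_jk = Int phi'_j phi'_k r dr,
# A2_jk = Int phi'_j phi_k r^2 dr. All element integrals are evaluated by
# 2-point Gauss quadrature, exact for the cubic integrands involved.

# D_elem: per-element diffusion coefficient multiplying the A1 (stiffness)
# contributions; used for exponentially fitted streamline stabilization.
fem_tridiag <- function(r, D_elem = 1) {
  n <- length(r)
  a <- r[-n]; b <- r[-1]
  h <- b - a
  if (length(D_elem) == 1) D_elem <- rep(D_elem, n - 1)
  gp <- c(-1, 1) / sqrt(3)

  zl <- numeric(n - 1)
  B  <- list(ll = zl, lr = zl, rr = zl)
  A1 <- list(ll = zl, lr = zl, rr = zl)
  A2 <- list(ll = zl, lr = zl, rl = zl, rr = zl)

  for (g in gp) {
    x <- (a + b) / 2 + g * h / 2
    w <- h / 2
    pl <- (b - x) / h; pr <- (x - a) / h        # hat values
    dl <- -1 / h;      dr <- 1 / h              # hat derivatives
    B$ll <- B$ll + w * pl * pl * x
    B$lr <- B$lr + w * pl * pr * x
    B$rr <- B$rr + w * pr * pr * x
    A1$ll <- A1$ll + D_elem * w * dl * dl * x
    A1$lr <- A1$lr + D_elem * w * dl * dr * x
    A1$rr <- A1$rr + D_elem * w * dr * dr * x
    x2 <- x * x
    A2$ll <- A2$ll + w * dl * pl * x2           # row: derivative index
    A2$lr <- A2$lr + w * dl * pr * x2
    A2$rl <- A2$rl + w * dr * pl * x2
    A2$rr <- A2$rr + w * dr * pr * x2
  }

  asm <- function(ll, rr, up, lo) {
    d <- numeric(n)
    d[1:(n - 1)] <- d[1:(n - 1)] + ll
    d[2:n] <- d[2:n] + rr
    list(dl = lo, d = d, du = up)
  }
  list(
    B  = asm(B$ll, B$rr, B$lr, B$lr),
    A1 = asm(A1$ll, A1$rr, A1$lr, A1$lr),
    A2 = asm(A2$ll, A2$rr, A2$lr, A2$rl)
  )
}

#' Solve the Lamm equation for a single species
#'
#' Crank–Nicolson finite-element solution of sedimentation-diffusion
#' transport in a sector-shaped cell, starting from a uniform unit loading
#' concentration, with zero-flux conditions at meniscus and bottom. The time
#' step is bounded so that the sedimentation boundary moves at most one
#' radial cell per step.
#'
#' @param s sedimentation coefficient, svedberg (>= 0)
#' @param D diffusion coefficient, cm^2/s (>= 0)
#' @param geom a [cell_geometry()] object
#' @param rpm rotor speed, revolutions per minute
#' @param times non-negative, increasing vector of solution times, s
#' @param n_radial number of radial nodes (>= 50)
#' @return an object of class `sv_lamm` with fields `radii` (cm), `times`
#'   (s), and `concentration` (time-by-radius matrix, unit loading)
#' @export
solve_lamm <- function(s, D, geom, rpm, times, n_radial = 180L) {
  if (s < 0) sv_value_error("floating species (s < 0) are not supported")
  if (D < 0) sv_value_error("diffusion coefficient must be non-negative")
  if (n_radial < 50) sv_value_error("n_radial must be at least 50")
  if (is.unsorted(times, strictly = FALSE) || any(times < 0))
    sv_value_error("times must be non-negative and non-decreasing")

  m <- geom$meniscus; b <- geom$bottom
  r <- exp(seq(log(m), log(b), length.out = n_radial))
  nt <- length(times)

  s_sec <- s * .svedberg
  omega2 <- (rpm * pi / 30)^2

  if ((s_sec * omega2 == 0 && D == 0) || max(times) == 0) {
    conc <- matrix(1, nt, n_radial)
    return(structure(list(radii = r, times = times, concentration = conc),
                     class = "sv_lamm"))
  }

  # Critical streamline stabilization: elements whose cell Peclet number
  # Pe = v h / 2D (v = s w^2 r) exceeds 1 receive the minimal artificial
  # diffusion (v h / 2)(1 - 1/Pe) that keeps the advection-dominated limit
  # stable; resolved elements (Pe <= 1) use the exact Galerkin operator, so
  # well-resolved kernels carry no numerical broadening. The addition is
  # O(h) only where the grid underresolves a boundary and vanishes under
  # refinement.
  h_el <- diff(r)
  r_mid <- (r[-1] + r[-n_radial]) / 2
  v_el <- s_sec * omega2 * r_mid
  D_el <- if (D > 0) {
    pe <- v_el * h_el / (2 * D)
    D + (v_el * h_el / 2) * pmax(0, 1 - 1 / pmax(pe, 1e-12))
  } else {
    v_el * h_el / 2
  }
  fm <- fem_tridiag(r, D_elem = D_el)
  A <- list(
    dl = fm$A1$dl - s_sec * omega2 * fm$A2$dl,
    d  = fm$A1$d  - s_sec * omega2 * fm$A2$d,
    du = fm$A1$du - s_sec * omega2 * fm$A2$du
  )

  tmax <- max(times)
  hmin <- min(diff(r))
  v_b <- s_sec * omega2 * b                     # boundary speed at the bottom
  dt <- if (v_b > 0) hmin / v_b else Inf
  dt <- min(dt, tmax / 20)
  nsteps <- ceiling(tmax / dt)
  if (!is.finite(nsteps) || nsteps > 5e5)
    sv_solver_error("unstable step configuration: %g time steps required", nsteps)
  dt <- tmax / nsteps

  M1 <- list(dl = fm$B$dl + dt / 2 * A$dl,
             d  = fm$B$d  + dt / 2 * A$d,
             du = fm$B$du + dt / 2 * A$du)
  M2 <- list(dl = fm$B$dl - dt / 2 * A$dl,
             d  = fm$B$d  - dt / 2 * A$d,
             du = fm$B$du - dt / 2 * A$du)

  conc <- lamm_cn_march(M1$dl, M1$d, M1$du, M2$dl, M2$d, M2$du,
                        rep(1, n_radial), dt, as.integer(nsteps),
                        as.numeric(times))
  structure(list(radii = r, times = times, concentration = conc),
            class = "sv_lamm")
}

#' Non-diffusing step boundary profile
#'
#' Closed-form single-species profile in the absence of diffusion: zero below
#' the boundary position m*exp(s w^2 t) and the radially diluted plateau
#' exp(-2 s w^2 t) above it. This is the kernel of the apparent ls-g*(s)
#' distribution. When the boundary has moved past the bottom of the cell the
#' solution column is cleared and the profile is zero throughout (the
#' sedimented material piles up at the bottom and is not represented).
#'
#' @param s sedimentation coefficient, svedberg (>= 0)
#' @param geom a [cell_geometry()] object
#' @param rpm rotor speed, rpm
#' @param time time, s
#' @param radii radii at which to evaluate, cm
#' @return concentration vector at `radii` (unit loading)
#' @export
nondiffusing_profile <- function(s, geom, rpm, time, radii) {
  if (s < 0) sv_value_error("floating species (s < 0) are not supported")
  s_sec <- s * .svedberg
  omega2 <- (rpm * pi / 30)^2
  rb <- geom$meniscus * exp(s_sec * omega2 * time)
  if (rb >= geom$bottom) return(rep(0, length(radii)))
  plateau <- exp(-2 * s_sec * omega2 * time)
  ifelse(radii < rb, 0, plateau)
}
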