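#' Solution conditions for hydrodynamic scaling
#'
#' Bundle of solvent and solute properties entering the buoyancy factor and
#' the frictional-ratio scaling law: partial-specific volume (mL/g), solvent
#' density (g/mL), solvent viscosity (poise) and absolute temperature (K).
#'
#' @param vbar partial-specific volume, mL/g
#' @param density solvent density, g/mL
#' @param viscosity solvent viscosity, poise
#' @param temperature absolute temperature, K
#' @return an object of class `sv_conditions`
#' @export
solution_conditions <- function(vbar = 0.73, density = 0.99823,
                                viscosity = 0.01002, temperature = 293.15) {
  if (any(c(vbar, density, viscosity, temperature) <= 0))
    sv_value_error("solution conditions must all be positive")
  if (1 - vbar * density == 0)
    sv_value_error("buoyancy factor (1 - vbar*density) must be non-zero")
  structure(list(vbar = vbar, density = density, viscosity = viscosity,
                 temperature = temperature),
            class = "sv_conditions")
}

#' Cell geometry of the solution column
#'
#' @param meniscus air/solution interface, cm from the center of rotation
#' @param bottom distal end of the solution column, cm
#' @return an object of class `sv_geometry`
#' @export
cell_geometry <- function(meniscus, bottom) {
  if (!(meniscus > 0 && bottom > meniscus))
    sv_value_error("cell geometry requires 0 < meniscus < bottom")
  structure(list(meniscus = meniscus, bottom = bottom), class = "sv_geometry")
}

#' Diffusion coefficient from the constant frictional-ratio scaling law
#'
#' Maps a sedimentation coefficient to a diffusion coefficient assuming all
#' species share one hydrodynamic frictional ratio f/f0:
#' D = (sqrt(2)/18*pi) * kT * s^(-1/2) * (eta*f/f0)^(-3/2) *
#'     ((1 - vbar*rho)/vbar)^(1/2),
#' with s in seconds and all quantities in CGS units. This is the scaling law
#' underlying diffusion-deconvoluted c(s) analysis.
#'
#' @param s sedimentation coefficient, svedberg
#' @param ffr frictional ratio f/f0, dimensionless, >= 1
#' @param cond a [solution_conditions()] object
#' @return diffusion coefficient, cm^2/s
#' @export
diffusion_from_s <- function(s, ffr, cond) {
  if (any(s <= 0)) sv_value_error("sedimentation coefficient must be positive")
  if (any(ffr < 1)) sv_value_error("frictional ratio must be >= 1")
  buoy <- 1 - cond$vbar * cond$density
  if (buoy <= 0)
    sv_value_error("non-positive buoyancy factor; floating species are not supported")
  s_sec <- s * .svedberg
  (sqrt(2) / (18 * pi)) * .kB_cgs * cond$temperature *
    s_sec^(-0.5) * (cond$viscosity * ffr)^(-1.5) * (buoy / cond$vbar)^0.5
}
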