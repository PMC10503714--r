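# Synthetic SV-AUC experiment generator: multi-species sedimentation
# boundaries in a sector-shaped cell plus Gaussian noise, TI/RI systematic
# baselines and isolated data spikes, written as protocol-conformant scan
# files with a ground-truth sidecar. Everything is deterministic under the
# spec's seed. omega^2 t assumes instant rotor acceleration (no ramp).

#' Specify a synthetic SV-AUC experiment
#'
#' @param species data.frame with columns `s` (svedberg), `ffr` (frictional
#'   ratio, used to derive D via the scaling law; alternatively supply a `D`
#'   column in cm^2/s) and `loading` (signal units, >= 0)
#' @param geometry a [cell_geometry()]
#' @param rpm rotor speed
#' @param scan_times increasing scan times, s
#' @param radial_step radial point spacing of the simulated scans, cm
#' @param noise_sigma Gaussian noise s.d., signal units
#' @param ti_amplitude amplitude of the radius-dependent (TI) baseline
#' @param ri_amplitude s.d. of the per-scan (RI) offsets
#' @param n_spikes number of isolated data spikes to inject
#' @param seed integer seed; fixed seed implies byte-identical output
#' @param conditions a [solution_conditions()]
#' @param channel scan file extension to write
#' @param wavelength header wavelength, nm
#' @param temperature_drift total linear temperature drift across scans, deg C
#' @return an object of class `sv_simspec`
#' @export
simulation_spec <- function(species, geometry, rpm, scan_times,
                            radial_step = 0.003, noise_sigma = 0.005,
                            ti_amplitude = 0.01, ri_amplitude = 0.005,
                            n_spikes = 0L, seed = 1L,
                            conditions = solution_conditions(),
                            channel = "ra1", wavelength = 280,
                            temperature_drift = 0.1) {
  stopifnot(is.data.frame(species), all(c("s", "loading") %in% names(species)))
  if (any(species$loading < 0)) sv_value_error("loadings must be >= 0")
  if (any(species$s <= 0)) sv_value_error("species s-values must be positive")
  if (any(diff(scan_times) <= 0) || any(scan_times < 0))
    sv_value_error("scan times must be non-negative and strictly increasing")
  if (!"D" %in% names(species) && !"ffr" %in% names(species))
    sv_value_error("species need either an ffr or a D column")
  structure(list(species = species, geometry = geometry, rpm = rpm,
                 scan_times = scan_times, radial_step = radial_step,
                 noise_sigma = noise_sigma, ti_amplitude = ti_amplitude,
                 ri_amplitude = ri_amplitude, n_spikes = as.integer(n_spikes),
                 seed = as.integer(seed), conditions = conditions,
                 channel = channel, wavelength = wavelength,
                 temperature_drift = temperature_drift),
            class = "sv_simspec")
}

# deterministic TI baseline profile (part of the ground truth)
sv_ti_profile <- function(radii, m, amplitude) {
  amplitude * (0.6 * sin(2 * pi * (radii - m) / 0.35) +
               0.4 * cos(2 * pi * (radii - m) / 0.11 + 1))
}

#' Generate a synthetic SV-AUC dataset
#'
#' Simulates the experiment of `spec` (sum of single-species Lamm solutions
#' scaled by the loadings, plus TI baseline, per-scan RI offsets, Gaussian
#' noise, and isolated spikes), writes the numbered scan files
#' (`00001.<ext>` ...) into `out_dir`, and a `ground_truth.json` sidecar
#' sufficient to score any recovery test without re-simulation.
#'
#' @param spec an `sv_simspec`
#' @param out_dir existing, empty output directory
#' @param n_radial radial nodes of the simulation kernels
#' @return list with `scan_paths` and `truth`
#' @export
generate_dataset <- function(spec, out_dir, n_radial = 250L) {
  out_dir <- normalize_path_sep(out_dir)
  if (!dir.exists(out_dir)) sv_io_error("output directory does not exist: %s", out_dir)
  if (length(list.files(out_dir))) sv_io_error("output directory is not empty: %s", out_dir)

  m <- spec$geometry$meniscus; b <- spec$geometry$bottom
  radii <- seq(m - 0.03, b, by = spec$radial_step)
  in_col <- radii >= m
  nt <- length(spec$scan_times)
  nr <- length(radii)

  clean <- matrix(0, nt, nr)
  for (k in seq_len(nrow(spec$species))) {
    sp <- spec$species[k, ]
    if (sp$loading == 0) next
    D <- if ("D" %in% names(spec$species) && !is.na(sp$D)) sp$D
         else diffusion_from_s(sp$s, sp$ffr, spec$conditions)
    sol <- solve_lamm(sp$s, D, spec$geometry, spec$rpm, spec$scan_times,
                      n_radial = n_radial)
    for (i in seq_len(nt))
      clean[i, in_col] <- clean[i, in_col] + sp$loading *
        approx(sol$radii, sol$concentration[i, ], xout = radii[in_col],
               rule = 2)$y
  }

  ti <- sv_ti_profile(radii, m, spec$ti_amplitude)
  omega2 <- (spec$rpm * pi / 30)^2
  temps <- 20 + spec$temperature_drift * (seq_len(nt) - 1) / max(nt - 1, 1)

  gen <- sv_with_seed(spec$seed, {
    ri <- rnorm(nt, 0, spec$ri_amplitude)
    noise <- matrix(rnorm(nt * nr, 0, spec$noise_sigma), nt, nr)
    # isolated spikes: interior points, no two adjacent or duplicated
    spikes <- data.frame(scan = integer(), index = integer(),
                         radius = numeric(), amplitude = numeric())
    if (spec$n_spikes > 0) {
      taken <- character()
      guard <- 0L
      while (nrow(spikes) < spec$n_spikes && guard < 1000L) {
        guard <- guard + 1L
        sc <- sample.int(nt, 1)
        ix <- sample(3:(nr - 2), 1)
        keys <- paste(sc, (ix - 1):(ix + 1))
        if (any(keys %in% taken)) next
        taken <- c(taken, paste(sc, ix))
        amp <- sample(c(-1, 1), 1) * runif(1, 1.0, 1.5)
        spikes <- rbind(spikes, data.frame(scan = sc, index = ix,
                                           radius = radii[ix],
                                           amplitude = amp))
      }
    }
    list(ri = ri, noise = noise, spikes = spikes)
  })

  signal <- clean + gen$noise +
    matrix(ti, nt, nr, byrow = TRUE) + matrix(gen$ri, nt, nr)
  for (j in seq_len(nrow(gen$spikes)))
    signal[gen$spikes$scan[j], gen$spikes$index[j]] <-
      signal[gen$spikes$scan[j], gen$spikes$index[j]] + gen$spikes$amplitude[j]

  paths <- character(nt)
  for (i in seq_len(nt)) {
    scan <- structure(list(
      description = "synthetic SV-AUC scan (svengine synthgen)",
      data_type = "R", cell = 1L, temperature = temps[i], rpm = spec$rpm,
      time_s = spec$scan_times[i], w2t = omega2 * spec$scan_times[i],
      wavelength = spec$wavelength, radii = radii, signal = signal[i, ]
    ), class = "sv_scan")
    paths[i] <- file.path(out_dir, sprintf("%05d.%s", i, spec$channel))
    write_scan(scan, paths[i])
  }

  truth <- list(
    species = spec$species,
    geometry = unclass(spec$geometry),
    rpm = spec$rpm,
    scan_times = spec$scan_times,
    noise_sigma = spec$noise_sigma,
    seed = spec$seed,
    plateau_signals = spec$species$loading,
    total_loading = sum(spec$species$loading),
    ti_profile = data.frame(radius = radii, value = ti),
    ri_values = data.frame(scan = seq_len(nt), value = gen$ri),
    spikes = gen$spikes
  )
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(list(scan_paths = paths, truth = truth))
}

#' Four-species preset resembling a stressed monoclonal antibody sample
#'
#' Species near 4.2 S (trace degradation product), 6.5 S (monomer), 9.5 S
#' (dimer) and 16.8 S (higher aggregates) with a common frictional ratio of
#' 1.37, loadings chosen so the signal fractions approximate a partially
#' degraded antibody preparation, at 50,000 rpm in a 6.0–7.2 cm solution
#' column; 13 scans between 300 s and 6300 s, noise sigma 0.005, TI/RI
#' systematic baselines, and a few data spikes.
#'
#' @param seed integer seed
#' @return an `sv_simspec`
#' @export
nistmab_like_preset <- function(seed = 1234L) {
  simulation_spec(
    species = data.frame(
      s = c(4.2, 6.5, 9.5, 16.8),
      ffr = c(1.37, 1.37, 1.37, 1.37),
      loading = c(0.0095, 0.2920, 0.1251, 0.5177)
    ),
    geometry = cell_geometry(6.0, 7.2),
    rpm = 50000,
    scan_times = seq(300, 6300, by = 500),
    radial_step = 0.003,
    noise_sigma = 0.005,
    ti_amplitude = 0.01,
    ri_amplitude = 0.005,
    n_spikes = 3L,
    seed = seed,
    conditions = solution_conditions(0.73, 0.99823, 0.01002, 293.15),
    channel = "ra1"
  )
}
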