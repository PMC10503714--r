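#' Automated-vs-operator equivalence study on a synthetic antibody analog
#'
#' Reproduces, at desk scale, the validation experiment for headless
#' operation: the same synthetic four-species dataset
#' ([nistmab_like_preset()]) is analyzed twice through the full protocol
#' (XML request, session, output files). Path A is a single fully automated
#' session (AutoFit, meniscus and frictional ratio fitted). Path B emulates
#' operator-style stepwise work: a Run-only session first, then a fitting
#' session whose starting meniscus and frictional ratio are perturbed by
#' +0.5% / -0.5%. The three principal peaks (degradation product, monomer,
#' dimer) are integrated over fixed s-windows in both results and compared.
#'
#' @param seed integer seed for the synthetic dataset
#' @param dir working directory (created if needed); all data, requests and
#'   results are placed beneath it
#' @param resolution s-grid size
#' @param smin,smax s-grid range, svedberg
#' @param algorithm nonlinear fitting algorithm for both paths
#' @param windows list of three `c(lo, hi)` integration windows, svedberg
#' @param n_radial radial nodes of the Lamm kernels
#' @return list with `delta_s_max` (S), `delta_fraction_max` (percentage
#'   points), per-path peak tables, best-fit parameters, and `n_points`
#' @export
cs_equivalence_study <- function(seed = 1234L, dir = tempfile("equivalence"),
                                 resolution = 60L, smin = 1, smax = 30,
                                 algorithm = "Levenberg-Marquardt",
                                 windows = list(c(3, 5.4), c(5.4, 8), c(8, 12.5)),
                                 n_radial = 150L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(dir, "data")
  dir.create(data_dir, showWarnings = FALSE)
  preset <- nistmab_like_preset(seed = seed)
  generate_dataset(preset, data_dir)

  base_args <- list(
    DataDirectory = data_dir,
    Channel = preset$channel,
    FirstScan = 1L, LastScan = length(preset$scan_times), ScanInterval = 1L,
    Meniscus = 6.0, MeniscusLowerLimit = 5.95, MeniscusUpperLimit = 6.045,
    Bottom = 7.2, LeftFitLimit = 6.05, RightFitLimit = 7.10,
    Model = "cofs", Resolution = as.integer(resolution),
    Smin = smin, Smax = smax, UseLogSpaceSgrid = TRUE,
    RegularizationType = "maxent", RegularizationPvalue = 0.68,
    SuppressBaselineCorrelation = TRUE,
    FittingAlgorithm = algorithm,
    StartingFrictionalRatio = 1.25,
    TINoiseFitted = TRUE, RINoiseFitted = TRUE
  )

  session <- function(tag, extra) {
    args <- utils::modifyList(base_args, extra)
    args$AllDoneFlagFile <- file.path(dir, paste0("flag_", tag, ".txt"))
    args$OutputResultsDirectory <- file.path(dir, paste0("results_", tag))
    req <- do.call(analysis_request, args)
    xml <- file.path(dir, paste0("input_", tag, ".xml"))
    write_request_xml(req, xml)
    cmd <- parse_command_line(c("111", paste0("study-", tag), xml))
    run_session(cmd, n_radial = n_radial)
  }

  # Path A: fully automated single session
  res_a <- session("A", list(AutoRun = TRUE, AutoFit = TRUE,
                             MeniscusFitted = TRUE,
                             FrictionalRatioFitted = TRUE))
  # Path B: operator-style — Run only, then restart with perturbed guesses
  session("B1", list(AutoRun = TRUE, AutoFit = FALSE))
  res_b <- session("B2", list(AutoRun = TRUE, AutoFit = TRUE,
                              MeniscusFitted = TRUE,
                              FrictionalRatioFitted = TRUE,
                              Meniscus = 6.0 * 1.005,
                              StartingFrictionalRatio = 1.25 * 0.995))

  peak_table <- function(res) {
    t(vapply(windows, function(w) {
      pk <- integrate_distribution(res$dist, w[1], w[2])
      c(s_lo = w[1], s_hi = w[2], sw = pk$sw, fraction = pk$fraction)
    }, numeric(4)))
  }
  pa <- peak_table(res_a)
  pb <- peak_table(res_b)

  list(
    delta_s_max = max(abs(pa[, "sw"] - pb[, "sw"])),
    delta_fraction_max = max(abs(pa[, "fraction"] - pb[, "fraction"])),
    peaks_a = pa, peaks_b = pb,
    par_a = res_a$par, par_b = res_b$par,
    rmsd_a = res_a$stats$RMSD, rmsd_b = res_b$stats$RMSD,
    n_points = res_a$stats$RMSD_points,
    dir = dir
  )
}
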