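# Protocol lifecycle: three-token command line -> XML request -> analysis ->
# result files -> completion flag file (written last, containing the
# handshake string as sole content).

#' Parse the three-token command line
#'
#' The engine is invoked as `<mode> <handshake> <input.xml>`: an operation
#' mode (111 = full analysis menu, 112 = restricted elementary
#' size-distribution profile), an arbitrary handshake string echoed in the
#' completion flag file, and the path of the XML input file.
#'
#' @param argv character vector of the three tokens (after the program name)
#' @param check_input verify that the input file is readable
#' @return an object of class `sv_cmdline` with `mode`, `handshake`,
#'   `input_path`, and `restricted`
#' @export
parse_command_line <- function(argv, check_input = TRUE) {
  if (length(argv) != 3)
    sv_usage_error("usage: svengine <mode> <handshake> <input.xml> (got %d tokens)",
                   length(argv))
  mode_txt <- argv[1]
  if (!mode_txt %in% c("111", "112"))
    sv_mode_error("unsupported operation mode '%s' (supported: 111, 112)",
                  mode_txt)
  handshake <- argv[2]
  if (!nzchar(trimws(handshake)))
    sv_usage_error("handshake string must be non-empty")
  input_path <- argv[3]
  if (check_input) {
    p <- normalize_path_sep(input_path)
    if (!file.exists(p) || file.access(p, 4) != 0)
      sv_io_error("input file not readable: %s", input_path)
  }
  structure(list(mode = as.integer(mode_txt), handshake = handshake,
                 input_path = input_path, restricted = mode_txt == "112"),
            class = "sv_cmdline")
}

# deterministic seed for the Simplex initial randomization, derived from the
# handshake string (documented; below 2^31)
sv_seed_from_handshake <- function(handshake) {
  codes <- utf8ToInt(handshake)
  as.integer(sum(codes * (seq_along(codes) %% 97 + 1)) %% 2147483647)
}

#' Run one complete analysis session
#'
#' Drives the full lifecycle: read and validate the XML request, load and
#' filter the scan files, restrict to the fit range, build the s-grid and
#' kernels, run the (optionally nonlinear) fit, compute the fit statistics,
#' write every output artifact into the freshly created results directory,
#' and finally write the completion flag file — strictly last, so that its
#' existence certifies a complete result set. A pre-existing flag file makes
#' the session refuse to run. In restricted mode (112) requests using
#' non-standard options are rejected.
#'
#' @param cmd an `sv_cmdline` from [parse_command_line()]
#' @param n_radial radial nodes of the Lamm kernels
#' @return the `sv_result`, invisibly
#' @export
run_session <- function(cmd, n_radial = 180L) {
  req <- read_request(cmd$input_path)

  flag_path <- normalize_path_sep(req$AllDoneFlagFile)
  if (!is.na(flag_path) && file.exists(flag_path))
    sv_abort("sv_refuse_error",
             "flag file already exists, refusing to run: %s", flag_path)

  viol <- validate_request(req, check_fs = TRUE,
                           restricted = isTRUE(cmd$restricted))
  if (nrow(viol))
    sv_value_error("invalid request:\n%s",
                   paste(sprintf("  %s: %s", viol$parameter, viol$rule),
                         collapse = "\n"))

  out_dir <- normalize_path_sep(req$OutputResultsDirectory)
  if (!dir.create(out_dir, showWarnings = FALSE))
    sv_io_error("could not create results directory: %s", out_dir)

  data_dir <- normalize_path_sep(req$DataDirectory)
  scan_paths <- enumerate_scan_paths(data_dir, req$Channel, req$FirstScan,
                                     req$LastScan, req$ScanInterval)
  scans <- lapply(scan_paths, read_scan)
  spikes_removed <- 0L
  if (isTRUE(req$FilterDataSpikes)) {
    for (i in seq_along(scans)) {
      f <- filter_spikes(scans[[i]], req$DataSpikeThreshold)
      scans[[i]] <- f$scan
      spikes_removed <- spikes_removed + f$removed
    }
  }
  scanset_full <- scan_set(scans, channel = req$Channel,
                           source_paths = scan_paths)
  metadata <- aggregate_metadata(scanset_full)
  scanset <- restrict_fit_range(scanset_full, req$LeftFitLimit,
                                req$RightFitLimit)

  grid <- if (isTRUE(req$GridfromFile))
    grid_from_file(file.path(data_dir, paste0("sdist.", tolower(req$Channel))))
  else
    build_grid(req$Smin, req$Smax, req$Resolution,
               log_spaced = isTRUE(req$UseLogSpaceSgrid))

  cond <- solution_conditions(req$Vbar, req$BufferDensity, req$BufferViscosity,
                              metadata$TemperatureAverage + 273.15)

  req_run <- req
  if (!isTRUE(req$AutoFit)) {
    # Run behavior: a single linear fit at the initial parameters
    req_run$MeniscusFitted <- FALSE
    req_run$BottomFitted <- FALSE
    req_run$FrictionalRatioFitted <- FALSE
  }
  opt <- optimize_parameters(req_run, scanset, grid, cond,
                             seed = sv_seed_from_handshake(cmd$handshake),
                             n_radial = n_radial)

  req$Meniscus <- unname(opt$par[["Meniscus"]])
  req$Bottom <- unname(opt$par[["Bottom"]])
  if (identical(req$Model, "cofs"))
    req$StartingFrictionalRatio <- unname(opt$par[["FrictionalRatio"]])

  dist <- opt$dist
  idx <- split(seq_along(dist$residuals), dist$row_index$scan)
  stats <- rmsd_stats(lapply(idx, function(ii) dist$residuals[ii]))
  runs <- runs_test_z(dist$residuals)
  hh <- histogram_h(dist$residuals)

  scan_numbers <- as.integer(sub("\\..*$", "", basename(scan_paths)))
  paths <- list(
    screenshot = file.path(out_dir, "screenshot.bmp"),
    ri_noise = file.path(out_dir, "RInoise.dat"),
    ti_noise = file.path(out_dir, "TInoise.dat"),
    scan_rmsd = file.path(out_dir, "ScanRMSD.dat"),
    distribution = file.path(out_dir, "distribution.dat"),
    dfr = file.path(out_dir, "dfr.dat"),
    session_log = file.path(out_dir, "session_log.json"),
    result_xml = file.path(out_dir, "ResultParameters.xml")
  )

  result <- structure(list(
    request = req,
    handshake = cmd$handshake,
    mode = cmd$mode,
    version = paste0("engine:svengine ", as.character(packageVersion("svengine"))),
    par = opt$par,
    dist = dist,
    scanset = scanset,
    scan_paths = scan_paths,
    scan_numbers = scan_numbers,
    spikes_removed = spikes_removed,
    metadata = metadata,
    stats = stats,
    runs_z = if (runs$defined) runs$z else NA_real_,
    hist_h = if (hh$defined) hh$h else NA_real_,
    trace_text = opt$trace$text,
    paths = paths,
    out_dir = out_dir
  ), class = "sv_result")

  sv_checkpoint("sdist")
  write_sdist(grid, file.path(data_dir, paste0("sdist.", tolower(req$Channel))))
  write_all(result, out_dir)

  sv_checkpoint("AllDoneFlagFile")
  writeLines(cmd$handshake, flag_path)   # sole content: the handshake string
  invisible(result)
}

#' Command-line entry point
#'
#' Thin wrapper suitable for `Rscript`: parses the three tokens, runs the
#' session, and returns an exit status (0 only when the completion flag file
#' was written).
#'
#' @param argv command-line tokens (defaults to the process arguments)
#' @return integer exit status, invisibly
#' @export
svengine_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    cmd <- parse_command_line(argv)
    run_session(cmd)
    0L
  }, sv_error = function(e) {
    message("svengine error: ", conditionMessage(e))
    1L
  }, error = function(e) {
    message("svengine internal error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
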