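# Scan file dialect (versioned: "svengine scan dialect 1"), mirroring the
# customary XL-A/XL-I ASCII layout:
#   line 1: free-text description
#   line 2: data-type char, cell, temperature (C), rpm, time (s),
#           omega^2 t (1/s), wavelength, replicate count
#   then:   radius (cm, >= 4 decimals) <TAB> signal (>= 5 decimals)

#' Enumerate scan file paths
#'
#' Builds the file names `NNNNN.<ext>` (5-digit zero-padded) for the scan
#' numbers first, first+interval, ... up to last, and verifies that each file
#' exists (the extension is matched case-insensitively on lookup).
#'
#' @param dir data directory
#' @param channel scan file extension identifying cell and scan type
#' @param first,last first and last scan number (1-based), `last >= first`
#' @param interval scan number stride, >= 1
#' @param must_exist check existence of every enumerated file
#' @return character vector of paths
#' @export
enumerate_scan_paths <- function(dir, channel, first, last, interval = 1L,
                                 must_exist = TRUE) {
  if (!(first >= 1 && last >= first && interval >= 1))
    sv_value_error("invalid scan range: first=%s last=%s interval=%s",
                   first, last, interval)
  dir <- normalize_path_sep(dir)
  nums <- seq(from = first, to = last, by = interval)
  names_lc <- sprintf("%05d.%s", nums, tolower(channel))
  paths <- file.path(dir, names_lc)
  if (must_exist) {
    missing <- !file.exists(paths)
    if (any(missing)) {
      # case-insensitive fallback on the extension
      alt <- file.path(dir, sprintf("%05d.%s", nums, channel))
      use_alt <- missing & file.exists(alt)
      paths[use_alt] <- alt[use_alt]
      missing <- !file.exists(paths)
    }
    if (any(missing))
      sv_io_error("missing scan files: %s",
                  paste(basename(paths[missing]), collapse = ", "))
  }
  paths
}

#' Read one SV-AUC scan file
#'
#' @param path scan file path
#' @return an object of class `sv_scan` with header metadata and the
#'   radius/signal vectors
#' @export
read_scan <- function(path) {
  path <- normalize_path_sep(path)
  if (!file.exists(path)) sv_io_error("scan file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) sv_format_error("scan file too short: %s", path)
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(hdr) < 7)
    sv_format_error("malformed scan header in %s: '%s'", path, lines[2])
  num <- suppressWarnings(as.numeric(hdr[2:7]))
  if (anyNA(num))
    sv_format_error("non-numeric scan header field in %s", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  if (anyNA(vals) || length(vals) %% 2 != 0)
    sv_format_error("malformed radius/signal data in %s", path)
  radii <- vals[seq(1, length(vals), by = 2)]
  signal <- vals[seq(2, length(vals), by = 2)]
  if (length(radii) < 2) sv_data_error("fewer than 2 data points in %s", path)
  if (any(diff(radii) <= 0))
    sv_data_error("radii not strictly increasing in %s", path)
  structure(list(
    description = lines[1],
    data_type = hdr[1],
    cell = as.integer(num[1]),
    temperature = num[2],
    rpm = num[3],
    time_s = num[4],
    w2t = num[5],
    wavelength = num[6],
    radii = radii,
    signal = signal,
    path = path
  ), class = "sv_scan")
}

#' Write one SV-AUC scan file
#'
#' Inverse of [read_scan()] at the documented precision (radius with 5
#' decimals, signal with 6).
#'
#' @param scan an `sv_scan`
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_scan <- function(scan, path) {
  hdr2 <- sprintf("%s %d %.2f %d %.2f %.6e %.2f %d",
                  scan$data_type, as.integer(scan$cell), scan$temperature,
                  as.integer(round(scan$rpm)), scan$time_s, scan$w2t,
                  scan$wavelength, 1L)
  rows <- sprintf("%.5f\t%.6f", scan$radii, scan$signal)
  writeLines(c(scan$description, hdr2, rows), path)
  invisible(path)
}

#' Remove isolated data spikes from a scan
#'
#' An interior point is a spike when it deviates from both of its neighbors
#' in the same direction by more than `threshold`. Spikes are removed
#' together with their radii (no interpolation); endpoints are never removed.
#' Sweeps are repeated until no spike remains, which makes the filter
#' idempotent.
#'
#' @param scan an `sv_scan`
#' @param threshold spike threshold, signal units, > 0
#' @return list with the filtered `scan` and the `removed` count
#' @export
filter_spikes <- function(scan, threshold = 0.4) {
  if (threshold <= 0) sv_value_error("spike threshold must be positive")
  removed <- 0L
  repeat {
    sig <- scan$signal
    n <- length(sig)
    if (n < 3) break
    d_prev <- sig[2:(n - 1)] - sig[1:(n - 2)]
    d_next <- sig[2:(n - 1)] - sig[3:n]
    spike <- (d_prev > threshold & d_next > threshold) |
             (d_prev < -threshold & d_next < -threshold)
    idx <- which(spike) + 1L
    if (!length(idx)) break
    scan$radii <- scan$radii[-idx]
    scan$signal <- scan$signal[-idx]
    removed <- removed + length(idx)
  }
  list(scan = scan, removed = removed)
}

#' Assemble a time-ordered scan set
#'
#' @param scans list of `sv_scan` objects, in scan-number order
#' @param channel scan file extension
#' @param source_paths originating file paths (used for timestamp reporting)
#' @return an object of class `sv_scanset`
#' @export
scan_set <- function(scans, channel = "", source_paths = character()) {
  if (!length(scans)) sv_data_error("empty scan set")
  times <- vapply(scans, `[[`, numeric(1), "time_s")
  if (any(diff(times) <= 0))
    sv_data_error("scan times must be strictly increasing")
  w2t <- vapply(scans, `[[`, numeric(1), "w2t")
  if (any(diff(w2t) < 0))
    sv_data_error("omega^2 t must be non-decreasing across scans")
  rpms <- vapply(scans, `[[`, numeric(1), "rpm")
  if (length(unique(rpms)) > 1)
    warning("rotor speed differs across scans; using the first scan's value",
            call. = FALSE)
  types <- vapply(scans, `[[`, character(1), "data_type")
  if (length(unique(types)) > 1)
    sv_data_error("scans mix data types: %s", paste(unique(types), collapse = ", "))
  structure(list(scans = scans, channel = channel,
                 source_paths = source_paths),
            class = "sv_scanset")
}

#' Restrict a scan set to the fit range
#'
#' Keeps, in every scan, exactly the points with
#' `left <= radius <= right`, preserving order.
#'
#' @param set an `sv_scanset`
#' @param left,right fit limits, cm, `left < right`
#' @return the restricted `sv_scanset`
#' @export
restrict_fit_range <- function(set, left, right) {
  if (!(left < right)) sv_value_error("fit limits require left < right")
  set$scans <- lapply(set$scans, function(sc) {
    keep <- sc$radii >= left & sc$radii <= right
    if (!any(keep))
      sv_data_error("no data points in fit range [%g, %g] for scan at t=%g s",
                    left, right, sc$time_s)
    sc$radii <- sc$radii[keep]
    sc$signal <- sc$signal[keep]
    sc
  })
  set
}

#' Aggregate scan-set metadata
#'
#' Header metadata summarized across the loaded scans: rotor speed and
#' wavelength from the first scan, time and accumulated omega^2 t of the last
#' scan, and the temperature record (first/last/average/max-min range) used
#' to flag possible convection artifacts. `CheckTimeStamps` reports whether
#' filesystem modification times were readable for all scan files.
#'
#' @param set an `sv_scanset`
#' @return a list of class `sv_metadata`
#' @export
aggregate_metadata <- function(set) {
  sc <- set$scans
  temps <- vapply(sc, `[[`, numeric(1), "temperature")
  n <- length(sc)
  ts_ok <- length(set$source_paths) > 0 &&
    all(!is.na(file.mtime(set$source_paths)))
  structure(list(
    RotorSpeed = sc[[1]]$rpm,
    Wavelength = sc[[1]]$wavelength,
    tLastScan = sc[[n]]$time_s,
    w2tLastScan = sc[[n]]$w2t,
    TemperatureStart = temps[1],
    TemperatureEnd = temps[n],
    TemperatureAverage = mean(temps),
    TemperatureDiffMaxMin = max(temps) - min(temps),
    CheckTimeStamps = ts_ok
  ), class = "sv_metadata")
}
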