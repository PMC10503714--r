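# All output artifacts of a session: the results XML, the distribution and
# noise/rmsd tables, the data+fit matrix (dfr.dat), the report image, and a
# JSON session log under a deliberately engine-specific name (this engine
# writes no GUI session-restore file). Numeric files use a fixed precision
# of 6 significant digits in exponent format.

sv_fmt_num <- function(x) sprintf("%.6e", x)

# fault-injection checkpoint: tests set options(svengine.abort_stage=) to
# verify that an interrupted run never leaves a flag file behind
sv_checkpoint <- function(stage) {
  if (identical(getOption("svengine.abort_stage"), stage))
    sv_abort("sv_injected_fault", "injected fault before writing %s", stage)
  invisible(stage)
}

sv_write_two_col <- function(a, b, path) {
  writeLines(paste(sv_fmt_num(a), sv_fmt_num(b), sep = "\t"), path)
  invisible(path)
}

#' Write the data/fit/noise matrix file (dfr.dat)
#'
#' Tab-delimited matrix with columns: radius (TI noise), TI noise, RI noise,
#' then for each scan: radius, raw data, fit value; rows correspond to
#' consecutive radii (data columns) or scan times (RI column). Columns
#' shorter than the longest are padded with empty fields.
#'
#' @param scanset the fitted `sv_scanset` (restricted to the fit range)
#' @param fitted_by_scan list of fitted-value vectors, one per scan
#' @param ti data.frame (radius, value) of the TI noise profile
#' @param ri data.frame (time, value) of the RI noise
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_dfr <- function(scanset, fitted_by_scan, ti, ri, path) {
  cols <- list(sv_fmt_num(ti$radius), sv_fmt_num(ti$value),
               sv_fmt_num(ri$value))
  for (i in seq_along(scanset$scans)) {
    sc <- scanset$scans[[i]]
    cols <- c(cols, list(sv_fmt_num(sc$radii), sv_fmt_num(sc$signal),
                         sv_fmt_num(fitted_by_scan[[i]])))
  }
  nmax <- max(vapply(cols, length, integer(1)))
  cols <- lapply(cols, function(x) c(x, rep("", nmax - length(x))))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Text block of the report image
#'
#' The informational text shown in the report image (data location, scans
#' fitted, model, and the overall rmsd at the printed precision). Exposed so
#' that cross-artifact consistency (image text vs results XML) can be
#' checked without parsing pixels.
#'
#' @param result an `sv_result`
#' @return character vector of lines
#' @export
report_text_block <- function(result) {
  c(sprintf("data: %s (%d scans, channel %s)",
            result$request$DataDirectory, length(result$scanset$scans),
            result$request$Channel),
    sprintf("model: %s, grid %d points [%g, %g] S", result$request$Model,
            length(result$dist$grid$values), min(result$dist$grid$values),
            max(result$dist$grid$values)),
    sprintf("rmsd %.6f (%d points)", result$stats$RMSD,
            result$stats$RMSD_points),
    result$trace_text)
}

# 24-bit uncompressed BMP writer (img: H x W x 3 array in [0,1])
write_bmp <- function(img, path) {
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  H <- dim(img)[1]; W <- dim(img)[2]
  px <- pmin(pmax(round(img[, , 1:3] * 255), 0), 255)
  rowbytes <- 3L * W
  pad <- (4L - rowbytes %% 4L) %% 4L
  imgsize <- (rowbytes + pad) * H
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(charToRaw("BM"), con)
  w4(14 + 40 + imgsize); w4(0); w4(54)
  w4(40); w4(W); w4(H); w2(1); w2(24); w4(0); w4(imgsize)
  w4(2835); w4(2835); w4(0); w4(0)
  # rows bottom-up, BGR within each pixel
  flip <- H:1
  M <- matrix(0L, rowbytes + pad, H)
  M[seq(1, rowbytes, by = 3), ] <- t(px[flip, , 3])
  M[seq(2, rowbytes, by = 3), ] <- t(px[flip, , 2])
  M[seq(3, rowbytes, by = 3), ] <- t(px[flip, , 1])
  writeBin(as.raw(M), con)
  invisible(path)
}

#' Render the report image
#'
#' Bitmap (`screenshot.bmp`-compatible) with the scan data + fit overlay,
#' residuals overlay, the fitted distribution, an optional residuals
#' histogram, and the informational text block. With `subtract_noise` the
#' best-fit systematic noise components are subtracted from the displayed
#' scans (and fits). A rendering failure degrades to a minimal placeholder
#' bitmap so the session can complete.
#'
#' @param scanset fitted `sv_scanset`
#' @param dist an `sv_distfit`
#' @param info_lines text block lines (see [report_text_block()])
#' @param subtract_noise subtract TI/RI/baseline from the display
#' @param show_histogram include a residuals histogram panel
#' @param path destination `.bmp` path
#' @return `path`, invisibly
#' @export
render_report_image <- function(scanset, dist, info_lines = character(),
                                subtract_noise = FALSE,
                                show_histogram = FALSE, path) {
  tmp <- tempfile(fileext = ".png")
  ok <- tryCatch({
    grDevices::png(tmp, width = 960, height = 720)
    on.exit(if (dev.cur() > 1) dev.off(), add = TRUE)
    lay <- if (show_histogram) matrix(1:4, 2, 2, byrow = TRUE)
           else matrix(c(1, 2, 3, 3), 2, 2, byrow = TRUE)
    graphics::layout(lay)
    par(mar = c(4, 4, 2, 1), oma = c(5, 0, 0, 0))

    scans <- scanset$scans
    n <- length(scans)
    cols <- grDevices::hcl.colors(n, "Viridis")
    noise_of <- function(i) {
      ofs <- rep(dist$baseline, length(scans[[i]]$radii))
      if (nrow(dist$ti_noise))
        ofs <- ofs + dist$ti_noise$value[
          match(scans[[i]]$radii, dist$ti_noise$radius)]
      if (nrow(dist$ri_noise)) ofs <- ofs + dist$ri_noise$value[i]
      ofs[is.na(ofs)] <- 0
      ofs
    }
    idx <- split(seq_along(dist$fitted), dist$row_index$scan)
    rng_x <- range(unlist(lapply(scans, `[[`, "radii")))
    disp <- lapply(seq_len(n), function(i) {
      off <- if (subtract_noise) noise_of(i) else 0
      list(r = scans[[i]]$radii,
           y = scans[[i]]$signal - off,
           f = dist$fitted[idx[[i]]] - off)
    })
    rng_y <- range(unlist(lapply(disp, `[[`, "y")))
    plot(NA, xlim = rng_x, ylim = rng_y, xlab = "radius (cm)",
         ylab = "signal", main = "data and fit")
    for (i in seq_len(n)) {
      points(disp[[i]]$r, disp[[i]]$y, pch = ".", col = cols[i])
      lines(disp[[i]]$r, disp[[i]]$f, col = cols[i])
    }

    plot(NA, xlim = rng_x, ylim = range(dist$residuals),
         xlab = "radius (cm)", ylab = "residual", main = "residuals")
    for (i in seq_len(n))
      lines(scans[[i]]$radii, dist$residuals[idx[[i]]], col = cols[i])
    abline(h = 0, lty = 2)

    plot(dist$grid$values, dist$c, type = "l", xlab = "s (S)",
         ylab = "c(s) (signal/S)", main = "distribution")

    if (show_histogram)
      hist(dist$residuals, breaks = 40, main = "residuals histogram",
           xlab = "residual", col = "grey80")

    mtext(paste(info_lines, collapse = "\n"), side = 1, outer = TRUE,
          line = 3, cex = 0.7, adj = 0)
    dev.off()
    TRUE
  }, error = function(e) FALSE)

  if (ok && file.exists(tmp)) {
    img <- png::readPNG(tmp)
    unlink(tmp)
    write_bmp(img, path)
  } else {
    write_bmp(array(0.92, c(120, 320, 3)), path)  # placeholder
  }
  invisible(path)
}

#' Write the results XML (ResultParameters.xml)
#'
#' Same XML conventions as the input file (root `cGMPSedfitCall`), echoing
#' every input parameter at its post-fit value, plus the additional output
#' parameters: engine version, output file paths, the loaded scan files, the
#' metadata aggregates, the fitting trace line, and the fit statistics.
#' `PassThrough` is reproduced verbatim.
#'
#' @param result an `sv_result`
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_result_xml <- function(result, path) {
  md <- result$metadata
  st <- result$stats
  extra <- list(
    SEDFITVersion = result$version,
    ScreenShotPath = result$paths$screenshot,
    CofsDataPath = result$paths$distribution,
    TINoisePath = result$paths$ti_noise,
    RINoisePath = result$paths$ri_noise,
    ScanRMSDpath = result$paths$scan_rmsd,
    ScanDataFilesLoaded = setNames(as.list(result$scan_paths),
                                   rep("File", length(result$scan_paths))),
    CheckTimeStamps = md$CheckTimeStamps,
    RotorSpeed = as.integer(round(md$RotorSpeed)),
    Wavelength = md$Wavelength,
    w2tLastScan = md$w2tLastScan,
    tLastScan = md$tLastScan,
    TemperatureStart = md$TemperatureStart,
    TemperatureEnd = md$TemperatureEnd,
    TemperatureAverage = md$TemperatureAverage,
    `TemperatureDiffMax-Min` = md$TemperatureDiffMaxMin,
    FittingStepsText = result$trace_text,
    RMSD = st$RMSD,
    `RMSD-points` = st$RMSD_points,
    `RMSD-SSR` = st$RMSD_SSR,
    RunsTestZ = result$runs_z,
    HistogramH = result$hist_h,
    FrictionalRatio = result$par[["FrictionalRatio"]]
  )
  write_request_xml(result$request, path, extra = extra)
}

#' Write every result file of a completed analysis
#'
#' Writes, in a fixed order, `screenshot.bmp`, `RInoise.dat`, `TInoise.dat`,
#' `ScanRMSD.dat`, `distribution.dat`, `dfr.dat`, `session_log.json`, and
#' `ResultParameters.xml` into the (already created) output directory. The
#' completion flag file is NOT written here: the protocol layer writes it
#' strictly after this function returns, so the flag certifies completeness.
#'
#' @param result an `sv_result`
#' @param out_dir the session's output directory
#' @return character vector of all written paths
#' @export
write_all <- function(result, out_dir) {
  dist <- result$dist
  scanset <- result$scanset
  folded <- fold_noise(dist, scanset)
  p <- result$paths

  sv_checkpoint("screenshot.bmp")
  render_report_image(scanset, dist, report_text_block(result),
                      subtract_noise = isTRUE(result$request$AutoSubtractSystematicNoise),
                      show_histogram = isTRUE(result$request$ShowResidualsHistogram),
                      path = p$screenshot)

  sv_checkpoint("RInoise.dat")
  sv_write_two_col(folded$ri$time, folded$ri$value, p$ri_noise)
  sv_checkpoint("TInoise.dat")
  sv_write_two_col(folded$ti$radius, folded$ti$value, p$ti_noise)
  sv_checkpoint("ScanRMSD.dat")
  writeLines(paste(result$scan_numbers,
                   sv_fmt_num(result$stats$per_scan$rmsd), sep = "\t"),
             p$scan_rmsd)
  sv_checkpoint("distribution.dat")
  sv_write_two_col(dist$grid$values, dist$c, p$distribution)

  sv_checkpoint("dfr.dat")
  idx <- split(seq_along(dist$fitted), dist$row_index$scan)
  fitted_by_scan <- lapply(idx, function(ii) dist$fitted[ii])
  write_dfr(scanset, fitted_by_scan, folded$ti, folded$ri, p$dfr)

  sv_checkpoint("session_log.json")
  jsonlite::write_json(list(
    engine = result$version,
    request = unclass(result$request)[!vapply(unclass(result$request),
                                              function(x) length(x) == 1 && is.na(x),
                                              logical(1))],
    scan_files = result$scan_paths,
    spikes_removed = result$spikes_removed,
    best_fit = as.list(result$par),
    lambda = dist$lambda
  ), p$session_log, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  sv_checkpoint("ResultParameters.xml")
  write_result_xml(result, p$result_xml)

  unlist(p, use.names = FALSE)
}
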