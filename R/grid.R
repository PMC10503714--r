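#' Build a sedimentation-coefficient grid
#'
#' Discrete grid of s-values for the distribution analysis, inclusive of both
#' endpoints, either equidistant or with logarithmically increasing spacing
#' (the latter concentrates resolution at small s).
#'
#' @param smin,smax grid range, svedberg; 0 < smin < smax
#' @param resolution number of grid points, >= 2
#' @param log_spaced logical; geometric instead of arithmetic progression
#' @return an object of class `sv_sgrid` (list with ascending `values`)
#' @export
build_grid <- function(smin, smax, resolution, log_spaced = FALSE) {
  if (!(smin > 0 && smax > smin)) sv_value_error("grid requires 0 < smin < smax")
  if (resolution < 2) sv_value_error("resolution must be at least 2")
  values <- if (log_spaced)
    exp(seq(log(smin), log(smax), length.out = resolution))
  else
    seq(smin, smax, length.out = resolution)
  structure(list(values = values), class = "sv_sgrid")
}

#' Read a distribution grid from an sdist file
#'
#' The sdist file holds a single column of ascending s-values; it is written
#' next to the scan data after every analysis and may be hand-edited to
#' define custom-spaced grids.
#'
#' @param path path to the grid file
#' @return an object of class `sv_sgrid`
#' @export
grid_from_file <- function(path) {
  path <- normalize_path_sep(path)
  if (!file.exists(path)) sv_io_error("grid file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    sv_format_error("non-numeric grid entry on line %d: '%s'", bad, lines[bad])
  }
  if (any(diff(vals) <= 0)) sv_data_error("grid file values must be strictly ascending")
  if (any(vals <= 0)) sv_data_error("grid values must be positive")
  structure(list(values = vals), class = "sv_sgrid")
}

#' Write a distribution grid to an sdist file
#'
#' @param grid an `sv_sgrid`
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_sdist <- function(grid, path) {
  writeLines(formatC(grid$values, digits = 12, format = "g"), path)
  invisible(path)
}
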