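# The analysis request: the complete XML-controlled parameter set of one
# session. Parameter names are case-sensitive. Booleans use the literals
# TRUE/FALSE. Unset parameters take the documented defaults below; meniscus
# and bottom fitting limits default to the point values themselves
# (degenerate bracket = parameter effectively fixed unless limits are given).

sv_param_registry <- function() {
  p <- function(name, type, default = NA, required = FALSE)
    list(name = name, type = type, default = default, required = required)
  list(
    p("AllDoneFlagFile", "path", required = TRUE),
    p("OutputResultsDirectory", "path", required = TRUE),
    p("PassThrough", "xmlstring", default = ""),
    p("DataDirectory", "path", required = TRUE),
    p("Channel", "string", required = TRUE),
    p("FirstScan", "int", required = TRUE),
    p("LastScan", "int", required = TRUE),
    p("ScanInterval", "int", default = 1L),
    p("FilterDataSpikes", "bool", default = TRUE),
    p("DataSpikeThreshold", "num", default = 0.4),
    p("Meniscus", "num", required = TRUE),
    p("MeniscusLowerLimit", "num"),
    p("MeniscusUpperLimit", "num"),
    p("Bottom", "num", required = TRUE),
    p("BottomLowerLimit", "num"),
    p("BottomUpperLimit", "num"),
    p("LeftFitLimit", "num", required = TRUE),
    p("RightFitLimit", "num", required = TRUE),
    p("AutoRun", "bool", default = FALSE),
    p("AutoFit", "bool", default = FALSE),
    p("AutoSubtractSystematicNoise", "bool", default = FALSE),
    p("ShowResidualsHistogram", "bool", default = FALSE),
    p("Model", "enum:cofs|lsgofs", default = "cofs"),
    p("Resolution", "int", default = 50L),
    p("Smin", "num", default = 1),
    p("Smax", "num", default = 20),
    p("GridfromFile", "bool", default = FALSE),
    p("UseLogSpaceSgrid", "bool", default = FALSE),
    p("RegularizationType", "enum:maxent|Tikhonov", default = "maxent"),
    p("RegularizationPvalue", "num", default = 0.68),
    p("SuppressBaselineCorrelation", "bool", default = FALSE),
    p("NumberComputationThreads", "int", default = 2L),
    p("FittingAlgorithm", "enum:Simplex|Levenberg-Marquardt",
      default = "Simplex"),
    p("StartingFrictionalRatio", "num", default = 1.2),
    p("FrictionalRatioFitted", "bool", default = FALSE),
    p("MeniscusFitted", "bool", default = FALSE),
    p("BottomFitted", "bool", default = FALSE),
    p("BaselineFitted", "bool", default = FALSE),
    p("RINoiseFitted", "bool", default = TRUE),
    p("TINoiseFitted", "bool", default = TRUE),
    p("Vbar", "num", default = 0.73),
    p("BufferDensity", "num", default = 0.99823),
    p("BufferViscosity", "num", default = 0.01002)
  )
}

sv_parse_value <- function(text, type, name) {
  text <- trimws(text)
  if (startsWith(type, "enum:")) {
    choices <- strsplit(sub("^enum:", "", type), "|", fixed = TRUE)[[1]]
    if (!text %in% choices)
      sv_value_error("parameter %s: '%s' is not one of %s",
                     name, text, paste(choices, collapse = ", "))
    return(text)
  }
  switch(type,
    bool = {
      if (!text %in% c("TRUE", "FALSE"))
        sv_value_error("parameter %s: expected TRUE or FALSE, got '%s'",
                       name, text)
      text == "TRUE"
    },
    int = {
      v <- suppressWarnings(as.numeric(text))
      if (is.na(v) || v != round(v))
        sv_value_error("parameter %s: expected an integer, got '%s'", name, text)
      as.integer(v)
    },
    num = {
      v <- suppressWarnings(as.numeric(text))
      if (is.na(v))
        sv_value_error("parameter %s: expected a number, got '%s'", name, text)
      v
    },
    path = ,
    string = ,
    xmlstring = text,
    sv_value_error("unknown parameter type for %s", name)
  )
}

sv_apply_derived_defaults <- function(req) {
  if (is.na(req$MeniscusLowerLimit) && !is.na(req$Meniscus))
    req$MeniscusLowerLimit <- req$Meniscus
  if (is.na(req$MeniscusUpperLimit) && !is.na(req$Meniscus))
    req$MeniscusUpperLimit <- req$Meniscus
  if (is.na(req$BottomLowerLimit) && !is.na(req$Bottom))
    req$BottomLowerLimit <- req$Bottom
  if (is.na(req$BottomUpperLimit) && !is.na(req$Bottom))
    req$BottomUpperLimit <- req$Bottom
  req
}

#' Construct an analysis request programmatically
#'
#' Starts from the documented defaults and overrides the named parameters.
#' Required parameters (data location, scan range, geometry and fit limits,
#' flag file and results directory) have no defaults and must be supplied
#' before the request validates.
#'
#' @param ... named parameter overrides, using the XML parameter names
#' @return an object of class `sv_request`
#' @export
analysis_request <- function(...) {
  reg <- sv_param_registry()
  req <- setNames(lapply(reg, `[[`, "default"), vapply(reg, `[[`, "", "name"))
  over <- list(...)
  unknown <- setdiff(names(over), names(req))
  if (length(unknown))
    sv_value_error("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  req[names(over)] <- over
  req <- sv_apply_derived_defaults(req)
  structure(req, class = "sv_request")
}

# Capture a node's content verbatim: nested markup is preserved as an XML
# fragment string, plain content as text.
sv_node_content <- function(node) {
  kids <- xml2::xml_children(node)
  if (length(kids))
    paste(vapply(kids, as.character, ""), collapse = "")
  else
    xml2::xml_text(node)
}

#' Read an analysis request from an XML input file
#'
#' Parses a `cGMPSedfitCall` document. Parameter names are case-sensitive
#' and order-free; unset parameters take their documented defaults; unknown
#' elements are ignored with a warning. `PassThrough` is captured verbatim,
#' including any nested markup.
#'
#' @param path path to the XML file
#' @return an object of class `sv_request`
#' @export
read_request <- function(path) {
  path <- normalize_path_sep(path)
  if (!file.exists(path)) sv_io_error("input file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) sv_format_error(
                    "malformed XML in %s: %s", path, conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (!identical(root, "cGMPSedfitCall"))
    sv_format_error("expected root element cGMPSedfitCall, found <%s>", root)

  reg <- sv_param_registry()
  types <- setNames(vapply(reg, `[[`, "", "type"),
                    vapply(reg, `[[`, "", "name"))
  req <- analysis_request()
  seen <- character()
  for (node in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(node)
    if (!nm %in% names(types)) {
      warning(sprintf("ignoring unknown input element <%s>", nm), call. = FALSE)
      next
    }
    val <- if (types[[nm]] == "xmlstring") sv_node_content(node)
           else xml2::xml_text(node)
    req[[nm]] <- sv_parse_value(val, types[[nm]], nm)
    seen <- c(seen, nm)
  }
  req <- sv_apply_derived_defaults(req)
  attr(req, "set_explicitly") <- seen
  class(req) <- "sv_request"
  req
}

#' Write an analysis request as an XML input file
#'
#' Inverse of [read_request()]: emits the `cGMPSedfitCall` document with one
#' child element per parameter. Numbers are written with 17 significant
#' digits so that the read/write round trip is lossless.
#'
#' @param req an `sv_request`
#' @param path destination path
#' @param extra named list of additional (output) elements to append; values
#'   may be atomic or character vectors of pre-formatted XML fragments
#' @return `path`, invisibly
#' @export
write_request_xml <- function(req, path, extra = NULL) {
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "TRUE" else "FALSE")
    if (is.numeric(v)) return(formatC(v, digits = 17, format = "g"))
    as.character(v)
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  reg <- sv_param_registry()
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>', "<cGMPSedfitCall>")
  for (p in reg) {
    v <- req[[p$name]]
    if (is.null(v) || (length(v) == 1 && is.na(v) && !is.character(v))) next
    body <- if (p$type == "xmlstring") v else esc(fmt(v))  # verbatim markup
    lines <- c(lines, sprintf("  <%s>%s</%s>", p$name, body, p$name))
  }
  for (nm in names(extra)) {
    v <- extra[[nm]]
    if (is.list(v)) {  # nested children; duplicate tags allowed
      inner <- unlist(lapply(seq_along(v), function(i)
        sprintf("    <%s>%s</%s>", names(v)[i], esc(fmt(v[[i]])), names(v)[i])))
      lines <- c(lines, sprintf("  <%s>", nm), inner, sprintf("  </%s>", nm))
    } else {
      lines <- c(lines, sprintf("  <%s>%s</%s>", nm, esc(fmt(v)), nm))
    }
  }
  lines <- c(lines, "</cGMPSedfitCall>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Validate an analysis request
#'
#' Checks every type and consistency invariant of the parameter set
#' (orderings of scan numbers and radial landmarks, grid ranges, the
#' regularization p-value window 0.5–1.0, positivity of the solution
#' properties) and, when `check_fs` is `TRUE`, the filesystem preconditions:
#' the flag file must not exist yet (its parent directory must), and the
#' results directory leaf must not exist (its parent must).
#'
#' Violations are data, not exceptions: each entry names the parameter and
#' the broken rule.
#'
#' @param req an `sv_request`
#' @param check_fs also check filesystem preconditions
#' @param restricted apply the restricted-mode (112) profile, which rejects
#'   non-standard options (grid from file, log-spaced grid, bottom fitting)
#' @return data.frame with columns `parameter` and `rule`; zero rows when
#'   the request is valid
#' @export
validate_request <- function(req, check_fs = TRUE, restricted = FALSE) {
  v <- list()
  bad <- function(parameter, rule) v[[length(v) + 1]] <<- data.frame(
    parameter = parameter, rule = rule, stringsAsFactors = FALSE)
  miss <- function(x) is.null(x) || (length(x) == 1 && is.na(x))

  collect <- function() do.call(rbind, c(v, list(data.frame(
    parameter = character(), rule = character(), stringsAsFactors = FALSE))))

  for (p in sv_param_registry())
    if (p$required && miss(req[[p$name]]))
      bad(p$name, "required parameter is not set")
  if (length(v)) return(collect())  # cannot check orderings with parts missing

  if (!(req$FirstScan <= req$LastScan))
    bad("FirstScan", "FirstScan must be <= LastScan")
  if (req$ScanInterval < 1) bad("ScanInterval", "ScanInterval must be >= 1")
  if (req$FilterDataSpikes && req$DataSpikeThreshold <= 0)
    bad("DataSpikeThreshold", "spike threshold must be positive")

  if (!(req$MeniscusLowerLimit <= req$Meniscus))
    bad("MeniscusLowerLimit", "must be <= Meniscus")
  if (!(req$Meniscus <= req$MeniscusUpperLimit))
    bad("MeniscusUpperLimit", "must be >= Meniscus")
  if (!(req$MeniscusUpperLimit < req$LeftFitLimit))
    bad("MeniscusUpperLimit", "must be < LeftFitLimit")
  if (!(req$LeftFitLimit < req$RightFitLimit))
    bad("LeftFitLimit", "must be < RightFitLimit")
  if (!(req$BottomLowerLimit <= req$Bottom))
    bad("BottomLowerLimit", "must be <= Bottom")
  if (!(req$Bottom <= req$BottomUpperLimit))
    bad("BottomUpperLimit", "must be >= Bottom")
  if (!(req$RightFitLimit < req$BottomLowerLimit))
    bad("RightFitLimit", "must be < the bottom (and its lower fitting limit)")

  if (!(req$Smin > 0 && req$Smin < req$Smax))
    bad("Smin", "requires 0 < Smin < Smax")
  if (req$Resolution < 2) bad("Resolution", "Resolution must be >= 2")
  if (req$RegularizationPvalue < 0.5 || req$RegularizationPvalue > 1.0)
    bad("RegularizationPvalue", "must be between 0.5 and 1.0")
  if (req$NumberComputationThreads < 1)
    bad("NumberComputationThreads", "must be a positive integer")
  if (req$StartingFrictionalRatio < 1)
    bad("StartingFrictionalRatio", "frictional ratio must be >= 1")
  if (req$Vbar <= 0) bad("Vbar", "must be positive")
  if (req$BufferDensity <= 0) bad("BufferDensity", "must be positive")
  if (req$BufferViscosity <= 0) bad("BufferViscosity", "must be positive")
  if (req$Vbar > 0 && req$BufferDensity > 0 &&
      1 - req$Vbar * req$BufferDensity == 0)
    bad("Vbar", "buoyancy factor (1 - Vbar*BufferDensity) must be non-zero")

  if (restricted) {
    if (isTRUE(req$GridfromFile))
      bad("GridfromFile", "not available in restricted mode (112)")
    if (isTRUE(req$UseLogSpaceSgrid))
      bad("UseLogSpaceSgrid", "not available in restricted mode (112)")
    if (isTRUE(req$BottomFitted))
      bad("BottomFitted", "not available in restricted mode (112)")
  }

  if (check_fs) {
    flag <- normalize_path_sep(req$AllDoneFlagFile)
    if (file.exists(flag))
      bad("AllDoneFlagFile", "flag file must not exist before the run")
    if (!dir.exists(dirname(flag)))
      bad("AllDoneFlagFile", "parent directory of the flag file must exist")
    outd <- normalize_path_sep(req$OutputResultsDirectory)
    if (file.exists(outd))
      bad("OutputResultsDirectory", "results directory leaf must not exist yet")
    if (!dir.exists(dirname(outd)))
      bad("OutputResultsDirectory", "parent of the results directory must exist")
    datad <- normalize_path_sep(req$DataDirectory)
    if (!dir.exists(datad))
      bad("DataDirectory", "data directory must exist")
  }

  collect()
}
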