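# Classed conditions so callers (and the CLI) can distinguish failure modes.

sv_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sv_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

sv_usage_error  <- function(msg, ...) sv_abort("sv_usage_error", msg, ...)
sv_mode_error   <- function(msg, ...) sv_abort("sv_mode_error", msg, ...)
sv_io_error     <- function(msg, ...) sv_abort("sv_io_error", msg, ...)
sv_format_error <- function(msg, ...) sv_abort("sv_format_error", msg, ...)
sv_value_error  <- function(msg, ...) sv_abort("sv_value_error", msg, ...)
sv_data_error   <- function(msg, ...) sv_abort("sv_data_error", msg, ...)
sv_solver_error <- function(msg, ...) sv_abort("sv_solver_error", msg, ...)

# Windows-origin protocol: normalize backslash separators for host file access;
# paths are otherwise treated as opaque strings.
normalize_path_sep <- function(path) {
  if (.Platform$OS.type == "windows") path else gsub("\\\\", "/", path)
}
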