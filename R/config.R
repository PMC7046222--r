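#' Run configuration for the command-line interface
#'
#' A named bundle of subcommand parameters that round-trips losslessly
#' through JSON, used by the `geofold` CLI script
#' (`system.file("cli", "geofold.R", package = "geofold")`).
#'
#' @param command subcommand name (`simulate`, `ensemble`, `prn`,
#'   `metrics`, `spectrum`, `scaling`, `fixtures`).
#' @param ... named scalar parameters for the subcommand.
#' @return An object of class `run_config`.
#' @export
run_config <- function(command, ...) {
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == "")))
    stop("all configuration parameters must be named")
  structure(list(command = command, args = args), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("geofold run config:", x$command, "\n")
  for (nm in names(x$args)) cat("  ", nm, "=", format(x$args[[nm]]), "\n")
  invisible(x)
}

#' Write / read a run configuration as JSON
#'
#' @param cfg a [run_config()].
#' @param file path to the JSON file.
#' @return `write_run_config` returns `file` invisibly; `read_run_config`
#'   a [run_config()] equal to the one written.
#' @export
write_run_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(list(command = cfg$command, args = cfg$args), file,
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  args <- as.list(x$args)
  do.call(run_config, c(list(command = x$command), args))
}
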