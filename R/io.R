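#' Read and write raw dose-response estimate tables
#'
#' Raw estimates travel as headered delimited text with columns `id`,
#' `a`, `b`, `rmse` (plus `sigma` once noise levels are calibrated).
#' Reading validates the positivity invariants.
#'
#' @param path File path.
#' @param raw A raw-estimates data frame.
#' @param delim Field delimiter (default tab).
#' @return `read_raw_estimates()`: a validated tibble.
#' @export
read_raw_estimates <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  validate_raw_estimates(raw)
  tibble::as_tibble(raw)
}

#' @rdname read_raw_estimates
#' @export
write_raw_estimates <- function(raw, path, delim = "\t") {
  validate_raw_estimates(raw)
  readr::write_delim(raw, path, delim = delim)
  invisible(path)
}

#' Serialize posterior draws for reuse without re-fitting
#'
#' Writes the draws of a fitted component as columnar delimited text (one
#' row per draw, one column per parameter, plus `.chain` and
#' `.iteration`). `read_draws()` restores the tibble; diagnostics can be
#' recomputed with [compute_diagnostics()].
#'
#' @param fit A `mel_regression` or `mel_noise` object (or any draws
#'   tibble with a `.chain` column).
#' @param path File path.
#' @param delim Field delimiter.
#' @export
write_draws <- function(fit, path, delim = "\t") {
  draws <- if (inherits(fit, "mel_fit")) fit$draws else fit
  stopifnot(is.data.frame(draws), ".chain" %in% names(draws))
  readr::write_delim(draws, path, delim = delim)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path, delim = "\t") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE)
}

#' Serialize a virtual experiment or power table
#'
#' Virtual experiments and power grids are already tidy tables; these
#' helpers write them as delimited text, and `write_power_grid()` also
#' drops a JSON summary (cell count, power range, settings) alongside
#' when `json_path` is given.
#'
#' @param x A `mel_experiment` or `mel_power_grid` tibble.
#' @param path Output path for the delimited table.
#' @param delim Field delimiter.
#' @param json_path Optional path for the JSON summary.
#' @export
write_experiment <- function(x, path, delim = "\t") {
  readr::write_delim(tibble::as_tibble(x), path, delim = delim)
  invisible(path)
}

#' @rdname write_experiment
#' @export
write_power_grid <- function(x, path, delim = "\t", json_path = NULL) {
  readr::write_delim(tibble::as_tibble(x), path, delim = delim)
  if (!is.null(json_path)) {
    summary <- list(
      cells = nrow(x),
      class = unique(x$class),
      design = unique(x$design),
      replicates = unique(x$replicates),
      power_range = range(x$power)
    )
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
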