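#' Write a trial dataset to delimited text
#'
#' Long-format CSV with one row per sample: `subject`, `trial`, `perturbed`,
#' `direction`, `onset_ms`, `time_ms` and the value column, whose name
#' declares the units - `f0_hz` for raw Hz, `deviation` for normalized
#' fractional deviation. Ground truth, when given, goes to a JSON sidecar
#' `<path>.truth.json`.
#'
#' @param trials Long-format data.frame ([synth_subject()] layout) or a
#'   `psr_cohort` from [synth_cohort()].
#' @param path Output CSV file.
#' @param truths Optional named list of [psr_truth()] objects (taken from the
#'   cohort automatically).
#' @export
write_psr_dataset <- function(trials, path, truths = NULL) {
  if (inherits(trials, "psr_cohort")) {
    if (is.null(truths)) truths <- trials$truths
    trials <- trials$data
  }
  stopifnot(is.data.frame(trials))
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truths)) {
    jsonlite::write_json(
      lapply(truths, function(tr)
        list(model = tr$model, params = as.list(tr$params), f_T = tr$f_T,
             noise_sd = tr$noise_sd, ar1 = tr$ar1, drift_sd = tr$drift_sd)),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trial dataset from delimited text
#'
#' Validates the long-format schema written by [write_psr_dataset()]: the
#' required metadata columns must be present, the value column name declares
#' the units (`f0_hz` or `deviation` - never guessed), and all trials must
#' share a single sampling step.
#'
#' @param path CSV file.
#' @return The trials data.frame with attribute `units` (`"hz"` or
#'   `"deviation"`).
#' @export
read_psr_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "trial", "direction", "onset_ms", "time_ms")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dataset schema violation: missing column(s) ",
         paste(miss, collapse = ", "))
  units <- if ("f0_hz" %in% names(df)) "hz"
           else if ("deviation" %in% names(df)) "deviation"
           else stop("dataset schema violation: no value column ",
                     "(expected 'f0_hz' or 'deviation')")
  dts <- unique(unlist(tapply(df$time_ms, interaction(df$subject, df$trial,
                                                      drop = TRUE),
                              function(t) round(diff(sort(t)), 9))))
  if (length(dts) > 1L)
    stop("mixed sampling grids: found dt values ",
         paste(utils::head(dts, 5), collapse = ", "), " ms")
  attr(df, "units") <- units
  df
}
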