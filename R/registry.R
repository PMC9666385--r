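# The 19 controller configurations: 4 PID-family models and 15 DIVA/state-
# space variants. Equation ids: 4 = PID, 5 = basic DIVA, 6 = velocity-
# generalized DIVA, 7 = two-timescale DIVA. Free-parameter sets define which
# entries of the parameter vector the optimizer may move; all others stay 0.
psr_model_table <- list(
  P    = list(eq = 4L, free = c("alpha_P", "tau_A")),
  PI   = list(eq = 4L, free = c("alpha_P", "alpha_I", "tau_A")),
  PD   = list(eq = 4L, free = c("alpha_P", "alpha_D", "tau_A")),
  PID  = list(eq = 4L, free = c("alpha_P", "alpha_I", "alpha_D", "tau_A")),
  D1   = list(eq = 5L, free = c("alpha_A", "tau_A", "alpha_S")),
  D2   = list(eq = 5L, free = c("alpha_A", "tau_A", "alpha_S", "tau_S")),
  D3   = list(eq = 6L, free = c("alpha_A", "tau_A", "alpha_Av")),
  D4   = list(eq = 6L, free = c("alpha_A", "tau_A", "alpha_Av", "tau_Av")),
  D5   = list(eq = 6L, free = c("alpha_A", "tau_A", "alpha_S", "alpha_Av")),
  D6   = list(eq = 6L, free = c("alpha_A", "tau_A", "alpha_S", "tau_S", "alpha_Av")),
  D7   = list(eq = 6L, free = c("alpha_A", "tau_A", "alpha_S", "tau_S", "alpha_Av", "tau_Av")),
  D8   = list(eq = 6L, free = c("alpha_A", "tau_A", "alpha_S", "alpha_Av", "tau_Av", "alpha_Sv")),
  D9   = list(eq = 6L, free = c("alpha_A", "tau_A", "alpha_S", "tau_S", "alpha_Av", "tau_Av", "alpha_Sv")),
  D10  = list(eq = 6L, free = c("alpha_A", "tau_A", "alpha_S", "tau_S", "alpha_Av", "tau_Av", "alpha_Sv", "tau_Sv")),
  D11  = list(eq = 7L, free = c("alpha_A", "tau_A", "alpha_As", "tau_As")),
  D12  = list(eq = 7L, free = c("alpha_A", "tau_A", "alpha_S", "tau_S", "alpha_As", "tau_As")),
  D13  = list(eq = 7L, free = c("alpha_A", "tau_A", "alpha_S", "alpha_As", "tau_As", "alpha_Ss")),
  D14  = list(eq = 7L, free = c("alpha_A", "tau_A", "alpha_S", "tau_S", "alpha_As", "tau_As", "alpha_Ss")),
  D15  = list(eq = 7L, free = c("alpha_A", "tau_A", "alpha_S", "tau_S", "alpha_As", "tau_As", "alpha_Ss", "tau_Ss"))
)

#' Retrieve one controller model specification
#'
#' @param name Model name: one of `"P"`, `"PI"`, `"PD"`, `"PID"`,
#'   `"D1"`..`"D15"`.
#' @return An object of class `psr_model`: list with `name`, `equation`
#'   (4, 5, 6 or 7), `free` (free-parameter names), `k` (their count) and
#'   `lower`/`upper` default fitting bounds for the free parameters.
#' @examples
#' psr_model("D1")
#' @seealso [psr_models()] for the full registry.
#' @export
psr_model <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(psr_model_table))
    stop("unknown model: ", paste(name, collapse = ", "),
         " (see psr_models() for the registry)")
  entry <- psr_model_table[[name]]
  b <- psr_default_bounds()
  structure(
    list(name = name, equation = entry$eq, free = entry$free,
         k = length(entry$free),
         lower = b$lower[entry$free], upper = b$upper[entry$free]),
    class = "psr_model")
}

#' The model registry
#'
#' All 19 controller configurations compared by the framework: four PID-family
#' models and fifteen DIVA/state-space variants with 2-8 free parameters.
#'
#' @return Named list of [psr_model()] objects, length 19.
#' @examples
#' length(psr_models())
#' sapply(psr_models(), function(m) m$k)
#' @export
psr_models <- function() {
  out <- lapply(names(psr_model_table), psr_model)
  names(out) <- names(psr_model_table)
  out
}

#' @export
print.psr_model <- function(x, ...) {
  cat(sprintf("<psr_model> %s (equation %d, %d free parameters)\n",
              x$name, x$equation, x$k))
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' Export the model registry as a table
#'
#' Writes (or returns) a machine-readable table of the registry: model name,
#' governing equation, free-parameter count and free-parameter names.
#'
#' @param path Optional output file; `.json` extension selects JSON,
#'   anything else tab-separated text.
#' @return The registry as a data.frame (invisibly when written to `path`).
#' @export
export_model_registry <- function(path = NULL) {
  models <- psr_models()
  df <- data.frame(
    name = names(models),
    equation = vapply(models, function(m) m$equation, integer(1)),
    n_parameters = vapply(models, function(m) m$k, integer(1)),
    parameters = vapply(models, function(m) paste(m$free, collapse = ","),
                        character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
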