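# Canonical controller-parameter layout shared with src/sim.cpp.
# Gains are per-step increments; delays are seconds (rounded to grid steps
# at simulation time).
psr_param_names <- c("alpha_P", "alpha_I", "alpha_D",
                     "alpha_A", "alpha_S",
                     "alpha_Av", "alpha_Sv", "alpha_As", "alpha_Ss",
                     "tau_A", "tau_S", "tau_Av", "tau_Sv", "tau_As", "tau_Ss")

# Default fitting bounds when a parameter is free.
psr_default_bounds <- function() {
  lower <- c(alpha_P = -0.1, alpha_I = -0.001, alpha_D = -0.1,
             alpha_A = -0.1, alpha_S = -0.1,
             alpha_Av = -0.1, alpha_Sv = -0.1, alpha_As = -0.1, alpha_Ss = -0.1,
             tau_A = 0, tau_S = 0, tau_Av = -0.1, tau_Sv = -0.1,
             tau_As = 0, tau_Ss = 0)
  upper <- c(alpha_P = 1.1, alpha_I = 0.001, alpha_D = 1.1,
             alpha_A = 1.1, alpha_S = 1.1,
             alpha_Av = 1.1, alpha_Sv = 1.1, alpha_As = 1.1, alpha_Ss = 1.1,
             tau_A = 0.5, tau_S = 0.5, tau_Av = 0.5, tau_Sv = 0.5,
             tau_As = 0.5, tau_Ss = 0.5)
  list(lower = lower[psr_param_names], upper = upper[psr_param_names])
}

#' Controller parameter vector
#'
#' Builds the full named parameter vector used by the simulator. All gains
#' (`alpha_*`, per-step increments) and delays (`tau_*`, seconds) default to
#' zero; name any subset to set it.
#'
#' Gains: `alpha_P`, `alpha_I`, `alpha_D` (PID position/integral/derivative),
#' `alpha_A`, `alpha_S` (auditory and somatosensory position-error gains),
#' `alpha_Av`, `alpha_Sv` (velocity-error gains), `alpha_As`, `alpha_Ss`
#' (slow-component gains). Delays: `tau_A`, `tau_S` (sensory feedback
#' delays), `tau_Av`, `tau_Sv` (differential velocity delays, may be
#' negative), `tau_As`, `tau_Ss` (differential slow-component delays).
#'
#' @param ... Named parameter values, e.g. `alpha_A = 0.011, tau_A = 0.115`.
#' @return Named numeric vector of length 15.
#' @examples
#' psr_params(alpha_A = 0.011, alpha_S = 0.013, tau_A = 0.115)
#' @export
psr_params <- function(...) {
  p <- structure(numeric(length(psr_param_names)), names = psr_param_names)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameters must be named")
    bad <- setdiff(names(dots), psr_param_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    vals <- unlist(dots)
    if (!all(is.finite(vals))) stop("parameter values must be finite")
    p[names(dots)] <- vals
  }
  p
}

# Coerce a user-supplied params object (psr_params vector, named vector or
# named list) to the full 15-vector.
as_psr_params <- function(params) {
  if (is.list(params)) params <- unlist(params)
  if (is.null(names(params))) {
    if (length(params) == length(psr_param_names)) {
      names(params) <- psr_param_names
      return(params)
    }
    stop("parameters must be named")
  }
  do.call(psr_params, as.list(params))
}
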