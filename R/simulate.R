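#' Simulate a normalized f_o trajectory
#'
#' Runs a controller model in discrete time against a perturbation profile.
#' The plant is updated as `f[n+1] = f[n] + f_C[n]` in normalized units
#' (target = 1), with the controller command `f_C` given by the model's
#' governing equation and forced to zero throughout the baseline window
#' (t < 0). Delayed terms read the pre-onset history as "plant at target, no
#' perturbation". Delays are rounded to the nearest grid step.
#'
#' @param model A [psr_model()] or model name.
#' @param params Controller parameters ([psr_params()], or a named vector /
#'   list). Parameters outside the model's free set must be zero.
#' @param perturbation A [psr_perturbation()].
#' @param f_T Optional baseline f_o in Hz, carried on the returned trace.
#' @return A [psr_trace()]: fractional deviation from baseline per sample.
#' @examples
#' g <- psr_grid(t_start = -0.5, t_end = 1.5)
#' p <- psr_perturbation(g, -100, ramp_ms = 110)
#' tr <- psr_simulate("D1", psr_params(alpha_A = 0.011, alpha_S = 0.013,
#'                                     tau_A = 0.115), p)
#' max(tr$values)
#' @export
psr_simulate <- function(model, params, perturbation, f_T = NULL) {
  if (is.character(model)) model <- psr_model(model)
  stopifnot(inherits(model, "psr_model"),
            inherits(perturbation, "psr_perturbation"))
  par <- as_psr_params(params)
  fixed <- setdiff(psr_param_names, model$free)
  if (any(par[fixed] != 0))
    stop("non-zero value for parameter(s) not free in model ", model$name,
         ": ", paste(fixed[par[fixed] != 0], collapse = ", "))
  grid <- perturbation$grid
  max_delay_steps <- grid$n
  delays <- par[grepl("^tau_", names(par))]
  if (any(abs(round(delays / grid$dt)) > max_delay_steps))
    stop("a delay exceeds the grid capacity")
  dev <- cpp_simulate(model$equation, unname(par), perturbation$P,
                      grid$dt, grid$onset - 1L)
  psr_trace(dev, grid, f_T = f_T)
}

#' Closed-form steady-state compensation of the basic DIVA controller
#'
#' For the basic auditory + somatosensory position-error controller under a
#' sustained fractional shift `P`, the plant settles at
#' `f* = (alpha_A + alpha_S) / (alpha_A (1 + P) + alpha_S)` (normalized
#' units). The compensation ratio is the cents-space fraction of the
#' perturbation that this equilibrium opposes:
#' `-1200 log2(f*) / magnitude_cents`.
#'
#' @param alpha_A Auditory feedback gain.
#' @param alpha_S Somatosensory feedback gain.
#' @param magnitude_cents Signed perturbation size in cents (non-zero).
#' @return Fraction of the perturbation opposed (1 = full compensation).
#' @examples
#' steady_state_compensation(0.011, 0.013, -100)  # ~0.451
#' steady_state_compensation(0.02, 0, -100)       # 1: auditory-only
#' @export
steady_state_compensation <- function(alpha_A, alpha_S, magnitude_cents) {
  stopifnot(is.finite(alpha_A), is.finite(alpha_S),
            is.finite(magnitude_cents), magnitude_cents != 0)
  P <- cents_to_fraction(magnitude_cents)
  denom <- alpha_A * (1 + P) + alpha_S
  if (denom <= 0)
    stop("no stable equilibrium: alpha_A (1 + P) + alpha_S must be positive")
  if (alpha_A + alpha_S == 0) return(0)
  f_star <- (alpha_A + alpha_S) / denom
  -1200 * log2(f_star) / magnitude_cents
}
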