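#' Time grid for perturbation-aligned traces
#'
#' A uniform sampling grid in seconds relative to perturbation onset. The
#' pre-onset portion `[t_start, 0)` is the baseline window: the controller
#' command is forced to zero there, traces are normalized against it, and it
#' is excluded from fit error.
#'
#' @param dt Step size in seconds (default 0.005 s).
#' @param t_start Window start in seconds, strictly negative.
#' @param t_end Window end in seconds, strictly positive.
#' @return An object of class `psr_grid`: list with `dt`, `t_start`, `t_end`,
#'   `times` (sample times), `n` (sample count) and `onset` (1-based index of
#'   the t = 0 sample).
#' @examples
#' g <- psr_grid(t_start = -0.5, t_end = 1.5)
#' g$n          # 401 samples
#' g$times[g$onset]  # 0
#' @export
psr_grid <- function(dt = 0.005, t_start = -0.5, t_end = 1.5) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  stopifnot(is.finite(t_start), is.finite(t_end), t_start < 0, t_end > 0)
  n <- round((t_end - t_start) / dt) + 1L
  onset <- round(-t_start / dt) + 1L
  structure(
    list(dt = dt, t_start = t_start, t_end = t_end,
         times = t_start + (seq_len(n) - 1L) * dt, n = as.integer(n),
         onset = as.integer(onset)),
    class = "psr_grid")
}

#' @export
print.psr_grid <- function(x, ...) {
  cat(sprintf("<psr_grid> %d samples, dt = %g s, window [%g, %g] s (onset at index %d)\n",
              x$n, x$dt, x$t_start, x$t_end, x$onset))
  invisible(x)
}

#' Convert a pitch shift between cents and fractional units
#'
#' A shift of `c` cents multiplies frequency by `2^(c/1200)`; the fractional
#' shift is that factor minus one.
#'
#' @param cents Signed shift in cents (100 cents = one semitone).
#' @param fraction Signed fractional frequency shift.
#' @return The corresponding fractional shift (or cents).
#' @examples
#' cents_to_fraction(-100)   # -0.0561...
#' fraction_to_cents(cents_to_fraction(40))  # 40
#' @export
cents_to_fraction <- function(cents) {
  if (!all(is.finite(cents))) stop("`cents` must be finite")
  2^(cents / 1200) - 1
}

#' @rdname cents_to_fraction
#' @export
fraction_to_cents <- function(fraction) {
  if (!all(is.finite(fraction))) stop("`fraction` must be finite")
  if (any(fraction <= -1)) stop("`fraction` must be > -1")
  1200 * log2(1 + fraction)
}

#' Build a sampled perturbation profile
#'
#' The heard pitch is shifted by `magnitude_cents` starting at `onset_s`
#' (default 0, i.e. the grid's alignment point). With `ramp_ms = 0` the shift
#' is a step; otherwise the fractional shift rises linearly over the ramp and
#' then holds at the full value for the rest of the window.
#'
#' @param grid A [psr_grid()].
#' @param magnitude_cents Signed perturbation size in cents.
#' @param ramp_ms Linear ramp duration in milliseconds (0 = step onset).
#' @param onset_s Onset time in seconds; must lie on the grid window.
#' @return An object of class `psr_perturbation`: list with the `grid`,
#'   `magnitude_cents`, `ramp_ms`, `onset_s` and the sampled fractional shift
#'   `P` (one value per grid sample).
#' @examples
#' g <- psr_grid(t_start = -0.5, t_end = 1.5)
#' p <- psr_perturbation(g, -100, ramp_ms = 110)
#' range(p$P)  # 0 down to -0.0561
#' @export
psr_perturbation <- function(grid, magnitude_cents, ramp_ms = 0, onset_s = 0) {
  stopifnot(inherits(grid, "psr_grid"))
  stopifnot(is.finite(magnitude_cents), is.finite(ramp_ms), ramp_ms >= 0)
  if (onset_s < grid$t_start || onset_s > grid$t_end)
    stop("perturbation onset lies outside the time grid")
  full <- cents_to_fraction(magnitude_cents)
  tt <- grid$times - onset_s
  if (ramp_ms > 0) {
    frac <- pmin(pmax(tt / (ramp_ms / 1000), 0), 1)
  } else {
    frac <- as.numeric(tt >= 0)
  }
  structure(
    list(grid = grid, magnitude_cents = magnitude_cents, ramp_ms = ramp_ms,
         onset_s = onset_s, P = full * frac),
    class = "psr_perturbation")
}

#' @export
print.psr_perturbation <- function(x, ...) {
  kind <- if (x$ramp_ms > 0) sprintf("%g ms linear ramp", x$ramp_ms) else "step"
  cat(sprintf("<psr_perturbation> %+g cents (%s) at t = %g s on %d-sample grid\n",
              x$magnitude_cents, kind, x$onset_s, x$grid$n))
  invisible(x)
}

#' Construct a normalized f_o trace
#'
#' A trace is a sampled fundamental-frequency time series on a fixed grid,
#' stored as fractional deviation from baseline (0 = baseline).
#'
#' @param values Numeric vector of deviations, one per grid sample.
#' @param grid The [psr_grid()] the values are sampled on.
#' @param f_T Optional subject baseline mean in Hz.
#' @return An object of class `psr_trace`.
#' @export
psr_trace <- function(values, grid, f_T = NULL) {
  stopifnot(inherits(grid, "psr_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop("trace length does not match the grid")
  if (!all(is.finite(values))) stop("trace values must be finite")
  structure(list(values = values, grid = grid, f_T = f_T),
            class = "psr_trace")
}

#' @export
print.psr_trace <- function(x, ...) {
  cat(sprintf("<psr_trace> %d samples on [%g, %g] s; post-onset range [%.4g, %.4g]\n",
              x$grid$n, x$grid$t_start, x$grid$t_end,
              min(x$values[x$grid$onset:x$grid$n]),
              max(x$values[x$grid$onset:x$grid$n])))
  invisible(x)
}

#' @export
plot.psr_trace <- function(x, ..., xlab = "time re onset (ms)",
                           ylab = "f_o deviation (fraction of baseline)") {
  graphics::plot(x$grid$times * 1000, x$values, type = "l",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 0, lty = 3, col = "grey40")
  invisible(x)
}
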