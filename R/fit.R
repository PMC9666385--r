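#' Root-mean-square fit error over the post-onset window
#'
#' RMSE between a model simulation and an observed trace, computed from the
#' perturbation onset (t = 0) to the end of the grid only; the baseline
#' window is excluded by convention (the controller command is defined as
#' zero there).
#'
#' @inheritParams psr_simulate
#' @param data A [psr_trace()] on the same grid as `perturbation`.
#' @return RMSE in fractional-deviation units.
#' @export
fit_error <- function(model, params, data, perturbation) {
  stopifnot(inherits(data, "psr_trace"))
  check_same_grid(data$grid, perturbation$grid)
  sim <- psr_simulate(model, params, perturbation)
  post_onset_rmse(sim$values, data$values, data$grid$onset)
}

check_same_grid <- function(a, b) {
  if (a$n != b$n || a$dt != b$dt ||
      abs(a$t_start - b$t_start) > 1e-9 || abs(a$t_end - b$t_end) > 1e-9)
    stop("time grids do not match")
  invisible(TRUE)
}

post_onset_rmse <- function(x, y, onset) {
  idx <- onset:length(x)
  sqrt(mean((x[idx] - y[idx])^2))
}

#' Fit a controller model to a perturbation-response trace
#'
#' Optimizes the model's free parameters to minimize post-onset RMSE against
#' the data using the recombination swarm ([swarm_minimize()]). The optimizer
#' is run `control$n_repeats` times from independent seeds (derived as
#' `seed + repeat`); the minimum-RMSE solution is kept and Pearson's r
#' between the best simulation and the data over the post-onset window
#' summarizes fit quality.
#'
#' @param data A [psr_trace()] (typically a subject or group mean trace,
#'   normalized and aligned to perturbation onset).
#' @param model Model name or [psr_model()] (default `"D1"`).
#' @param perturbation The [psr_perturbation()] the data was collected under,
#'   on the same grid as `data`.
#' @param control A [swarm_control()].
#' @param seed Master integer seed.
#' @param lower,upper Optional named overrides of the model's default
#'   per-parameter bounds.
#' @return An object of class `psr_fit` with components `model`, `coef`
#'   (free parameters), `params` (full parameter vector), `rmse`, `r`,
#'   `repeats` (per-repeat seed/RMSE/convergence table), `fitted`
#'   (best-fit [psr_trace()]), `interior` (whether each free parameter is
#'   strictly inside its bounds), plus the inputs.
#' @examples
#' g <- psr_grid(t_start = -0.5, t_end = 1.5)
#' p <- psr_perturbation(g, -100, ramp_ms = 110)
#' target <- psr_simulate("D1", psr_params(alpha_A = 0.02, alpha_S = 0.01,
#'                                         tau_A = 0.1), p)
#' fit <- psr_fit(target, "D1", p,
#'                control = swarm_control(n_particles = 300, n_repeats = 2,
#'                                        max_iter = 150), seed = 7)
#' coef(fit)
#' @export
psr_fit <- function(data, model = "D1", perturbation,
                    control = swarm_control(), seed = 1,
                    lower = NULL, upper = NULL) {
  if (is.character(model)) model <- psr_model(model)
  stopifnot(inherits(data, "psr_trace"),
            inherits(perturbation, "psr_perturbation"))
  check_same_grid(data$grid, perturbation$grid)
  grid <- data$grid

  lo <- model$lower
  hi <- model$upper
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  if (any(lo > hi)) stop("lower bound exceeds upper bound")

  free_idx <- match(model$free, psr_param_names)
  objective <- function(X) {
    full <- matrix(0, nrow(X), length(psr_param_names))
    full[, free_idx] <- X
    cpp_batch_rmse(model$equation, full, perturbation$P, data$values,
                   grid$dt, grid$onset - 1L)
  }

  # delays act through rounding to grid steps, so the objective is
  # piecewise-constant in them; keep one-step jitter so neighbouring delay
  # bins stay reachable after the swarm contracts
  jfloor <- ifelse(grepl("^tau_", model$free), grid$dt, 0)

  repeats <- data.frame(repeat_ = seq_len(control$n_repeats),
                        seed = seed + seq_len(control$n_repeats),
                        rmse = NA_real_, iterations = NA_integer_,
                        converged = NA)
  best <- NULL
  for (r in seq_len(control$n_repeats)) {
    run <- swarm_minimize(objective, lo, hi, control = control,
                          seed = seed + r, vectorized = TRUE,
                          jitter_floor = jfloor)
    repeats$rmse[r] <- run$value
    repeats$iterations[r] <- run$iterations
    repeats$converged[r] <- run$converged
    if (is.null(best) || run$value < best$value) best <- run
  }

  coefs <- structure(best$par, names = model$free)
  params <- psr_params()
  params[model$free] <- coefs
  fitted_trace <- psr_simulate(model, params, perturbation, f_T = data$f_T)
  idx <- grid$onset:grid$n
  r_pearson <- suppressWarnings(cor(fitted_trace$values[idx], data$values[idx]))
  tol <- 1e-8 * (hi - lo)
  interior <- coefs > lo + tol & coefs < hi - tol

  structure(
    list(model = model, coef = coefs, params = params,
         rmse = best$value, r = r_pearson, repeats = repeats,
         fitted = fitted_trace, interior = interior,
         data = data, perturbation = perturbation, grid = grid,
         bounds = list(lower = lo, upper = hi),
         control = control, seed = seed),
    class = "psr_fit")
}

#' @export
print.psr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Controller model fit: %s (equation %d, k = %d)\n",
              x$model$name, x$model$equation, x$model$k))
  cat("Parameters:\n")
  print(round(x$coef, 6))
  cat(sprintf("Post-onset RMSE: %.*g   Pearson r: %.*g\n",
              digits, x$rmse, digits, x$r))
  invisible(x)
}

#' @export
summary.psr_fit <- function(object, ...) {
  bl <- object$data$values[seq_len(object$grid$onset - 1L)]
  N <- tryCatch(effective_df(bl, n = object$grid$n - object$grid$onset + 1L),
                error = function(e) NA_real_)
  mse <- object$rmse^2
  structure(
    list(fit = object, N = N,
         caic = if (is.finite(N) && mse > 0) caic(object$model$k, mse, N)
                else NA_real_,
         spread = diff(range(object$repeats$rmse))),
    class = "summary.psr_fit")
}

#' @export
print.summary.psr_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Effective df (from pre-onset data): %.1f\n", x$N))
  if (is.finite(x$caic)) cat(sprintf("cAIC: %.5f\n", x$caic))
  cat(sprintf("Repeat RMSE spread: %.3g over %d repeats\n",
              x$spread, nrow(x$fit$repeats)))
  if (!all(x$fit$interior))
    cat("Warning: parameter(s) at a bound:",
        paste(names(x$fit$interior)[!x$fit$interior], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.psr_fit <- function(object, ...) object$coef

#' @export
fitted.psr_fit <- function(object, ...) object$fitted

#' @export
residuals.psr_fit <- function(object, ...) {
  object$data$values - object$fitted$values
}

#' Predict the fitted controller's response
#'
#' Simulates the fitted parameters against a (possibly new) perturbation
#' profile.
#'
#' @param object A [psr_fit()].
#' @param perturbation A [psr_perturbation()]; defaults to the one fit.
#' @param ... Unused.
#' @return A [psr_trace()].
#' @export
predict.psr_fit <- function(object, perturbation = NULL, ...) {
  if (is.null(perturbation)) return(object$fitted)
  psr_simulate(object$model, object$params, perturbation,
               f_T = object$data$f_T)
}

#' Simulate noisy trial traces from a fitted model
#'
#' Draws trial-level deviation traces around the fitted model response using
#' the package's trial noise law (multiplicative AR(1) plus a per-trial
#' baseline offset; see [synth_subject()]).
#'
#' @param object A [psr_fit()].
#' @param nsim Number of trials.
#' @param seed Optional integer seed.
#' @param noise_sd Stationary AR(1) noise SD in deviation units.
#' @param ar1 Lag-1 autocorrelation of the noise at the grid step.
#' @param drift_sd SD of the per-trial constant baseline offset.
#' @param ... Unused.
#' @return Matrix `nsim` x `grid$n` of deviation traces.
#' @export
simulate.psr_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0.003, ar1 = 0.9, drift_sd = 0, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- object$grid$n
  out <- matrix(NA_real_, nsim, n)
  for (s in seq_len(nsim)) {
    eps <- ar1_noise(n, noise_sd, ar1)
    b <- if (drift_sd > 0) rnorm(1, 0, drift_sd) else 0
    out[s, ] <- (1 + object$fitted$values) * (1 + eps + b) - 1
  }
  out
}

#' @export
plot.psr_fit <- function(x, show_full_compensation = FALSE, ...) {
  tms <- x$grid$times * 1000
  ylim <- range(x$data$values, x$fitted$values)
  full <- NULL
  if (show_full_compensation) {
    full <- 1 / (1 + cents_to_fraction(x$perturbation$magnitude_cents)) - 1
    ylim <- range(ylim, full)
  }
  graphics::plot(tms, x$data$values, type = "l", col = "steelblue",
                 xlab = "time re onset (ms)",
                 ylab = "f_o deviation (fraction of baseline)",
                 ylim = ylim, ...)
  graphics::lines(tms, x$fitted$values, col = "firebrick", lwd = 2)
  if (!is.null(full))
    graphics::abline(h = full, col = "darkgreen", lty = 2)
  graphics::abline(v = 0, lty = 3, col = "grey40")
  graphics::legend("topleft", bty = "n", lwd = c(1, 2),
                   col = c("steelblue", "firebrick"),
                   legend = c("data", x$model$name))
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes the fitted parameters together with full provenance: model name,
#' bounds, master seed, per-repeat seeds and RMSEs, and fit quality.
#'
#' @param fit A [psr_fit()].
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @export
write_psr_fit <- function(fit, path = NULL) {
  obj <- list(model = fit$model$name, equation = fit$model$equation,
              k = fit$model$k,
              coef = as.list(fit$coef), rmse = fit$rmse, pearson_r = fit$r,
              bounds = list(lower = as.list(fit$bounds$lower),
                            upper = as.list(fit$bounds$upper)),
              seed = fit$seed,
              repeats = fit$repeats,
              interior = as.list(fit$interior))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            dataframe = "rows"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
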