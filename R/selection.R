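#' Effective degrees of freedom of autocorrelated residuals
#'
#' Residuals of f_o traces are correlated across timepoints, so the nominal
#' sample count overstates the information in a trace. Following the
#' Satterthwaite-Welch idea applied to the residual sum of squares, the
#' effective degrees of freedom of a length-`n` window with stationary
#' autocorrelations `rho_k` is `N = (tr R)^2 / tr(R^2)` where `R` is the
#' implied Toeplitz correlation matrix, i.e.
#' `N = n^2 / (n + 2 sum_k (n - k) rho_k^2)`, clipped to `[1, n]`.
#'
#' `effective_df()` estimates the autocorrelations from pre-onset (baseline)
#' data - which is common to all models being compared - pooling across
#' segments and tapering the estimate to zero from the first lag whose
#' autocorrelation is not distinguishable from noise (`|rho_k| < 2/sqrt(m)`
#' with `m` the pooled sample count), so that noise in high lags cannot
#' collapse the degrees of freedom. `effective_df_from_acf()` skips the
#' estimation step and takes autocorrelations directly.
#'
#' @param baseline A numeric vector, a list of numeric vectors, or a matrix
#'   (rows = segments) of pre-onset samples.
#' @param n Length of the scored (post-onset) window the degrees of freedom
#'   are for.
#' @param rho Autocorrelations at lags 1, 2, ... (lag 0 excluded).
#' @return Effective degrees of freedom, a scalar in `[1, n]`.
#' @examples
#' effective_df_from_acf(0.5^(1:99), n = 100)  # ~60.3 for AR(1), rho = 0.5
#' @export
effective_df <- function(baseline, n) {
  if (is.matrix(baseline))
    baseline <- lapply(seq_len(nrow(baseline)), function(i) baseline[i, ])
  if (!is.list(baseline)) baseline <- list(baseline)
  lens <- vapply(baseline, length, integer(1))
  if (any(lens < 2L)) stop("each baseline segment needs at least 2 samples")
  m <- sum(lens)
  mu <- mean(unlist(baseline))
  centered <- lapply(baseline, function(x) x - mu)
  g0 <- sum(vapply(centered, function(x) sum(x^2), numeric(1))) / m
  if (g0 <= 0) stop("degenerate (constant) baseline input")
  maxlag <- min(max(lens) - 1L, n - 1L)
  rho <- numeric(maxlag)
  for (k in seq_len(maxlag)) {
    gk <- sum(vapply(centered, function(x) {
      nk <- length(x) - k
      if (nk <= 0) 0 else sum(x[seq_len(nk)] * x[k + seq_len(nk)])
    }, numeric(1))) / m
    rho[k] <- gk / g0
  }
  thr <- 2 / sqrt(m)
  cut <- which(abs(rho) < thr)
  if (length(cut)) rho[seq.int(cut[1], maxlag)] <- 0
  effective_df_from_acf(rho, n)
}

#' @rdname effective_df
#' @export
effective_df_from_acf <- function(rho, n) {
  stopifnot(n >= 1, all(is.finite(rho)))
  k <- seq_along(rho)
  keep <- k < n
  s <- sum((n - k[keep]) * rho[keep]^2)
  N <- n^2 / (n + 2 * s)
  min(max(N, 1), n)
}

#' Corrected AIC for a trace fit
#'
#' AIC divided by the effective degrees of freedom `N`, so that values are
#' comparable across datasets of different length and autocorrelation:
#' `caic = 2k/N + ln(MSE) + 1 + ln(2*pi)`. This follows from
#' `AIC = 2k - 2 ln(L)` with the Gaussian log-likelihood approximation
#' `ln(L) = N/2 (-ln(MSE) - 1 - ln(2*pi))`.
#'
#' @param k Number of free parameters.
#' @param mse Mean squared error of the fit (positive).
#' @param N Effective degrees of freedom (positive); see [effective_df()].
#' @return The corrected AIC value (smaller is better).
#' @examples
#' caic(3, 1e-4, 200)
#' @export
caic <- function(k, mse, N) {
  stopifnot(k >= 0)
  if (!all(mse > 0)) stop("`mse` must be positive")
  if (!all(N > 0)) stop("`N` must be positive")
  2 * k / N + log(mse) + 1 + log(2 * pi)
}

#' Significance threshold for corrected-AIC differences
#'
#' The cAIC difference supporting a 20:1 relative likelihood between two
#' models: `2 ln(20) / N`. A model whose cAIC is lower than another's by more
#' than this threshold is, with 95 percent likelihood, the superior model.
#'
#' @inheritParams caic
#' @return The threshold value.
#' @examples
#' caic_threshold(200)
#' @export
caic_threshold <- function(N) {
  if (!all(N > 0)) stop("`N` must be positive")
  2 * log(20) / N
}

#' Relative likelihood of a model from an AIC difference
#'
#' `exp((AIC_min - AIC) / 2)`: the likelihood of the worse model relative to
#' the better one. For cAIC values, multiply the difference by `N` first (or
#' equivalently pass `aic = caic * N`).
#'
#' @param aic_min AIC of the better (smaller-AIC) model.
#' @param aic AIC of the model being compared (`aic >= aic_min`).
#' @return Value in `(0, 1]`.
#' @examples
#' relative_likelihood(10, 12)           # exp(-1)
#' relative_likelihood(0, 2 * log(20))   # 0.05, the 20:1 rule
#' @export
relative_likelihood <- function(aic_min, aic) {
  if (any(aic < aic_min)) stop("`aic` must be >= `aic_min`")
  exp((aic_min - aic) / 2)
}

#' Combined out-of-sample cAIC across test trials
#'
#' For cross-validation, a single cAIC per model/subject is formed by setting
#' MSE to the mean of the per-test-trial MSEs and the effective sample count
#' to the mean per-trial effective degrees of freedom multiplied by the
#' subject's trial count.
#'
#' @param mse Per-test-trial mean squared errors (non-empty, positive).
#' @param df Per-test-trial effective degrees of freedom (positive); recycled
#'   against `mse`.
#' @param n_trials Total number of trials for the model/subject combination.
#' @param k Number of free parameters.
#' @return The combined cAIC value.
#' @examples
#' combined_caic(c(1e-4, 4e-4), c(50, 50), n_trials = 20, k = 3)
#' @export
combined_caic <- function(mse, df, n_trials, k) {
  if (!length(mse)) stop("`mse` must be non-empty")
  if (!all(df > 0)) stop("`df` must be positive")
  stopifnot(n_trials >= 1)
  caic(k, mean(mse), mean(df) * n_trials)
}

#' Intraclass correlation of parameter estimates
#'
#' Quantifies stability of a parameter across repeated estimates (e.g.
#' cross-validation iterations):
#' `ICC = sigma_between^2 / (sigma_between^2 + sigma_within^2)`, where
#' `sigma_between` is the standard deviation of subject means and
#' `sigma_within` the pooled within-subject standard deviation (square root
#' of the mean per-subject unbiased variance). Values below 0.5 indicate poor
#' reliability; 0.5-0.75 moderate, 0.75-0.9 good, and 0.9-1 excellent.
#'
#' @param samples Matrix of parameter estimates, subjects in rows and
#'   iterations in columns (at least 2 of each).
#' @return List with `sigma_between`, `sigma_within` and `icc` (`NA` when
#'   both variance components are zero, i.e. all estimates identical).
#' @examples
#' m <- rbind(rnorm(10, 0, 0.1), rnorm(10, 2, 0.1), rnorm(10, 4, 0.1))
#' icc(m)$icc  # close to 1
#' @export
icc <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L || ncol(samples) < 2L)
    stop("need at least 2 subjects and 2 iterations")
  sb <- sd(rowMeans(samples))
  sw <- sqrt(mean(apply(samples, 1, var)))
  val <- if (sb == 0 && sw == 0) NA_real_ else sb^2 / (sb^2 + sw^2)
  list(sigma_between = sb, sigma_within = sw, icc = val)
}

#' Fit and compare controller models on one trace
#'
#' Fits each requested model to the trace, computes a shared effective
#' degrees of freedom from the trace's pre-onset window, and reports RMSE,
#' Pearson r and cAIC per model, flagging all models within the cAIC
#' threshold of the best one ("best models").
#'
#' @inheritParams psr_fit
#' @param models Character vector of registry model names (default: all 19).
#' @return An object of class `psr_compare`: a data.frame with one row per
#'   model (`model`, `k`, `rmse`, `r`, `caic`, `delta_caic`, `best`) plus
#'   attributes `N` (effective df), `threshold`, and `fits` (the underlying
#'   [psr_fit()] objects).
#' @export
psr_compare <- function(data, perturbation, models = names(psr_model_table),
                        control = swarm_control(), seed = 1) {
  stopifnot(inherits(data, "psr_trace"))
  fits <- lapply(seq_along(models), function(i)
    psr_fit(data, models[i], perturbation, control = control,
            seed = seed + 1000L * i))
  names(fits) <- models
  N <- effective_df(data$values[seq_len(data$grid$onset - 1L)],
                    n = data$grid$n - data$grid$onset + 1L)
  df <- data.frame(
    model = models,
    k = vapply(fits, function(f) f$model$k, integer(1)),
    rmse = vapply(fits, function(f) f$rmse, numeric(1)),
    r = vapply(fits, function(f) f$r, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  df$caic <- caic(df$k, pmax(df$rmse^2, .Machine$double.xmin), N)
  thr <- caic_threshold(N)
  df$delta_caic <- df$caic - min(df$caic)
  df$best <- df$delta_caic <= thr
  structure(df, N = N, threshold = thr, fits = fits,
            class = c("psr_compare", "data.frame"))
}

#' @export
print.psr_compare <- function(x, digits = 5, ...) {
  cat(sprintf("Model comparison (N_eff = %.1f, cAIC threshold = %.5f)\n",
              attr(x, "N"), attr(x, "threshold")))
  df <- as.data.frame(x)
  df$rmse <- signif(df$rmse, digits)
  df$r <- signif(df$r, 4)
  df$caic <- round(df$caic, 5)
  df$delta_caic <- round(df$delta_caic, 5)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a model-comparison report
#'
#' Writes the comparison table as tab-separated text plus a JSON summary
#' marking the models within the cAIC threshold of the best.
#'
#' @param comparison A [psr_compare()] result.
#' @param path Output stem; `<path>.tsv` and `<path>.json` are written.
#' @export
write_psr_compare <- function(comparison, path) {
  df <- as.data.frame(comparison)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(N_effective = attr(comparison, "N"),
         caic_threshold = attr(comparison, "threshold"),
         best_models = df$model[df$best],
         models = df),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(path)
}
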