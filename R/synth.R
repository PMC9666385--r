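# AR(1) noise with stationary SD `sd` and lag-1 coefficient `phi`.
ar1_noise <- function(n, sd, phi) {
  if (sd <= 0) return(numeric(n))
  if (phi == 0) return(rnorm(n, 0, sd))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd)
  innov <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
  for (i in 2:n) e[i] <- phi * e[i - 1] + innov[i - 1]
  e
}

#' Sustained-vowel pitch-perturbation study designs
#'
#' Two built-in designs emulate the classic paradigms: `"study1"` - a 4-s
#' sustained /a/, 80 trials of which 20 carry a -100-cent perturbation with a
#' 110-ms linear ramp, onset jittered 1.0-1.5 s into the trial, no two
#' perturbed trials consecutive, parse window -500..+1500 ms; `"study2"` - a
#' 3-s sustained /i/, 60 trials all perturbed by a +/-100-cent step, onset
#' jittered 0.5-1.0 s after voice onset, direction pseudorandomized with at
#' most five consecutive trials in the same direction, parse window
#' -400..+1400 ms. Any field can be overridden through `...` (e.g. smaller
#' trial counts for quick simulations).
#'
#' @param name `"study1"` or `"study2"`.
#' @param ... Named overrides of design fields.
#' @return An object of class `psr_design`: trial duration `dur_s`, `n_trials`,
#'   `n_perturbed`, `directions` (subset of -1/+1), `magnitude_cents`
#'   (unsigned), `ramp_ms`, `jitter_s` (onset window), `parse_s` (window
#'   around onset), `dt`, `max_same_direction`,
#'   `no_consecutive_perturbed`.
#' @examples
#' study_design("study1")
#' study_design("study2", n_trials = 20)
#' @export
study_design <- function(name = c("study1", "study2"), ...) {
  name <- match.arg(name)
  d <- if (name == "study1") {
    list(name = "study1", dur_s = 4, n_trials = 80L, n_perturbed = 20L,
         directions = -1, magnitude_cents = 100, ramp_ms = 110,
         jitter_s = c(1.0, 1.5), parse_s = c(-0.5, 1.5), dt = 0.005,
         max_same_direction = Inf, no_consecutive_perturbed = TRUE)
  } else {
    list(name = "study2", dur_s = 3, n_trials = 60L, n_perturbed = 60L,
         directions = c(-1, 1), magnitude_cents = 100, ramp_ms = 0,
         jitter_s = c(0.5, 1.0), parse_s = c(-0.4, 1.4), dt = 0.005,
         max_same_direction = 5L, no_consecutive_perturbed = FALSE)
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(d))
  if (length(bad)) stop("unknown design field(s): ", paste(bad, collapse = ", "))
  d[names(ov)] <- ov
  stopifnot(d$parse_s[1] < 0, d$parse_s[2] > 0,
            d$jitter_s[1] + d$parse_s[1] >= 0,
            d$jitter_s[2] + d$parse_s[2] <= d$dur_s,
            d$n_perturbed <= d$n_trials)
  if (d$no_consecutive_perturbed && d$n_perturbed > (d$n_trials + 1L) %/% 2L)
    stop("too many perturbed trials for the no-consecutive constraint")
  structure(d, class = "psr_design")
}

#' @export
print.psr_design <- function(x, ...) {
  cat(sprintf("<psr_design> %s: %g s vowel, %d trials (%d perturbed), %s%g cents, %s\n",
              x$name, x$dur_s, x$n_trials, x$n_perturbed,
              if (length(x$directions) > 1) "+/-" else ifelse(x$directions < 0, "-", "+"),
              x$magnitude_cents,
              if (x$ramp_ms > 0) sprintf("%g ms ramp", x$ramp_ms) else "step"))
  cat(sprintf("  onset jitter %g-%g s, parse window %g..%g ms, dt %g s\n",
              x$jitter_s[1], x$jitter_s[2],
              x$parse_s[1] * 1000, x$parse_s[2] * 1000, x$dt))
  invisible(x)
}

#' Ground-truth description of a synthetic subject
#'
#' @param model Registry model name generating the subject's responses.
#' @param params Controller parameters ([psr_params()] or named vector).
#' @param f_T Baseline f_o in Hz.
#' @param noise_sd Stationary SD of the multiplicative AR(1) trial noise, in
#'   deviation units.
#' @param ar1 Lag-1 coefficient of the trial noise at the grid step.
#' @param drift_sd SD of the per-trial constant baseline offset.
#' @return An object of class `psr_truth`.
#' @export
psr_truth <- function(model = "D1",
                      params = psr_params(alpha_A = 0.011, alpha_S = 0.013,
                                          tau_A = 0.115),
                      f_T = 200, noise_sd = 0.003, ar1 = 0.9,
                      drift_sd = 0.001) {
  stopifnot(noise_sd >= 0, drift_sd >= 0, ar1 >= 0, ar1 < 1, f_T > 0)
  structure(list(model = model, params = as_psr_params(params), f_T = f_T,
                 noise_sd = noise_sd, ar1 = ar1, drift_sd = drift_sd),
            class = "psr_truth")
}

# Perturbation schedule for one subject: which trials are perturbed and in
# which direction, honoring the design's sequencing constraints.
schedule_trials <- function(design) {
  n <- design$n_trials
  perturbed <- rep(FALSE, n)
  if (design$no_consecutive_perturbed && design$n_perturbed < n) {
    # choose positions with no two adjacent via the gap construction
    pos <- sort(sample.int(n - design$n_perturbed + 1L, design$n_perturbed))
    pos <- pos + seq_len(design$n_perturbed) - 1L
    perturbed[pos] <- TRUE
  } else {
    perturbed[sample.int(n, design$n_perturbed)] <- TRUE
  }
  dirs <- rep(NA_real_, n)
  k <- design$n_perturbed
  if (length(design$directions) == 1L) {
    dirs[perturbed] <- design$directions
  } else {
    half <- rep(design$directions, length.out = k)
    repeat {
      cand <- sample(half)
      if (is.infinite(design$max_same_direction) ||
          max(rle(cand)$lengths) <= design$max_same_direction) break
    }
    dirs[perturbed] <- cand
  }
  list(perturbed = perturbed, direction = dirs)
}

#' Generate one synthetic subject's trials
#'
#' Simulates every trial of the design for a ground-truth subject: the onset
#' is drawn uniformly in the jitter window (snapped to the grid), the truth
#' model is simulated against that trial's perturbation, scaled to Hz by
#' `f_T`, and corrupted with multiplicative AR(1) noise plus a per-trial
#' constant baseline offset. Unperturbed trials contain baseline plus noise.
#'
#' @param design A [study_design()].
#' @param truth A [psr_truth()].
#' @param subject Subject label stored in the output.
#' @param seed Optional integer seed.
#' @return Long-format data.frame with columns `subject`, `trial`,
#'   `perturbed`, `direction`, `onset_ms`, `time_ms`, `f0_hz`.
#' @examples
#' d <- study_design("study1", n_trials = 4, n_perturbed = 2)
#' head(synth_subject(d, psr_truth(noise_sd = 0), seed = 1))
#' @export
synth_subject <- function(design, truth, subject = "S1", seed = NULL) {
  stopifnot(inherits(design, "psr_design"), inherits(truth, "psr_truth"))
  if (!is.null(seed)) set.seed(seed)
  sched <- schedule_trials(design)
  n_samp <- round(design$dur_s / design$dt) + 1L
  t_ms <- (seq_len(n_samp) - 1L) * design$dt * 1000
  rows <- vector("list", design$n_trials)
  for (tr in seq_len(design$n_trials)) {
    if (sched$perturbed[tr]) {
      onset <- runif(1, design$jitter_s[1], design$jitter_s[2])
      onset <- round(onset / design$dt) * design$dt
      g <- psr_grid(design$dt, t_start = -onset, t_end = design$dur_s - onset)
      p <- psr_perturbation(g, sched$direction[tr] * design$magnitude_cents,
                            ramp_ms = design$ramp_ms)
      dev <- psr_simulate(truth$model, truth$params, p)$values
      onset_ms <- onset * 1000
    } else {
      dev <- numeric(n_samp)
      onset_ms <- NA_real_
    }
    eps <- ar1_noise(n_samp, truth$noise_sd, truth$ar1)
    b <- if (truth$drift_sd > 0) rnorm(1, 0, truth$drift_sd) else 0
    f0 <- truth$f_T * (1 + dev) * (1 + eps + b)
    rows[[tr]] <- data.frame(subject = subject, trial = tr,
                             perturbed = sched$perturbed[tr],
                             direction = sched$direction[tr],
                             onset_ms = onset_ms, time_ms = t_ms, f0_hz = f0,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject ground-truth parameters (uniformly within ranges
#' centered on typical group-level estimates for the basic DIVA controller,
#' unless explicit truths are given) and generates every subject's trials.
#'
#' @param design A [study_design()].
#' @param n_subjects Number of subjects (ignored when `truths` is given).
#' @param truths Optional list of [psr_truth()] objects, one per subject.
#' @param model Truth model name used when drawing parameters.
#' @param ranges Named list of `c(lower, upper)` ranges to draw free
#'   parameters from. Defaults: `alpha_A` 0.006-0.011, `alpha_S` 0.013-0.033,
#'   `tau_A` 0.093-0.115 s.
#' @param f_T Baseline f_o in Hz (recycled across subjects).
#' @param noise_sd,ar1,drift_sd Trial noise law, see [psr_truth()].
#' @param seed Integer seed.
#' @return An object of class `psr_cohort`: list with `data` (long-format
#'   data.frame over all subjects), `truths` and `design`.
#' @export
synth_cohort <- function(design, n_subjects = 6, truths = NULL, model = "D1",
                         ranges = list(alpha_A = c(0.006, 0.011),
                                       alpha_S = c(0.013, 0.033),
                                       tau_A = c(0.093, 0.115)),
                         f_T = 200, noise_sd = 0.003, ar1 = 0.9,
                         drift_sd = 0.001, seed = 1) {
  stopifnot(inherits(design, "psr_design"))
  set.seed(seed)
  if (is.null(truths)) {
    spec <- psr_model(model)
    truths <- lapply(seq_len(n_subjects), function(i) {
      args <- lapply(ranges, function(r) runif(1, r[1], r[2]))
      bad <- setdiff(names(args), spec$free)
      if (length(bad)) stop("range given for non-free parameter: ",
                            paste(bad, collapse = ", "))
      psr_truth(model = model, params = do.call(psr_params, args),
                f_T = f_T, noise_sd = noise_sd, ar1 = ar1,
                drift_sd = drift_sd)
    })
  }
  n_subjects <- length(truths)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  names(truths) <- ids
  data <- do.call(rbind, lapply(seq_len(n_subjects), function(i)
    synth_subject(design, truths[[i]], subject = ids[i],
                  seed = seed + 7919L * i)))
  structure(list(data = data, truths = truths, design = design),
            class = "psr_cohort")
}

#' Align, normalize and average perturbed trials
#'
#' Applies the standard preprocessing to raw Hz trials: each perturbed trial
#' is cropped to the design's parse window around its own onset, divided by
#' its baseline (pre-onset) average and expressed as fractional deviation,
#' and upshift-trial deviations are flipped so both perturbation directions
#' share one representation. The subject mean trace is the per-timepoint mean
#' across trials; the subject's baseline average in Hz is kept as `f_T`.
#'
#' @param trials Long-format data.frame as produced by [synth_subject()] (or
#'   read by [read_psr_dataset()]): columns `subject`, `trial`, `direction`,
#'   `onset_ms`, `time_ms`, `f0_hz`; unperturbed trials (missing `onset_ms`)
#'   are dropped.
#' @param design The [study_design()] providing the parse window and step.
#' @return An object of class `psr_dataset`: list with `grid` (parse-window
#'   [psr_grid()]), `design`, and `subjects` - a named list, one entry per
#'   subject, each with `trials` (matrix trials x samples of deviations),
#'   `trial_ids`, `direction`, `f_T` and `mean` (a [psr_trace()]).
#' @export
preprocess_trials <- function(trials, design) {
  stopifnot(is.data.frame(trials), inherits(design, "psr_design"))
  need <- c("subject", "trial", "direction", "onset_ms", "time_ms", "f0_hz")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  grid <- psr_grid(design$dt, design$parse_s[1], design$parse_s[2])
  rel <- round(grid$times / design$dt)
  subjects <- list()
  for (s in unique(trials$subject)) {
    ds <- trials[trials$subject == s & !is.na(trials$onset_ms), ]
    ids <- unique(ds$trial)
    mat <- matrix(NA_real_, length(ids), grid$n)
    dirs <- numeric(length(ids))
    bases <- numeric(length(ids))
    for (j in seq_along(ids)) {
      dtr <- ds[ds$trial == ids[j], ]
      dtr <- dtr[order(dtr$time_ms), ]
      onset_idx <- round(dtr$onset_ms[1] / 1000 / design$dt)
      idx <- onset_idx + rel + 1L
      if (any(idx < 1L) || any(idx > nrow(dtr)))
        stop("trial ", ids[j], " of subject ", s,
             " is too short for the parse window")
      f0 <- dtr$f0_hz[idx]
      base <- mean(f0[seq_len(grid$onset - 1L)])
      dev <- f0 / base - 1
      if (!is.na(dtr$direction[1]) && dtr$direction[1] > 0) dev <- -dev
      mat[j, ] <- dev
      dirs[j] <- dtr$direction[1]
      bases[j] <- base
    }
    f_T <- mean(bases)
    subjects[[s]] <- list(trials = mat, trial_ids = ids, direction = dirs,
                          f_T = f_T,
                          mean = psr_trace(colMeans(mat), grid, f_T = f_T))
  }
  structure(list(grid = grid, design = design, subjects = subjects),
            class = "psr_dataset")
}

#' @export
print.psr_dataset <- function(x, ...) {
  nt <- vapply(x$subjects, function(s) nrow(s$trials), integer(1))
  cat(sprintf("<psr_dataset> %d subject(s), %s perturbed trials each, %d samples on [%g, %g] ms\n",
              length(x$subjects),
              if (length(unique(nt)) == 1L) as.character(nt[1])
              else paste(min(nt), "-", max(nt)),
              x$grid$n, x$grid$t_start * 1000, x$grid$t_end * 1000))
  invisible(x)
}

#' Group mean trace with standard error band
#'
#' Averages subject mean traces per timepoint and reports the standard error
#' of that mean across subjects.
#'
#' @param x A `psr_dataset` (from [preprocess_trials()]) or a list of
#'   [psr_trace()] subject means on a common grid.
#' @return List with `mean` (a [psr_trace()]) and `sem` (numeric vector,
#'   zero for a single subject).
#' @export
group_mean <- function(x) {
  traces <- if (inherits(x, "psr_dataset"))
    lapply(x$subjects, `[[`, "mean") else x
  stopifnot(length(traces) >= 1)
  g <- traces[[1]]$grid
  for (tr in traces) check_same_grid(g, tr$grid)
  m <- do.call(rbind, lapply(traces, `[[`, "values"))
  mu <- colMeans(m)
  sem <- if (nrow(m) > 1) apply(m, 2, sd) / sqrt(nrow(m)) else numeric(g$n)
  list(mean = psr_trace(mu, g), sem = sem)
}

#' Compensation percentage of a response trace
#'
#' The mean deviation over the final 250 ms of the window, converted to
#' cents and expressed as a percentage of the perturbation magnitude; the
#' sign is positive when the response opposes the shift.
#'
#' @param trace A [psr_trace()].
#' @param magnitude_cents Signed perturbation magnitude the trace responds
#'   to (after any direction-flipping, typically negative).
#' @return Compensation in percent (100 = full compensation).
#' @examples
#' g <- psr_grid(t_start = -0.5, t_end = 1.5)
#' p <- psr_perturbation(g, -100)
#' tr <- psr_simulate("D1", psr_params(alpha_A = 0.02), p)
#' compensation_percent(tr, -100)  # approaches 100 for an auditory-only model
#' @export
compensation_percent <- function(trace, magnitude_cents) {
  stopifnot(inherits(trace, "psr_trace"), magnitude_cents != 0)
  g <- trace$grid
  if (g$t_end - g$t_start < 0.25) stop("window shorter than 250 ms")
  idx <- which(g$times > g$t_end - 0.25 + 1e-9)
  mdev <- mean(trace$values[idx])
  -100 * fraction_to_cents(mdev) / magnitude_cents
}
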