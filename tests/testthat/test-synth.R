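test_that("built-in study designs carry the documented protocol", {
  d1 <- study_design("study1")
  expect_equal(d1$dur_s, 4)
  expect_identical(d1$n_trials, 80L)
  expect_identical(d1$n_perturbed, 20L)
  expect_equal(d1$directions, -1)
  expect_equal(d1$ramp_ms, 110)
  expect_equal(d1$jitter_s, c(1.0, 1.5))
  expect_equal(d1$parse_s, c(-0.5, 1.5))
  expect_true(d1$no_consecutive_perturbed)
  d2 <- study_design("study2")
  expect_equal(d2$dur_s, 3)
  expect_identical(d2$n_trials, 60L)
  expect_identical(d2$n_perturbed, 60L)
  expect_setequal(d2$directions, c(-1, 1))
  expect_equal(d2$ramp_ms, 0)
  expect_equal(d2$jitter_s, c(0.5, 1.0))
  expect_equal(d2$parse_s, c(-0.4, 1.4))
  expect_equal(d2$max_same_direction, 5L)
  expect_error(study_design("study1", bogus = 1), "unknown design field")
  expect_error(study_design("study1", n_trials = 30L, n_perturbed = 20L),
               "no-consecutive")
})

test_that("trial schedules honor the sequencing constraints", {
  for (s in 1:20) {
    set.seed(s)
    d1 <- study_design("study1")
    sched <- psrfit:::schedule_trials(d1)
    expect_identical(sum(sched$perturbed), 20L)
    # no two consecutive perturbed trials
    expect_false(any(sched$perturbed[-1] & sched$perturbed[-80]))
    d2 <- study_design("study2")
    sched2 <- psrfit:::schedule_trials(d2)
    expect_true(all(sched2$perturbed))
    runs <- rle(sched2$direction)$lengths
    expect_lte(max(runs), 5L)
    expect_equal(sum(sched2$direction == 1), 30L)
  }
})

test_that("zero-noise trials reproduce the truth model exactly", {
  design <- study_design("study1", n_trials = 6, n_perturbed = 3)
  truth <- psr_truth(noise_sd = 0, drift_sd = 0, f_T = 220)
  df <- synth_subject(design, truth, seed = 2)
  pert <- df[!is.na(df$onset_ms), ]
  # onsets lie in the jitter window
  onsets <- unique(pert$onset_ms) / 1000
  expect_true(all(onsets >= design$jitter_s[1] - 1e-9 &
                  onsets <= design$jitter_s[2] + 1e-9))
  for (tr in unique(pert$trial)) {
    d <- pert[pert$trial == tr, ]
    onset <- d$onset_ms[1] / 1000
    g <- psr_grid(design$dt, -onset, design$dur_s - onset)
    p <- psr_perturbation(g, d$direction[1] * design$magnitude_cents,
                          ramp_ms = design$ramp_ms)
    dev <- psr_simulate(truth$model, truth$params[psr_model(truth$model)$free],
                        p)$values
    expect_equal(d$f0_hz, 220 * (1 + dev), tolerance = 1e-12)
  }
  # unperturbed trials are flat at the baseline
  ctrl <- df[is.na(df$onset_ms), ]
  expect_true(all(ctrl$f0_hz == 220))
})

test_that("trial noise matches the configured stationary law", {
  design <- study_design("study1", n_trials = 500, n_perturbed = 0L)
  truth <- psr_truth(noise_sd = 0.004, ar1 = 0.9, drift_sd = 0, f_T = 200)
  df <- synth_subject(design, truth, seed = 9)
  mat <- matrix(df$f0_hz / 200 - 1, nrow = 500, byrow = TRUE)
  per_sample_sd <- apply(mat, 2, sd)
  expect_lt(abs(mean(per_sample_sd) / 0.004 - 1), 0.05)
  # lag-1 autocorrelation near the configured coefficient
  ac1 <- mean(apply(mat[1:100, ], 1, function(x)
    cor(x[-1], x[-length(x)])))
  expect_lt(abs(ac1 - 0.9), 0.05)
})

test_that("preprocessing normalizes, aligns and flips as specified", {
  design <- study_design("study1", n_trials = 8, n_perturbed = 4)
  cohort <- synth_cohort(design, n_subjects = 2, noise_sd = 0.002,
                         drift_sd = 0.002, seed = 5)
  ds <- preprocess_trials(cohort$data, design)
  expect_identical(ds$grid$n, 401L)
  base <- seq_len(ds$grid$onset - 1L)
  for (s in ds$subjects) {
    expect_identical(nrow(s$trials), 4L)
    # per-trial baseline mean is zero by construction of the divisor
    expect_true(all(abs(rowMeans(s$trials[, base])) < 1e-12))
    expect_equal(s$mean$values, colMeans(s$trials))
  }
  # zero-noise preprocessing recovers the simulated deviation exactly
  d0 <- study_design("study1", n_trials = 4, n_perturbed = 2)
  c0 <- synth_cohort(d0, n_subjects = 1, noise_sd = 0, drift_sd = 0, seed = 3)
  ds0 <- preprocess_trials(c0$data, d0)
  truth <- c0$truths[[1]]
  p <- psr_perturbation(ds0$grid, -d0$magnitude_cents, ramp_ms = d0$ramp_ms)
  sim <- psr_simulate(truth$model, truth$params[psr_model(truth$model)$free], p)
  expect_equal(ds0$subjects[[1]]$mean$values, sim$values, tolerance = 1e-9)
})

test_that("flipped upshift responses match downshift responses to O(P^2)", {
  par <- psr_params(alpha_A = 0.011, alpha_S = 0.013, tau_A = 0.115)
  down <- study_design("study1", n_trials = 2, n_perturbed = 1,
                       directions = -1)
  up <- study_design("study1", n_trials = 2, n_perturbed = 1, directions = 1)
  truth <- psr_truth(params = par, noise_sd = 0, drift_sd = 0)
  ds_d <- preprocess_trials(synth_subject(down, truth, seed = 7), down)
  ds_u <- preprocess_trials(synth_subject(up, truth, seed = 7), up)
  # the upshift trial was negated during preprocessing
  expect_lt(max(abs(ds_u$subjects[[1]]$mean$values -
                    ds_d$subjects[[1]]$mean$values)), 0.004)
})

test_that("group mean and SEM behave as per-timepoint statistics", {
  g <- psr_grid(0.005, -0.5, 1.5)
  one <- list(psr_trace(rep(0.02, g$n), g))
  gm1 <- group_mean(one)
  expect_equal(gm1$mean$values, rep(0.02, g$n))
  expect_equal(gm1$sem, numeric(g$n))
  two <- list(psr_trace(rep(0.01, g$n), g), psr_trace(rep(0.03, g$n), g))
  expect_equal(group_mean(two)$mean$values, rep(0.02, g$n))
  # SEM approaches sigma/sqrt(N) for i.i.d. subject noise
  set.seed(19)
  sigma <- 0.005; n_sub <- 12
  traces <- lapply(seq_len(n_sub), function(i)
    psr_trace(rnorm(g$n, 0, sigma), g))
  gm <- group_mean(traces)
  expect_lt(abs(mean(gm$sem) / (sigma / sqrt(n_sub)) - 1), 0.05)
  expect_error(group_mean(list(one[[1]],
                               psr_trace(numeric(361),
                                         psr_grid(0.005, -0.4, 1.4)))),
               "grids do not match")
})

test_that("compensation percentage uses the cents-space convention", {
  g <- psr_grid(0.005, -0.5, 1.5)
  expect_equal(compensation_percent(psr_trace(numeric(g$n), g), -100), 0)
  # pinned at exact full compensation
  full_dev <- 1 / (1 + cents_to_fraction(-100)) - 1
  expect_equal(compensation_percent(psr_trace(rep(full_dev, g$n), g), -100),
               100, tolerance = 1e-9)
  # long simulation approaches the steady-state oracle
  g_long <- psr_grid(0.005, -0.5, 30)
  tr <- psr_simulate("D1", psr_params(alpha_A = 0.011, alpha_S = 0.013,
                                      tau_A = 0.115),
                     psr_perturbation(g_long, -100))
  oracle <- 100 * steady_state_compensation(0.011, 0.013, -100)
  expect_equal(compensation_percent(tr, -100), oracle, tolerance = 0.01)
  expect_equal(compensation_percent(tr, -100), 45.1, tolerance = 0.2)
  expect_error(compensation_percent(psr_trace(numeric(21),
                                              psr_grid(0.005, -0.05, 0.05)),
                                    -100), "250 ms")
})
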