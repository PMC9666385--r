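test_that("swarm finds simple minima and respects bounds", {
  seen_lo <- c(Inf, Inf)
  seen_hi <- c(-Inf, -Inf)
  fn <- function(x) {
    seen_lo <<- pmin(seen_lo, x)
    seen_hi <<- pmax(seen_hi, x)
    sum((x - c(0.3, 0.7))^2)
  }
  out <- swarm_minimize(fn, lower = c(-0.1, -0.1), upper = c(1.1, 1.1),
                        control = swarm_control(n_particles = 400), seed = 1)
  expect_lt(max(abs(out$par - c(0.3, 0.7))), 1e-3)
  expect_true(all(seen_lo >= c(-0.1, -0.1)) && all(seen_hi <= c(1.1, 1.1)))

  out1 <- swarm_minimize(function(x) abs(x), lower = -1, upper = 1,
                         control = swarm_control(n_particles = 200), seed = 2)
  expect_lt(abs(out1$par), 1e-3)
})

test_that("swarm runs are reproducible from the seed", {
  fn <- function(x) sum(x^2) + 0.1 * sum(sin(20 * x))
  a <- swarm_minimize(fn, c(-1, -1), c(1, 1),
                      control = swarm_control(n_particles = 150,
                                              max_iter = 60), seed = 99)
  b <- swarm_minimize(fn, c(-1, -1), c(1, 1),
                      control = swarm_control(n_particles = 150,
                                              max_iter = 60), seed = 99)
  expect_identical(a$par, b$par)
  expect_identical(a$value, b$value)
})

test_that("fit error scores the post-onset window only", {
  g <- study1_grid()
  pert <- psr_perturbation(g, -100, ramp_ms = 110)
  par <- psr_params(alpha_A = 0.02, alpha_S = 0.01, tau_A = 0.1)
  sim <- psr_simulate("D1", par, pert)
  # data equal to its own simulation
  expect_equal(fit_error("D1", par, sim, pert), 0)
  # constant post-onset offset d gives RMSE |d|
  shifted <- sim$values
  shifted[g$onset:g$n] <- shifted[g$onset:g$n] + 0.004
  expect_equal(fit_error("D1", par, psr_trace(shifted, g), pert), 0.004)
  # baseline-window discrepancies are excluded by rule
  basey <- sim$values
  basey[seq_len(g$onset - 1L)] <- 0.5
  expect_equal(fit_error("D1", par, psr_trace(basey, g), pert), 0)
  # grids must match
  g2 <- psr_grid(0.005, -0.4, 1.4)
  expect_error(
    fit_error("D1", par, psr_trace(numeric(g2$n), g2), pert),
    "grids do not match")
})

test_that("noiseless self-generated data is recovered to high precision", {
  g <- study1_grid()
  pert <- psr_perturbation(g, -100, ramp_ms = 110)
  truth <- c(alpha_A = 0.02, alpha_S = 0.01, tau_A = 0.1)
  target <- psr_simulate("D1", psr_params(alpha_A = 0.02, alpha_S = 0.01,
                                          tau_A = 0.1), pert)
  fit <- psr_fit(target, "D1", pert,
                 control = swarm_control(n_particles = 1000, n_repeats = 3),
                 seed = 5)
  expect_lt(fit$rmse, 1e-6)
  expect_gt(fit$r, 0.999)
  # gains within 1 percent relative error, delay within one grid step
  expect_lt(abs(coef(fit)[["alpha_A"]] / truth[["alpha_A"]] - 1), 0.01)
  expect_lt(abs(coef(fit)[["alpha_S"]] / truth[["alpha_S"]] - 1), 0.01)
  expect_lt(abs(coef(fit)[["tau_A"]] - truth[["tau_A"]]), 0.005 + 1e-9)
  # reported RMSE is the minimum across repeats
  expect_equal(fit$rmse, min(fit$repeats$rmse))
  # all recovered parameters strictly interior to their bounds
  expect_true(all(fit$interior))
})

test_that("fitting is deterministic given the master seed", {
  g <- study1_grid()
  pert <- psr_perturbation(g, -100, ramp_ms = 110)
  target <- psr_simulate("D1", psr_params(alpha_A = 0.015, alpha_S = 0.02,
                                          tau_A = 0.11), pert)
  f1 <- psr_fit(target, "D1", pert, control = quick_control(), seed = 9)
  f2 <- psr_fit(target, "D1", pert, control = quick_control(), seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$repeats$rmse, f2$repeats$rmse)
  expect_identical(f1$repeats$seed, 9 + seq_len(nrow(f1$repeats)))
})

test_that("repeat RMSEs agree tightly when fitting noisy data", {
  g <- study1_grid()
  pert <- psr_perturbation(g, -100, ramp_ms = 110)
  clean <- psr_simulate("D1", psr_params(alpha_A = 0.015, alpha_S = 0.02,
                                         tau_A = 0.11), pert)
  set.seed(31)
  noisy <- psr_trace(clean$values + rnorm(g$n, 0, 0.003), g)
  fit <- psr_fit(noisy, "D1", pert,
                 control = swarm_control(n_particles = 1500, n_repeats = 4),
                 seed = 17)
  expect_lt(diff(range(fit$repeats$rmse)), 0.01 * fit$rmse)
})

test_that("fit summary and accessors are coherent", {
  g <- study1_grid()
  pert <- psr_perturbation(g, -100, ramp_ms = 110)
  clean <- psr_simulate("D1", psr_params(alpha_A = 0.02, alpha_S = 0.01,
                                         tau_A = 0.1), pert)
  set.seed(12)
  noisy <- psr_trace(clean$values + rnorm(g$n, 0, 0.002), g)
  fit <- psr_fit(noisy, "D1", pert, control = quick_control(), seed = 3)
  expect_equal(residuals(fit), noisy$values - fitted(fit)$values)
  expect_identical(predict(fit)$values, fitted(fit)$values)
  s <- summary(fit)
  expect_true(is.finite(s$N) && s$N >= 1)
  expect_true(is.finite(s$caic))
  js <- jsonlite::fromJSON(write_psr_fit(fit))
  expect_equal(js$model, "D1")
  expect_equal(js$rmse, fit$rmse)
  expect_identical(nrow(js$repeats), nrow(fit$repeats))
  # trial simulation from the fit reproduces the model trace at zero noise
  sims <- simulate(fit, nsim = 2, seed = 1, noise_sd = 0)
  expect_equal(sims[1, ], fitted(fit)$values)
})
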