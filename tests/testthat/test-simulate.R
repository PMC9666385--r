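test_that("no perturbation or zero gains yield an identically zero trace", {
  g <- study1_grid()
  p0 <- psr_perturbation(g, 0)
  pert <- psr_perturbation(g, -100, ramp_ms = 110)
  for (m in psr_models()) {
    vals <- psr_params()
    gains <- grep("^alpha_", m$free, value = TRUE)
    vals[gains] <- ifelse(gains == "alpha_I", 5e-4, 0.02)
    vals[grep("^tau_", m$free, value = TRUE)] <- 0.05
    # error-free input: no correction ever
    expect_true(all(psr_simulate(m, vals[m$free], p0)$values == 0),
                info = m$name)
    # zero gains: no correction regardless of the perturbation
    zero <- psr_params()
    expect_true(all(psr_simulate(m, zero[m$free], pert)$values == 0),
                info = m$name)
  }
})

test_that("every simulated trace is exactly zero over the baseline window", {
  g <- study1_grid()
  pert <- psr_perturbation(g, -100, ramp_ms = 110)
  base <- seq_len(g$onset - 1L)
  set.seed(11)
  for (m in psr_models()) {
    vals <- psr_params()
    gains <- grep("^alpha_", m$free, value = TRUE)
    vals[gains] <- ifelse(gains == "alpha_I",
                          runif(1, -1e-3, 1e-3), runif(length(gains), 0, 0.05))
    vals[grep("^tau_", m$free, value = TRUE)] <- sample(0:30, 1) * 0.005
    tr <- psr_simulate(m, vals[m$free], pert)
    expect_true(all(tr$values[base] == 0), info = m$name)
  }
})

test_that("undelayed auditory-only step response follows the geometric recursion", {
  g <- study1_grid()
  pert <- psr_perturbation(g, fraction_to_cents(-0.05))  # exact P = -0.05 step
  tr <- psr_simulate("D1", psr_params(alpha_A = 0.01), pert)
  n_half_sec <- 100L
  expect_equal(tr$values[g$onset + n_half_sec],
               geometric_reference(0.01, -0.05, n_half_sec),
               tolerance = 1e-12)
  expect_equal(geometric_reference(0.01, -0.05, 100), 0.0323690,
               tolerance = 1e-6)
  # whole trajectory, several parameterizations
  for (aA in c(0.005, 0.02, 0.08)) {
    tr <- psr_simulate("D1", psr_params(alpha_A = aA), pert)
    post <- 0:(g$n - g$onset)
    expect_equal(tr$values[g$onset + post],
                 geometric_reference(aA, -0.05, post), tolerance = 1e-12)
  }
})

test_that("long-run deviation converges to the equilibrium oracle", {
  P <- cents_to_fraction(-100)
  # group-mean-scale parameterization held for 30 s
  g_long <- psr_grid(0.005, -0.5, 30)
  tr <- psr_simulate("D1",
                     psr_params(alpha_A = 0.011, alpha_S = 0.013, tau_A = 0.115),
                     psr_perturbation(g_long, -100))
  eq <- equilibrium_reference(0.011, 0.013, P)
  expect_equal(eq, 0.0264035, tolerance = 1e-5)
  expect_equal(tr$values[g_long$n], eq, tolerance = 1e-9)
  # random stable parameterizations: within 0.1% after 20 time constants
  # (delayed feedback is only stable for small loop-gain x delay products)
  set.seed(7)
  for (i in 1:10) {
    aA <- runif(1, 0.005, 0.03)
    aS <- runif(1, 0.001, 0.03)
    tau_steps <- sample(0:20, 1)
    if ((aA + aS) * (tau_steps + 1) > 0.7) tau_steps <- 5L
    n_steps <- ceiling(20 / (aA * (1 + P) + aS)) + tau_steps
    g <- psr_grid(0.005, -0.05, n_steps * 0.005 + 0.005)
    tr <- psr_simulate("D1",
                       psr_params(alpha_A = aA, alpha_S = aS,
                                  tau_A = tau_steps * 0.005),
                       psr_perturbation(g, -100))
    eq <- equilibrium_reference(aA, aS, P)
    expect_equal(tr$values[g$n], eq, tolerance = 1e-3)
  }
})

test_that("basic DIVA, state-space and low-pass forms are equivalent", {
  g <- study1_grid()
  for (pert in list(psr_perturbation(g, -100, ramp_ms = 110),
                    psr_perturbation(g, 100))) {
    set.seed(42)
    for (i in 1:10) {
      aA <- runif(1, 0.001, 0.1)
      aS <- runif(1, 0.001, 0.1)
      d <- sample(0:40, 1)
      d1 <- psr_simulate("D1", psr_params(alpha_A = aA, alpha_S = aS,
                                          tau_A = d * 0.005), pert)$values
      ss <- ss_reference(A = -aS, B = aA, pert$P, g$onset, d)
      expect_lt(max(abs(d1 - ss)), 1e-12)
      # alpha_A = alpha_S: first-order low-pass with time constant dt/alpha
      d1e <- psr_simulate("D1", psr_params(alpha_A = aA, alpha_S = aA,
                                           tau_A = d * 0.005), pert)$values
      lp <- lowpass_reference(aA, pert$P, g$onset, d)
      expect_lt(max(abs(d1e - lp)), 1e-12)
    }
  }
})

test_that("PD and D3 produce bit-identical traces under the gain mapping", {
  g <- study1_grid()
  pert <- psr_perturbation(g, -100, ramp_ms = 110)
  set.seed(5)
  for (i in 1:8) {
    aP <- runif(1, -0.05, 0.1)
    aD <- runif(1, -0.1, 0.9)
    d <- sample(0:40, 1) * 0.005
    pd <- psr_simulate("PD", psr_params(alpha_P = aP, alpha_D = aD,
                                        tau_A = d), pert)
    d3 <- psr_simulate("D3", psr_params(alpha_A = aP, alpha_Av = aD,
                                        tau_A = d), pert)
    expect_identical(pd$values, d3$values)
  }
})

test_that("P equals D1 with the somatosensory gain fixed at zero", {
  g <- psr_grid(0.005, -0.4, 1.4)
  pert <- psr_perturbation(g, 100)
  set.seed(6)
  for (i in 1:8) {
    aP <- runif(1, 0.001, 0.1)
    d <- sample(0:40, 1) * 0.005
    p <- psr_simulate("P", psr_params(alpha_P = aP, tau_A = d), pert)
    d1 <- psr_simulate("D1", psr_params(alpha_A = aP, tau_A = d), pert)
    expect_identical(p$values, d1$values)
  }
})

test_that("simulation enforces the model's free-parameter mask", {
  g <- study1_grid()
  pert <- psr_perturbation(g, -100, ramp_ms = 110)
  expect_error(
    psr_simulate("D1", psr_params(alpha_A = 0.01, alpha_Av = 0.5), pert),
    "not free")
  expect_error(psr_simulate("nope", psr_params(), pert), "unknown model")
  expect_error(
    psr_simulate("D1", psr_params(alpha_A = NA_real_), pert),
    "finite")
  expect_error(
    psr_simulate("D1", psr_params(alpha_A = 0.01, tau_A = 5), pert),
    "grid")
})

test_that("steady-state compensation matches its closed form and limits", {
  # auditory-only drives the heard pitch fully back to target
  expect_equal(steady_state_compensation(0.05, 0, -100), 1)
  expect_equal(steady_state_compensation(0.02, 0, 250), 1)
  expect_equal(steady_state_compensation(0, 0.05, -100), 0)
  expect_equal(steady_state_compensation(0.011, 0.013, -100), 0.451,
               tolerance = 2e-3)
  # small-perturbation limit: alpha_A / (alpha_A + alpha_S)
  expect_lt(abs(steady_state_compensation(0.011, 0.013, -1) -
                0.011 / (0.011 + 0.013)), 1e-4)
  # strictly increasing in alpha_A, decreasing in alpha_S
  aa <- seq(0.002, 0.05, length.out = 9)
  comp_a <- vapply(aa, steady_state_compensation, numeric(1),
                   alpha_S = 0.013, magnitude_cents = -100)
  expect_true(all(diff(comp_a) > 0))
  comp_s <- vapply(aa, function(s)
    steady_state_compensation(0.011, s, -100), numeric(1))
  expect_true(all(diff(comp_s) < 0))
  expect_error(steady_state_compensation(-0.2, 0.01, -100), "equilibrium")
})
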