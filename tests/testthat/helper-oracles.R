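# Independent reference implementations used as oracles. These deliberately
# re-derive results through different routes than the package internals.

# State-space recursion f_C = A (f - f_T) + B (f_T - f_A), written directly.
ss_reference <- function(A, B, P, i0, d_aud) {
  n <- length(P)
  f <- rep(1, n)
  fh <- function(j) if (j < 1) 1 else f[j]
  Ph <- function(j) if (j < 1) 0 else P[j]
  for (i in seq_len(n - 1)) {
    fc <- 0
    if (i >= i0) {
      fA <- fh(i - d_aud) * (1 + Ph(i - d_aud))
      fc <- A * (f[i] - 1) + B * (1 - fA)
    }
    f[i + 1] <- f[i] + fc
  }
  f - 1
}

# First-order low-pass ("leaky integrator") of the delayed auditory error,
# smoothing factor alpha (time constant dt / alpha).
lowpass_reference <- function(alpha, P, i0, d_aud) {
  n <- length(P)
  f <- rep(1, n)
  y <- 0
  fh <- function(j) if (j < 1) 1 else f[j]
  Ph <- function(j) if (j < 1) 0 else P[j]
  for (i in seq_len(n - 1)) {
    if (i >= i0) {
      u <- 1 - fh(i - d_aud) * (1 + Ph(i - d_aud))
      y <- (1 - alpha) * y + alpha * u
      f[i + 1] <- 1 + y
    } else {
      f[i + 1] <- f[i]
    }
  }
  f - 1
}

# Geometric recursion for the undelayed auditory-only controller under a
# step perturbation: f_n = f* + (1 - f*) r^n.
geometric_reference <- function(alpha_A, P, n_steps) {
  f_star <- 1 / (1 + P)
  r <- 1 - alpha_A * (1 + P)
  (f_star - 1) * (1 - r^n_steps)
}

# Equilibrium of the basic DIVA controller under a sustained shift.
equilibrium_reference <- function(alpha_A, alpha_S, P) {
  (alpha_A + alpha_S) / (alpha_A * (1 + P) + alpha_S) - 1
}

# Effective df by explicit Toeplitz trace computation.
effective_df_toeplitz <- function(rho, n) {
  R <- stats::toeplitz(c(1, rho[seq_len(n - 1)]))
  sum(diag(R))^2 / sum(R * R)
}

# Classification tensor with i.i.d. continuous entries (chance conditions).
random_tensor <- function(n_iter, n_subj) {
  array(runif(n_iter * n_subj * n_iter * n_subj),
        c(n_iter, n_subj, n_iter, n_subj))
}

# Small swarm settings for quick unit-test fits.
quick_control <- function(n_particles = 500, n_repeats = 2, max_iter = 200,
                          ...) {
  swarm_control(n_particles = n_particles, n_repeats = n_repeats,
                max_iter = max_iter, ...)
}

study1_grid <- function() psr_grid(0.005, -0.5, 1.5)
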