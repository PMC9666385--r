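---
title: "Modelling the pitch-shift reflex: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the pitch-shift reflex: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a speaker sustains a vowel and the pitch (fundamental frequency, f_o)
they hear through headphones is shifted unexpectedly, they reflexively
change their produced f_o in the direction opposing the shift — the
*pitch-shift reflex*. The response is fast (onset ~100-200 ms), usually
incomplete (a -100-cent shift typically elicits tens of cents of opposing
change), and remarkably individual-specific. `psrfit` implements a family of
discrete-time feedback-control models of this reflex, a particle-swarm
fitting procedure, corrected-AIC model comparison, cross-validated subject
classification, and a synthetic-experiment generator, so the entire analysis
pipeline can be exercised and validated end to end without access to any
particular human dataset.

## The control models

All models share one plant: produced f_o integrates the controller command,

    f[n+1] = f[n] + f_C[n]

in normalized units where the speaker's target is 1 and time advances in
steps of `dt = 0.005` s. Public traces are reported as fractional deviation
`f - 1`. The controller reads two sensory channels:

* auditory: `f_A(t) = f(t - tau_A) * (1 + P(t - tau_A))`, where `P(t)` is
  the fractional perturbation applied to the headphone signal and `tau_A`
  lumps hardware and neural delays;
* somatosensory: `f_S(t) = f(t - tau_S)`, which is *not* perturbed.

Four governing equations define the registry of 19 named configurations
(`psr_models()`):

* **PID** (models P, PI, PD, PID): proportional, integral and derivative
  action on the auditory error `f_T - f_A(t)`.
* **Basic DIVA** (D1, D2): `f_C = alpha_A (f_T - f_A) + alpha_S (f_T - f_S)`.
  With `tau_S = 0` this is algebraically identical to the state-space update
  `f_C = A (f - f_T) + B (f_T - f_A)` with `B = alpha_A`, `A = -alpha_S`,
  and, when `alpha_A = alpha_S`, to a first-order low-pass filter of the
  delayed auditory error with time constant `dt / alpha_S`. The test suite
  verifies both equivalences to below 1e-12.
* **Velocity-generalized DIVA** (D3-D10): adds velocity-error terms
  `-alpha_Av fdot_A(t - tau_Av)` and `-alpha_Sv fdot_S(t - tau_Sv)` (the
  velocity *target* is zero: the task is to hold a constant pitch).
* **Two-timescale DIVA** (D11-D15): adds a second, slower position-error
  response per channel at differential delays `tau_As`, `tau_Ss`, modelling
  the fast automatic and slower voluntary components described in the
  perturbation literature. We read the fast somatosensory term as acting on
  `f_S(t)` (the delayed somatosensory signal) so that configurations with a
  free `tau_S` (D12, D14, D15) are meaningful.

### Numerical conventions

* **Per-step gains.** The update is forward-Euler with the step size folded
  into the gains, which is what makes gain magnitudes of order 0.01 natural:
  a gain of 1 corresponds to full correction of the perceived error within a
  single 5-ms step.
* **Velocity terms are per-step backward differences.** The velocity
  command is `gain * [s(t') - s(t' - dt)]`, the per-step change of the
  delayed sensory signal. Folding `dt` into the velocity gain in the same
  way as the position gains keeps fitted derivative gains of order 0.1-1
  dynamically stable; dividing by `dt` instead would make such values
  violently unstable (closed-loop poles well outside the unit circle), which
  is inconsistent with derivative gains near 0.9 being reported as optimal
  in this literature.
* **The perturbation's own discontinuity is excluded from velocity
  signals**: `fdot_A(t) = (1 + P(t - tau)) * [f(t - tau) - f(t - tau - dt)]/dt`
  differentiates the produced signal only. The step or ramp onset of `P`
  itself is ignored by the velocity channel, which models the observation
  that speakers do not produce the enormous transient such a derivative
  would imply.
* **Delays round to grid steps.** The 5-ms grid is finer than any
  behaviourally meaningful delay precision. A consequence worth knowing:
  the fit objective is piecewise-constant in each delay within a 5-ms bin,
  so a recovered delay is only ever identified up to its bin.
* **Negative differential delays.** `tau_Av`, `tau_Sv` may be negative
  (velocity response faster than position response), but the *total* delay
  of a term is clamped at zero — the controller cannot read future plant
  output.
* **Baseline discipline.** The controller command is held at zero before
  perturbation onset, pre-grid history reads "plant at target, no
  perturbation", the integral term accumulates from onset, and the baseline
  window is excluded from all RMSE computations.
* **Divergence guard.** Unstable parameterizations (reachable during
  optimization) are clamped at |f| = 1e6 and score a correspondingly large
  RMSE rather than propagating non-finite values.

## Fitting: a recombination swarm

`psr_fit()` minimizes post-onset RMSE with a population method
(`swarm_minimize()`): 10,000 random parameter sets are drawn inside the
bounds; each iteration the worst 50% are replaced by random convex
combinations of two rank-weighted draws from the best 10%, plus uniform
jitter. The run stops when every particle's objective is within 1% of the
incumbent best, after 100 consecutive non-improving iterations, or at an
iteration cap. Each fit runs 10 independent repeats (seeds derived as
`seed + repeat`) and keeps the minimum-RMSE solution; Pearson's r between
that solution and the data summarizes fit quality.

Two jitter scales are blended, and both matter:

* a *refinement* scale, 1% of the elite population's per-dimension spread,
  which contracts as the elites agree and lets noiseless self-fits reach
  RMSE below 1e-6;
* an *exploration floor*, 5% of each bound's range cooling geometrically
  with an e-folding time of 30 iterations, which prevents premature
  collapse onto the large plateau of near-zero-response parameterizations
  (where the objective is exactly constant and population agreement would
  otherwise masquerade as convergence — the convergence test is suppressed
  while the floor dominates).

Delay dimensions additionally keep a one-step absolute jitter floor so that
neighbouring delay bins remain reachable after the swarm has contracted;
without it, a swarm that settles one bin away from the optimum can never
cross the flat bin boundary.

Default bounds: all gains in [-0.1, 1.1] (negative gains permit "following"
responses; gains at 1 mean instantaneous full correction), except the
integral gain `alpha_I` in [-0.001, 0.001], whose error-sum accumulates
over hundreds of steps; delays in [0, 500] ms, differential velocity delays
in [-100, 500] ms. Fits flag any parameter that lands on a bound.

## Model comparison

Because trace residuals are strongly autocorrelated, sample counts
overstate the information in a trace. We use the Satterthwaite-Welch idea
applied to the residual sum of squares: with a Toeplitz correlation matrix
`R` built from stationary autocorrelations `rho_k`,

    N = (tr R)^2 / tr(R^2) = n^2 / (n + 2 * sum_k (n - k) rho_k^2),

clipped to [1, n]. The autocorrelations are estimated from *pre-onset*
(baseline) data — identical for all models under comparison — pooled across
trials, and tapered to zero from the first lag whose estimate falls below
`2/sqrt(m)` (m = pooled sample count), so estimation noise at long lags
cannot spuriously collapse N.

The corrected AIC is AIC divided by N, using the Gaussian likelihood
approximation:

    cAIC = 2k/N + ln(MSE) + 1 + ln(2*pi).

Two models differ significantly (20:1 relative likelihood, i.e. p < 0.05)
when their cAIC values differ by more than `2 ln(20) / N`; `psr_compare()`
flags every model within that threshold of the best as a "best model".

For cross-validation, `combined_caic()` forms a single out-of-sample cAIC
per model/subject by setting MSE to the mean per-test-trial MSE and N to
the mean per-trial effective df times the subject's total trial count. We
read "total number of trials" as the subject's full trial count in the
dataset; the alternative readings (test trials per iteration, or summed
test trials) only rescale the `2k/N` penalty and do not change model
orderings in our simulations.

## Cross-validated classification and parameter stability

`psr_crossval()` runs, per subject, 10 iterations each holding out a random
10 trials; the model is fit to the mean of the training trials. The RMSE
tensor `R[i, m, j, n]` compares the mean test trace of iteration i, subject
m against the fitted trace from iteration j, subject n. Classification
picks the subject with minimal RMSE; for each test case and competitor the
fraction (over training iterations) of strict wins is computed, the
*overall* score multiplies the fractions across competitors and the
*pairwise* score averages them, both in percent. Ties count against correct
classification, and pairwise >= overall always (an average of factors
dominates their product). Chance levels are 100/N% (overall) and 50%
(pairwise); with the tensor replaced by i.i.d. draws the implementation
reproduces both to Monte-Carlo precision.

A model-free reference classifier substitutes the training-trial mean for
the fitted trace — on data generated by the fitted model family it performs
on par with the best models, which is a useful sanity bound on what the
model parameterization adds.

Parameter stability across iterations is summarized by the intraclass
correlation `ICC = sigma_between^2 / (sigma_between^2 + sigma_within^2)`
with `sigma_within` the square root of the mean per-subject unbiased
variance (the pooling order is a choice; at 10 iterations per subject the
alternatives differ negligibly). Values below 0.5 are conventionally read
as poor reliability, 0.5-0.75 moderate, 0.75-0.9 good, 0.9-1 excellent.
Note one structural caveat: because delays are identified only up to their
5-ms bin, a delay's within-subject spread never shrinks entirely to zero
even on noiseless data, so its ICC approaches but does not reach 1.

## The synthetic-experiment generator

`study_design()` encodes two sustained-vowel protocols:

* **study1**: 4-s /a/, 80 trials, 20 perturbed by -100 cents with a 110-ms
  linear ramp, onset jittered 1.0-1.5 s, no two perturbed trials
  consecutive, parse window -500..+1500 ms;
* **study2**: 3-s /i/, 60 trials all perturbed by a +/-100-cent step, onset
  jittered 0.5-1.0 s, directions pseudorandomized with at most five
  consecutive trials per direction, parse window -400..+1400 ms.

`synth_subject()` simulates a ground-truth controller against each trial's
perturbation, scales by the subject's baseline f_T (Hz), and corrupts the
trial with multiplicative AR(1) noise (default stationary SD 0.003
deviation units, lag-1 coefficient 0.9 at 5-ms steps) plus a per-trial
constant baseline offset (default SD 0.001). The AR(1) choice makes
baseline residual autocorrelation nontrivial — deliberately exercising the
effective-df machinery — and is configurable. Default ground-truth
parameter ranges (`alpha_A` 0.006-0.011, `alpha_S` 0.013-0.033, `tau_A`
93-115 ms) are centred on group-level estimates typical of this paradigm,
so synthetic cohorts resemble published response shapes: an onset a little
over 100 ms after the shift, a rise over a few hundred ms, and a sustained
partial compensation of roughly 25-50%.

Preprocessing (`preprocess_trials()`) crops each perturbed trial to the
parse window around its own onset, divides by that trial's baseline mean
(so every preprocessed trial has baseline mean exactly zero, and per-trial
baseline drift is removed), flips upshift trials so both directions share
the downshift convention, and averages to subject means. We normalize per
trial rather than per subject: it makes the two study designs commensurable
and is the variant under which baseline-window statistics behave as the
rest of the pipeline assumes. The subject's baseline average in Hz is kept
as `f_T` metadata.

`compensation_percent()` summarizes a response as the mean deviation over
the final 250 ms converted to cents and expressed as a percentage of the
perturbation magnitude, positive when opposing. The closed-form equilibrium
of the basic DIVA controller (`steady_state_compensation()`) gives
`-1200 log2(f*) / cents` with `f* = (alpha_A + alpha_S) / (alpha_A (1 + P) + alpha_S)`;
at the default Study-1-like parameter centre this is ~45%, a useful oracle
for long-trial simulations.

### What the generator does and does not emulate

It reproduces the designs' timing, ramping, jitter and sequencing
constraints, plausible response shapes, trial-level noise with realistic
autocorrelation, and per-trial baseline drift. It does not model vocal-fold
biomechanics, microprosody, formant structure, following-response
subpopulations as a separate mixture (negative gains already produce
following responses), attention- or instruction-dependent late response
components, or f_o extraction error from real audio. Passing tests on
synthetic cohorts therefore validates the *pipeline* — simulation, fitting,
selection, classification — under a known truth; it does not certify the
models against human data.

### A known identifiability limit

Under the default correlated noise law, the smooth noise surviving in a
20-trial mean (SD ~7e-4, correlation time ~50 ms) trades off against the
auditory delay: the global RMSE optimum of a noisy cohort fit can sit one
to several 5-ms bins away from the generating delay even when the optimizer
provably finds that optimum (fits clamped to the true delay bin score
*worse*). With white noise of the same amplitude the delay is recovered to
within one bin. Gain recovery is much more robust (median relative error a
few percent in the correlated case, well under 1% noiseless). Interpret
fitted delays on real (autocorrelated) data with this in mind.

## Problem sizes and runtime choices

Defaults follow the full protocol (10,000 particles, 10 repeats). The test
suite and the bundled `scripts/acceptance.R` use reduced settings chosen to
keep a complete run in minutes on one CPU while preserving every behaviour
being checked: swarms of 300-1,500 particles (recovery checks use 1,000),
3-10 repeats, cohorts of 3-6 subjects with 20-40 trials, 18-subject cohorts
only for design-level summaries, and 5 cross-validation iterations with
5-trial test sets where the full 10x10 scheme is not itself under test.
The reduced-swarm consistency of parameter recovery is itself a tested
property.

## Limitations

* Within-trial (reflexive) control only: no across-trial adaptation or
  feedforward learning dynamics.
* The Gaussian likelihood behind cAIC is an approximation; N corrects for
  autocorrelation but not for non-stationarity of the residuals.
* Delay estimates are bin-limited (5 ms) and, under strongly correlated
  noise, biased as described above.
* The swarm is a global heuristic: repeats make failures to find the
  global basin rare and detectable (via repeat spread), not impossible.
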