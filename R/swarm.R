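#' Swarm optimizer settings
#'
#' The optimizer is a recombination swarm: a large random population is
#' iteratively improved by replacing the worst-scoring fraction of particles
#' with random convex combinations of two particles drawn from the current
#' elite fraction, plus a small uniform jitter. It stops when every particle's
#' objective value lies within `tol` (relative) of the incumbent best, after
#' `patience` consecutive iterations without improvement of the best value,
#' or at `max_iter`.
#'
#' @param n_particles Population size (default 10000).
#' @param tol Relative convergence band around the best objective value
#'   (default 0.01, i.e. all particles within 1 percent; an absolute floor of
#'   1e-12 applies when the best value is near zero).
#' @param patience Consecutive non-improving iterations before stopping
#'   (default 100).
#' @param replace_frac Fraction of particles replaced per iteration
#'   (default 0.5).
#' @param elite_frac Fraction of top particles recombined from (default 0.1).
#' @param jitter Refinement jitter amplitude as a fraction of the elite
#'   population's per-dimension spread (default 0.01), so replacement
#'   particles can refine arbitrarily finely once the elites agree.
#' @param explore Exploration jitter floor as a fraction of each bound's
#'   range (default 0.05), cooling geometrically over iterations so early
#'   replacements search broadly around the elite hull.
#' @param cooling e-folding time, in iterations, of the exploration floor
#'   (default 30).
#' @param max_iter Hard iteration cap (default 500).
#' @param n_repeats Independent optimizer runs per model fit (default 10);
#'   used by [psr_fit()].
#' @return A list of class `swarm_control`.
#' @export
swarm_control <- function(n_particles = 10000, tol = 0.01, patience = 100,
                          replace_frac = 0.5, elite_frac = 0.1,
                          jitter = 0.01, explore = 0.05, cooling = 30,
                          max_iter = 500, n_repeats = 10) {
  stopifnot(n_particles >= 2, tol > 0, tol < 1, patience >= 1,
            replace_frac > 0, replace_frac <= 1,
            elite_frac > 0, elite_frac <= 1,
            jitter >= 0, explore >= 0, cooling > 0, max_iter >= 1,
            n_repeats >= 1)
  structure(list(n_particles = as.integer(n_particles), tol = tol,
                 patience = as.integer(patience),
                 replace_frac = replace_frac, elite_frac = elite_frac,
                 jitter = jitter, explore = explore, cooling = cooling,
                 max_iter = as.integer(max_iter),
                 n_repeats = as.integer(n_repeats)),
            class = "swarm_control")
}

#' Minimize an objective with the recombination swarm
#'
#' @param fn Objective. With `vectorized = FALSE` (default) a function of a
#'   numeric parameter vector returning a scalar; with `vectorized = TRUE` a
#'   function of a matrix (particles in rows) returning one value per row.
#'   Non-finite values are treated as infinitely bad.
#' @param lower,upper Finite bounds per dimension; every particle ever
#'   evaluated lies inside them.
#' @param control A [swarm_control()].
#' @param seed Integer seed; the run is fully reproducible given it.
#' @param vectorized Whether `fn` is batch-evaluating.
#' @param jitter_floor Optional per-dimension absolute jitter floor. Useful
#'   when the objective is piecewise-constant in a dimension (e.g. delays
#'   that are rounded to grid steps): a floor of one step keeps neighbouring
#'   plateaus reachable after the swarm has contracted.
#' @return List with `par` (best parameters), `value` (its objective),
#'   `iterations`, and `converged` (`TRUE` if the population collapsed into
#'   the tolerance band, `FALSE` if stopped by patience or the iteration cap).
#' @examples
#' out <- swarm_minimize(function(x) sum((x - c(0.3, 0.7))^2),
#'                       lower = c(-0.1, -0.1), upper = c(1.1, 1.1),
#'                       control = swarm_control(n_particles = 500), seed = 1)
#' out$par
#' @export
swarm_minimize <- function(fn, lower, upper, control = swarm_control(),
                           seed = 1, vectorized = FALSE,
                           jitter_floor = NULL) {
  stopifnot(length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower <= upper))
  d <- length(lower)
  if (is.null(jitter_floor)) jitter_floor <- numeric(d)
  stopifnot(length(jitter_floor) == d, all(jitter_floor >= 0))
  evalf <- if (vectorized) fn else function(X) apply(X, 1, fn)
  n <- control$n_particles
  rng <- upper - lower

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  X <- matrix(runif(n * d), n, d)
  X <- sweep(sweep(X, 2, rng, "*"), 2, lower, "+")
  v <- as.numeric(evalf(X))
  v[!is.finite(v)] <- Inf
  if (all(is.infinite(v)))
    stop("objective is non-finite for every initial particle")

  n_rep <- max(1L, floor(control$replace_frac * n))
  n_eli <- max(1L, ceiling(control$elite_frac * n))
  best_i <- which.min(v)
  best_v <- v[best_i]
  best_x <- X[best_i, ]
  stall <- 0L
  iter <- 0L
  converged <- FALSE

  while (iter < control$max_iter) {
    iter <- iter + 1L
    ord <- order(v)
    elites <- ord[seq_len(n_eli)]
    worst <- ord[seq.int(n - n_rep + 1L, n)]
    pr <- 1 / seq_len(n_eli) # rank-weighted draw from the elite pool
    i1 <- sample(elites, n_rep, replace = TRUE, prob = pr)
    i2 <- sample(elites, n_rep, replace = TRUE, prob = pr)
    w <- runif(n_rep)
    Xn <- w * X[i1, , drop = FALSE] + (1 - w) * X[i2, , drop = FALSE]
    exploring <- FALSE
    if (control$jitter > 0 || control$explore > 0) {
      E <- X[elites, , drop = FALSE]
      spread <- apply(E, 2, function(z) diff(range(z)))
      floor_amp <- control$explore * rng * exp(-iter / control$cooling)
      refine_amp <- control$jitter * spread
      # objective plateaus can make all particles equal while the swarm is
      # still exploring; do not call that convergence
      exploring <- any(floor_amp > refine_amp)
      amp <- pmax(refine_amp, floor_amp, jitter_floor)
      J <- matrix(runif(n_rep * d, -1, 1), n_rep, d)
      Xn <- Xn + sweep(J, 2, amp, "*")
    }
    Xn <- pmin(pmax(Xn, matrix(lower, n_rep, d, byrow = TRUE)),
               matrix(upper, n_rep, d, byrow = TRUE))
    vn <- as.numeric(evalf(Xn))
    vn[!is.finite(vn)] <- Inf
    X[worst, ] <- Xn
    v[worst] <- vn

    i <- which.min(v)
    if (v[i] < best_v) {
      best_v <- v[i]
      best_x <- X[i, ]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    band <- max(best_v * (1 + control$tol), best_v + 1e-12)
    if (!exploring && all(v <= band)) { converged <- TRUE; break }
    if (stall >= control$patience) break
  }

  list(par = best_x, value = best_v, iterations = iter, converged = converged)
}
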