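#' Random train/test splits of a subject's trials
#'
#' Each iteration holds out a different random subset of `n_test` trials for
#' testing and trains on the remainder.
#'
#' @param trial_ids Vector of trial identifiers (more than `n_test`).
#' @param n_iter Number of cross-validation iterations (default 10).
#' @param n_test Test-set size per iteration (default 10).
#' @param seed Optional integer seed; splits are deterministic given it.
#' @return List of `n_iter` splits, each a list with `test` and `train`
#'   (disjoint, exhaustive subsets of `trial_ids`).
#' @examples
#' s <- make_splits(1:13, n_iter = 3, n_test = 10, seed = 1)
#' lengths(s[[1]])
#' @export
make_splits <- function(trial_ids, n_iter = 10, n_test = 10, seed = NULL) {
  if (length(trial_ids) <= n_test)
    stop("subject needs more than ", n_test, " trials to split")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_iter), function(i) {
    test <- sort(sample(trial_ids, n_test))
    list(test = test, train = setdiff(trial_ids, test))
  })
}

#' Overall and pairwise subject-classification scores
#'
#' Given the cross-validated RMSE tensor `R[i, m, j, n]` - the RMSE between
#' the mean test trace of iteration `i`, subject `m` and the fitted model
#' trace from training iteration `j`, subject `n` - classification chooses
#' the subject with minimal RMSE. For each test case `(i, m)` and each
#' competitor `n != m`, the fraction over `j` of strict inequalities
#' `R[i,m,i,m] < R[i,m,j,n]` is computed; the overall score multiplies these
#' fractions across competitors (probability the correct subject beats all
#' others), the pairwise score averages them (probability of beating one
#' random competitor). Both are averaged over test cases and expressed in
#' percent. Ties count against correct classification.
#'
#' @param tensor 4-d numeric array `[iteration, subject, iteration, subject]`
#'   with no missing entries.
#' @return List with `overall` and `pairwise` scores in percent.
#' @export
classification_scores <- function(tensor) {
  d <- dim(tensor)
  if (length(d) != 4L || d[1] != d[3] || d[2] != d[4])
    stop("tensor must be a 4-d array [iter, subject, iter, subject]")
  if (any(!is.finite(tensor))) stop("tensor has missing entries")
  n_iter <- d[1]; n_subj <- d[2]
  if (n_subj < 2L) stop("need at least 2 subjects")
  overall <- 0
  pairwise <- 0
  for (m in seq_len(n_subj)) {
    for (i in seq_len(n_iter)) {
      self <- tensor[i, m, i, m]
      frac <- colMeans(matrix(tensor[i, m, , ], n_iter, n_subj) > self)
      frac <- frac[-m]
      overall <- overall + prod(frac)
      pairwise <- pairwise + mean(frac)
    }
  }
  list(overall = 100 * overall / (n_iter * n_subj),
       pairwise = 100 * pairwise / (n_iter * n_subj))
}

#' Cross-validated model comparison, classification and parameter stability
#'
#' Runs the full train/test protocol on a preprocessed dataset: for each
#' model, subject and iteration, the model is fit to the mean trace of the
#' training trials; the fitted trace is scored against (a) each held-out test
#' trial, yielding a combined out-of-sample cAIC per subject (averaged across
#' subjects), and (b) the mean test traces of every subject and iteration,
#' yielding the RMSE tensor behind the overall/pairwise classification
#' scores. Parameter stability across iterations is summarized per parameter
#' by ICC. A model-free reference classifier that uses the training-trial
#' mean itself in place of a fitted trace is always included.
#'
#' @param dataset A `psr_dataset` from [preprocess_trials()].
#' @param models Character vector of registry model names (default `"D1"`).
#' @param control A [swarm_control()]; cross-validation typically uses a
#'   reduced swarm for tractability.
#' @param n_iter,n_test Split scheme per subject (default 10 and 10).
#' @param seed Master integer seed.
#' @return An object of class `psr_crossval`: list with `scores` (data.frame:
#'   model, combined cAIC averaged over subjects, overall and pairwise
#'   classification percentages), `reference` (scores of the training-mean
#'   classifier), `icc` (per model, a data.frame of per-parameter mean and
#'   ICC), `params` (per model, array subject x iteration x parameter),
#'   `tensors` (per model), `splits`, and `seed`.
#' @export
psr_crossval <- function(dataset, models = "D1", control = swarm_control(),
                         n_iter = 10, n_test = 10, seed = 1) {
  stopifnot(inherits(dataset, "psr_dataset"))
  grid <- dataset$grid
  design <- dataset$design
  subjects <- dataset$subjects
  n_subj <- length(subjects)
  if (n_subj < 2L) stop("need at least 2 subjects")
  # after direction-flipping all trials share the downshift convention
  pert <- psr_perturbation(grid, -design$magnitude_cents,
                           ramp_ms = design$ramp_ms)
  base_idx <- seq_len(grid$onset - 1L)
  post_n <- grid$n - grid$onset + 1L

  splits <- lapply(seq_len(n_subj), function(s)
    make_splits(subjects[[s]]$trial_ids, n_iter, n_test,
                seed = seed + 131L * s))
  names(splits) <- names(subjects)

  train_mean <- test_mean <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    mat <- subjects[[s]]$trials
    ids <- subjects[[s]]$trial_ids
    train_mean[[s]] <- lapply(splits[[s]], function(sp)
      colMeans(mat[match(sp$train, ids), , drop = FALSE]))
    test_mean[[s]] <- lapply(splits[[s]], function(sp)
      colMeans(mat[match(sp$test, ids), , drop = FALSE]))
  }

  # per-trial effective dfs for the combined cAIC (model-independent);
  # a constant (noise-free) baseline carries no autocorrelation evidence,
  # so the nominal sample count is used there
  trial_df <- lapply(seq_len(n_subj), function(s) {
    mat <- subjects[[s]]$trials
    vapply(seq_len(nrow(mat)), function(j)
      tryCatch(effective_df(mat[j, base_idx], n = post_n),
               error = function(e) as.numeric(post_n)), numeric(1))
  })

  empty_tensor <- function() array(NA_real_, c(n_iter, n_subj, n_iter, n_subj))
  scores <- data.frame(model = models, caic = NA_real_,
                       overall = NA_real_, pairwise = NA_real_,
                       stringsAsFactors = FALSE)
  icc_tabs <- params_out <- tensors <- list()

  for (mi in seq_along(models)) {
    spec <- psr_model(models[mi])
    fits <- array(NA_real_, c(n_subj, n_iter, spec$k),
                  dimnames = list(names(subjects), NULL, spec$free))
    traces <- vector("list", n_subj)
    caic_subj <- numeric(n_subj)
    for (s in seq_len(n_subj)) {
      traces[[s]] <- vector("list", n_iter)
      mses <- dfs <- NULL
      mat <- subjects[[s]]$trials
      ids <- subjects[[s]]$trial_ids
      for (i in seq_len(n_iter)) {
        tr <- psr_trace(train_mean[[s]][[i]], grid)
        fit <- psr_fit(tr, spec, pert, control = control,
                       seed = seed + 100003L * mi + 977L * s + 13L * i)
        fits[s, i, ] <- fit$coef
        traces[[s]][[i]] <- fit$fitted$values
        ti <- match(splits[[s]][[i]]$test, ids)
        mses <- c(mses, vapply(ti, function(j)
          mean((fit$fitted$values[grid$onset:grid$n] -
                mat[j, grid$onset:grid$n])^2), numeric(1)))
        dfs <- c(dfs, trial_df[[s]][ti])
      }
      caic_subj[s] <- combined_caic(mses, dfs, n_trials = length(ids),
                                    k = spec$k)
    }
    tens <- empty_tensor()
    for (m in seq_len(n_subj)) for (i in seq_len(n_iter)) {
      tm <- test_mean[[m]][[i]]
      for (n in seq_len(n_subj)) for (j in seq_len(n_iter))
        tens[i, m, j, n] <- post_onset_rmse(tm, traces[[n]][[j]], grid$onset)
    }
    cls <- classification_scores(tens)
    scores$caic[mi] <- mean(caic_subj)
    scores$overall[mi] <- cls$overall
    scores$pairwise[mi] <- cls$pairwise
    icc_tabs[[models[mi]]] <- data.frame(
      parameter = spec$free,
      mean = vapply(spec$free, function(p) mean(fits[, , p]), numeric(1)),
      icc = vapply(spec$free, function(p) icc(fits[, , p])$icc, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
    params_out[[models[mi]]] <- fits
    tensors[[models[mi]]] <- tens
  }

  # model-free reference: classify against the training-trial mean itself
  ref <- empty_tensor()
  for (m in seq_len(n_subj)) for (i in seq_len(n_iter)) {
    tm <- test_mean[[m]][[i]]
    for (n in seq_len(n_subj)) for (j in seq_len(n_iter))
      ref[i, m, j, n] <- post_onset_rmse(tm, train_mean[[n]][[j]], grid$onset)
  }
  ref_cls <- classification_scores(ref)

  structure(
    list(scores = scores, reference = ref_cls, icc = icc_tabs,
         params = params_out, tensors = tensors, splits = splits,
         n_iter = n_iter, n_test = n_test, seed = seed),
    class = "psr_crossval")
}

#' @export
print.psr_crossval <- function(x, ...) {
  cat(sprintf("Cross-validated classification (%d iterations, %d test trials)\n",
              x$n_iter, x$n_test))
  df <- x$scores
  df$caic <- round(df$caic, 4)
  df$overall <- round(df$overall, 2)
  df$pairwise <- round(df$pairwise, 2)
  print(df, row.names = FALSE)
  cat(sprintf("Training-mean reference classifier: overall %.2f%%, pairwise %.2f%%\n",
              x$reference$overall, x$reference$pairwise))
  invisible(x)
}

#' Write a cross-validation report
#'
#' Writes the per-model score table and per-parameter ICC tables as
#' tab-separated text plus a JSON summary including all seeds.
#'
#' @param report A [psr_crossval()] result.
#' @param path Output stem; `<path>_scores.tsv`, `<path>_icc.tsv` and
#'   `<path>.json` are written.
#' @export
write_psr_crossval <- function(report, path) {
  utils::write.table(report$scores, paste0(path, "_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  icc_all <- do.call(rbind, lapply(names(report$icc), function(m)
    cbind(model = m, report$icc[[m]])))
  utils::write.table(icc_all, paste0(path, "_icc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = report$seed, n_iter = report$n_iter, n_test = report$n_test,
         scores = report$scores, reference = report$reference,
         icc = icc_all),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(path)
}
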