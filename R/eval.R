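#' Cross-validation configuration
#'
#' @param folds number of folds (>= 2; default 5).
#' @param repetitions number of repeated CV passes averaged in the
#'   aggregate (default 5).
#' @param seed integer seed governing fold assignment and model fitting.
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(folds = 5L, repetitions = 5L, seed = 1L) {
  stopifnot(folds >= 2L, repetitions >= 1L)
  structure(list(folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# Stratified fold assignment: each patient is stratified on their rarest
# positive label, which keeps the cohort's long tail of rare diagnoses
# spread across folds; pure random folds would often leave labels with no
# positives in training.
stratified_folds <- function(Y, folds) {
  counts <- colSums(Y)
  strat <- apply(Y, 1L, function(r) {
    pos <- which(r == 1)
    pos[which.min(counts[pos])]
  })
  fold <- integer(nrow(Y))
  for (g in unique(strat)) {
    idx <- which(strat == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition, patients are partitioned into stratified folds;
#' each fold is held out once, a binary-relevance model is fitted on the
#' remainder, and held-out predictions are pooled over the repetition's
#' folds. Hamming loss, balanced accuracy, macro recall and the
#' correct/partial/incorrect categorization are computed on the pooled
#' predictions per repetition and averaged in the aggregate. Runtime is the
#' summed wall-clock of fit + predict over the folds. Fully deterministic
#' for a fixed `cv$seed`.
#'
#' @param X binary feature matrix.
#' @param Y binary label matrix (same rows).
#' @param spec a [model_spec].
#' @param cv a [cv_config].
#' @return an object of class `eval_result` with `$per_repetition` (data
#'   frame) and `$aggregate` (named list).
#' @export
cross_validate <- function(X, Y, spec, cv = cv_config()) {
  stopifnot(inherits(cv, "cv_config"), nrow(X) == nrow(Y))
  if (nrow(X) < cv$folds) stop("need at least as many patients as folds")
  reps <- vector("list", cv$repetitions)
  for (r in seq_len(cv$repetitions)) {
    set.seed(derive_seed(cv$seed, sprintf("folds-%d", r)))
    fold <- stratified_folds(Y, cv$folds)
    if (any(tabulate(fold, cv$folds) == 0L)) {
      stop("a fold received zero test rows; reduce the number of folds")
    }
    Y_pred <- matrix(0L, nrow(Y), ncol(Y), dimnames = dimnames(Y))
    runtime <- 0
    for (k in seq_len(cv$folds)) {
      test <- fold == k
      spec_k <- spec
      spec_k$seed <- derive_seed(cv$seed, sprintf("fit-%d-%d", r, k))
      t0 <- proc.time()[["elapsed"]]
      pred <- suppressMessages(fit_predict_binary_relevance(
        X[!test, , drop = FALSE], Y[!test, , drop = FALSE],
        X[test, , drop = FALSE], spec_k))
      runtime <- runtime + (proc.time()[["elapsed"]] - t0)
      Y_pred[test, ] <- pred
    }
    cat_counts <- categorize_results(Y, Y_pred)
    reps[[r]] <- data.frame(
      repetition = r,
      hamming_loss = hamming_loss(Y, Y_pred),
      balanced_accuracy = balanced_accuracy(Y, Y_pred),
      recall = recall_macro(Y, Y_pred),
      correct = cat_counts[["correct"]],
      partially_correct = cat_counts[["partially_correct"]],
      incorrect = cat_counts[["incorrect"]],
      runtime_seconds = runtime
    )
  }
  per_rep <- do.call(rbind, reps)
  aggregate <- as.list(colMeans(per_rep[, -1L, drop = FALSE]))
  structure(list(per_repetition = per_rep, aggregate = aggregate,
                 spec = spec, cv = cv),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    paste0("<eval_result> %s | hamming %.4f | bal.acc %.4f | recall %.4f | ",
           "correct %.1f | partial %.1f | incorrect %.1f | %.2fs\n"),
    x$spec$kind, a$hamming_loss, a$balanced_accuracy, a$recall,
    a$correct, a$partially_correct, a$incorrect, a$runtime_seconds))
  invisible(x)
}

#' Category-level feature importance
#'
#' Per-column importances (impurity gain for the tree models, absolute
#' standardized coefficient for logistic regression) are averaged over the
#' per-label binary models, summed within report category, and normalized
#' to sum to 1. Following the study protocol this is computed on baseline
#' (unmapped) features.
#'
#' @param fit a `binary_relevance_fit`, fitted on a feature matrix built
#'   with [build_features()].
#' @param col_meta the `col_meta` attribute of that feature matrix (looked
#'   up automatically when `fit` carries one via `attr(pred, "fit")`).
#' @return named numeric vector of class `importance_result`; scores are
#'   nonnegative and sum to 1.
#' @export
feature_importance <- function(fit, col_meta) {
  if (!inherits(fit, "binary_relevance_fit")) {
    stop("feature_importance needs a fitted binary_relevance_fit")
  }
  stopifnot(nrow(col_meta) == length(fit$feature_names))
  imp <- importance_by_feature(fit)
  scores <- tapply(imp, col_meta$category, sum)
  scores <- scores[!is.na(scores)]
  total <- sum(scores)
  if (total <= 0) {
    scores[] <- 1 / length(scores) # no splits anywhere: uniform
  } else {
    scores <- scores / total
  }
  structure(as.numeric(scores), names = names(scores),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat("Category feature-importance scores (sum = 1):\n")
  ord <- order(-unclass(x))
  for (i in ord) cat(sprintf("  %-22s %.4f\n", names(x)[[i]], x[[i]]))
  invisible(x)
}

#' Average wall-clock runtime of a task
#'
#' Runs `task` `executions` times (default 7, the study's runtime
#' protocol) and reports the mean elapsed seconds plus the per-run values.
#'
#' @param task a function of no arguments, runnable repeatedly.
#' @param executions number of executions.
#' @return list with `mean_seconds` and `runs`.
#' @export
runtime_benchmark <- function(task, executions = 7L) {
  stopifnot(is.function(task), executions >= 1L)
  runs <- numeric(executions)
  for (i in seq_len(executions)) {
    t0 <- proc.time()[["elapsed"]]
    tryCatch(task(), error = function(e) {
      stop(sprintf("benchmark task failed on run %d: %s", i,
                   conditionMessage(e)))
    })
    runs[[i]] <- proc.time()[["elapsed"]] - t0
  }
  list(mean_seconds = mean(runs), runs = runs)
}
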