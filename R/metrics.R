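check_shapes <- function(Y_true, Y_pred) {
  if (!all(dim(Y_true) == dim(Y_pred))) {
    stop("label matrices must have matching shapes")
  }
  invisible()
}

#' Hamming loss
#'
#' Fraction of label cells (patients x labels) where prediction and ground
#' truth disagree: `(1 / (N * L)) * sum_i |Y_true_i XOR Y_pred_i|`.
#'
#' @param Y_true,Y_pred binary label matrices of identical shape.
#' @return a number in `[0, 1]`.
#' @export
hamming_loss <- function(Y_true, Y_pred) {
  check_shapes(Y_true, Y_pred)
  mean(Y_true != Y_pred)
}

#' Macro-averaged balanced accuracy
#'
#' Per label, `(TPR + TNR) / 2`; labels with zero positives or zero
#' negatives in the truth are skipped; the mean over retained labels is
#' returned.
#'
#' @inheritParams hamming_loss
#' @return a number in `[0, 1]`.
#' @export
balanced_accuracy <- function(Y_true, Y_pred) {
  check_shapes(Y_true, Y_pred)
  vals <- vapply(seq_len(ncol(Y_true)), function(l) {
    t <- Y_true[, l]
    p <- Y_pred[, l]
    pos <- sum(t == 1)
    neg <- sum(t == 0)
    if (pos == 0 || neg == 0) return(NA_real_)
    tpr <- sum(t == 1 & p == 1) / pos
    tnr <- sum(t == 0 & p == 0) / neg
    (tpr + tnr) / 2
  }, numeric(1))
  if (all(is.na(vals))) stop("undefined balanced accuracy: all labels skipped")
  mean(vals, na.rm = TRUE)
}

#' Macro-averaged recall
#'
#' Per label `TP / (TP + FN)`, averaged over labels with at least one
#' positive in the truth.
#'
#' @inheritParams hamming_loss
#' @return a number in `[0, 1]`.
#' @export
recall_macro <- function(Y_true, Y_pred) {
  check_shapes(Y_true, Y_pred)
  vals <- vapply(seq_len(ncol(Y_true)), function(l) {
    pos <- sum(Y_true[, l] == 1)
    if (pos == 0) return(NA_real_)
    sum(Y_true[, l] == 1 & Y_pred[, l] == 1) / pos
  }, numeric(1))
  if (all(is.na(vals))) stop("undefined recall: no label has positives")
  mean(vals, na.rm = TRUE)
}

#' Correct / partially correct / incorrect categorization
#'
#' A patient's result is correct when the predicted diagnosis set equals
#' the ground-truth set, partially correct when the sets overlap without
#' being equal (possibly alongside incorrect labels), and incorrect when
#' they are disjoint. The three counts always partition the patients.
#'
#' @param Y_true,Y_pred binary label matrices (or lists of label-id sets)
#'   aligned by patient.
#' @return named integer vector with `correct`, `partially_correct`,
#'   `incorrect`.
#' @export
categorize_results <- function(Y_true, Y_pred) {
  if (is.matrix(Y_true) || is.data.frame(Y_true)) {
    check_shapes(Y_true, Y_pred)
    true_sets <- apply(Y_true, 1L, function(r) which(r == 1), simplify = FALSE)
    pred_sets <- apply(Y_pred, 1L, function(r) which(r == 1), simplify = FALSE)
  } else {
    if (length(Y_true) != length(Y_pred)) {
      stop("true and predicted set lists differ in length")
    }
    true_sets <- Y_true
    pred_sets <- Y_pred
  }
  correct <- partial <- incorrect <- 0L
  for (i in seq_along(true_sets)) {
    ts <- true_sets[[i]]
    ps <- pred_sets[[i]]
    if (setequal(ts, ps)) {
      correct <- correct + 1L
    } else if (length(intersect(ts, ps)) > 0L) {
      partial <- partial + 1L
    } else {
      incorrect <- incorrect + 1L
    }
  }
  c(correct = correct, partially_correct = partial, incorrect = incorrect)
}

#' Relative improvement between two counts
#'
#' `100 * (c_mapped - c_base) / c_base`, rounded to one decimal — the form
#' in which correct-result improvements and runtime reductions are
#' reported.
#'
#' @param c_base baseline count (must be positive).
#' @param c_mapped count under ontology mapping.
#' @return percentage, one decimal.
#' @export
relative_improvement <- function(c_base, c_mapped) {
  if (c_base <= 0) stop("baseline count must be positive")
  round(100 * (c_mapped - c_base) / c_base, 1)
}
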