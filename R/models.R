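#' Specification of one of the three study learners
#'
#' @param kind `"logistic_regression"` (ridge-penalized, C = 1),
#'   `"random_forest"` (100 bagged trees, `mtry = floor(sqrt(p))`), or
#'   `"gradient_tree_boosting"` (100 trees, learning rate 0.1, depth 3).
#' @param hyperparameters named list overriding the defaults above
#'   (`ntree`, `mtry`, `max_depth`, `min_node`, `shrinkage`, `lambda`).
#' @param seed integer seed applied at fit time, or `NULL` to use the
#'   caller's RNG stream.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(kind = c("logistic_regression", "random_forest",
                                "gradient_tree_boosting"),
                       hyperparameters = list(), seed = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    logistic_regression = list(C = 1),
    random_forest = list(ntree = 100L, mtry = NA_integer_, max_depth = 12L,
                         min_node = 1L),
    gradient_tree_boosting = list(ntree = 100L, shrinkage = 0.1,
                                  max_depth = 3L, min_node = 5L)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp, seed = seed),
            class = "model_spec")
}

#' The three learners of the study protocol
#'
#' @param seed optional common seed recorded in each spec.
#' @return named list of [model_spec] objects.
#' @export
default_model_specs <- function(seed = NULL) {
  list(logistic_regression = model_spec("logistic_regression", seed = seed),
       random_forest = model_spec("random_forest", seed = seed),
       gradient_tree_boosting = model_spec("gradient_tree_boosting",
                                           seed = seed))
}

as_indicator_matrix <- function(X) {
  m <- as.matrix(X)
  storage.mode(m) <- "integer"
  m
}

fit_single_binary <- function(X, y, spec) {
  hp <- spec$hyperparameters
  if (length(unique(y)) == 1L) {
    return(list(type = "constant", value = y[[1L]],
                importance = numeric(ncol(X))))
  }
  switch(spec$kind,
    logistic_regression = {
      if (min(tabulate(y + 1L, 2L)) < 2L) {
        # glmnet needs two observations per class; labels this rare get the
        # prior as a constant predictor
        return(list(type = "constant", value = mean(y),
                    importance = numeric(ncol(X))))
      }
      # ridge logistic regression; lambda = 1 / (n * C) mirrors an L2
      # penalty of strength C on the likelihood scale
      lambda <- hp$lambda %||% (1 / (nrow(X) * (hp$C %||% 1)))
      Xf <- X
      if (ncol(Xf) < 2L) Xf <- cbind(Xf, `.pad` = 0L) # glmnet needs >= 2 cols
      # short warm-start path down to the target lambda (much faster than a
      # cold single-lambda fit, numerically equivalent at the end point)
      lseq <- exp(seq(log(100 * lambda), log(lambda), length.out = 8L))
      fit <- withCallingHandlers(
        glmnet::glmnet(Xf, factor(y, levels = c(0, 1)),
                       family = "binomial", alpha = 0,
                       lambda = lseq, standardize = FALSE),
        # expected for the cohort's rare-label long tail
        warning = function(w) {
          if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      beta <- as.numeric(coef(fit, s = lambda))[-1L][seq_len(ncol(X))]
      sds <- apply(X, 2L, sd)
      list(type = "glmnet", fit = fit, lambda = lambda,
           padded = ncol(X) < 2L, importance = abs(beta) * sds)
    },
    random_forest = {
      mtry <- hp$mtry
      if (is.na(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
      fit <- cpp_forest_fit(X, as.numeric(y), as.integer(hp$ntree),
                            as.integer(mtry), as.integer(hp$max_depth),
                            as.integer(hp$min_node))
      list(type = "forest", fit = fit, importance = fit$importance)
    },
    gradient_tree_boosting = {
      fit <- cpp_gbm_fit(X, as.numeric(y), as.integer(hp$ntree),
                         hp$shrinkage, as.integer(hp$max_depth),
                         as.integer(hp$min_node))
      list(type = "gbm", fit = fit, importance = fit$importance)
    }
  )
}

predict_single_binary <- function(model, X) {
  switch(model$type,
    constant = rep(as.numeric(model$value), nrow(X)),
    glmnet = {
      Xf <- X
      if (isTRUE(model$padded)) Xf <- cbind(Xf, `.pad` = 0L)
      as.numeric(predict(model$fit, Xf, type = "response", s = model$lambda))
    },
    forest = cpp_forest_predict(model$fit, X),
    gbm = cpp_gbm_predict(model$fit, X)
  )
}

#' Fit one independent binary classifier per label (binary relevance)
#'
#' @param X_train binary feature matrix (patients x features).
#' @param Y_train binary label matrix (patients x labels).
#' @param spec a [model_spec].
#' @return an object of class `binary_relevance_fit` holding one model per
#'   label; labels that are all-positive or all-negative in training get a
#'   constant predictor (recorded in `$constant_labels`).
#' @export
fit_binary_relevance <- function(X_train, Y_train, spec) {
  stopifnot(inherits(spec, "model_spec"),
            nrow(X_train) == nrow(Y_train))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  X <- as_indicator_matrix(X_train)
  models <- vector("list", ncol(Y_train))
  names(models) <- colnames(Y_train)
  for (l in seq_len(ncol(Y_train))) {
    models[[l]] <- fit_single_binary(X, Y_train[, l], spec)
  }
  constant <- names(models)[vapply(models, function(m) m$type == "constant",
                                   TRUE)]
  structure(list(models = models, spec = spec,
                 feature_names = colnames(X_train),
                 constant_labels = constant),
            class = "binary_relevance_fit")
}

#' Predict label sets from a binary-relevance fit
#'
#' @param fit a `binary_relevance_fit`.
#' @param X_test feature matrix with the training columns.
#' @param threshold posterior probability above which a label is predicted.
#' @return binary matrix (patients x labels).
#' @export
predict_binary_relevance <- function(fit, X_test, threshold = 0.5) {
  stopifnot(inherits(fit, "binary_relevance_fit"))
  if (!identical(colnames(X_test), fit$feature_names)) {
    stop("test features must match training features")
  }
  X <- as_indicator_matrix(X_test)
  Y <- matrix(0L, nrow = nrow(X), ncol = length(fit$models),
              dimnames = list(rownames(X_test), names(fit$models)))
  for (l in seq_along(fit$models)) {
    Y[, l] <- as.integer(predict_single_binary(fit$models[[l]], X) > threshold)
  }
  Y
}

#' Fit and predict in one step
#'
#' Binary-relevance multilabel classification: one independent binary
#' classifier per label; a patient's predicted set is the set of labels
#' whose binary model outputs a posterior above 0.5. Deterministic given
#' the spec seed.
#'
#' @inheritParams fit_binary_relevance
#' @param X_test feature matrix sharing columns with `X_train`.
#' @return binary prediction matrix with the fitted model in attribute
#'   `"fit"`.
#' @export
fit_predict_binary_relevance <- function(X_train, Y_train, X_test, spec) {
  fit <- fit_binary_relevance(X_train, Y_train, spec)
  if (length(fit$constant_labels)) {
    message(sprintf("constant-model labels (single training class): %s",
                    paste(fit$constant_labels, collapse = ", ")))
  }
  pred <- predict_binary_relevance(fit, X_test)
  attr(pred, "fit") <- fit
  pred
}

# Mean per-feature importance across the per-label binary models.
importance_by_feature <- function(fit) {
  stopifnot(inherits(fit, "binary_relevance_fit"))
  imp <- vapply(fit$models, function(m) m$importance,
                numeric(length(fit$feature_names)))
  if (is.null(dim(imp))) imp <- matrix(imp, nrow = 1L)
  out <- rowMeans(imp)
  names(out) <- fit$feature_names
  out
}
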