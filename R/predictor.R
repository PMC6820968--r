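# Protein-abundance predictors: the naive two-input linear baseline, OLS on
# the full design, and gradient-boosted regression trees (1000 base trees,
# learning rate 0.01, depth 3 by default — compiled level-wise exact-greedy
# implementation in src/gbrt.cpp). Out-of-sample evaluation is leave-one-out
# by default, with a grouped k-fold `fast` approximation for tractability
# with tree ensembles.

#' Model specification
#'
#' @param kind one of "gbrt", "ols", "naive_linear"
#' @param n_trees number of boosting iterations (T >= 1)
#' @param learning_rate shrinkage eta in (0, 1]
#' @param max_depth per-tree depth
#' @param min_leaf minimum samples per leaf
#' @param seed stored for provenance; boosting is deterministic (no
#'   stochastic subsampling), so it does not affect the fit
#' @return list of class `model_spec`
#' @export
model_spec <- function(kind = c("gbrt", "ols", "naive_linear"),
                       n_trees = 1000L, learning_rate = 0.01,
                       max_depth = 3L, min_leaf = 1L, seed = 1L) {
  kind <- match.arg(kind)
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  if (learning_rate <= 0 || learning_rate > 1) {
    stop("learning_rate must be in (0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit gradient-boosted regression trees
#'
#' Deterministic squared-loss boosting; feature importances are per-feature
#' sums of split squared-error reductions, normalised to sum to 1.
#'
#' @param X numeric design matrix of the selected features (no missing
#'   values; a bias column is dropped — trees do not need it)
#' @param y numeric target
#' @param spec a [model_spec()] of kind "gbrt"
#' @return object of class `gbrt_model` with `importances`
#' @export
fit_gbrt <- function(X, y, spec = model_spec("gbrt")) {
  X <- .drop_bias(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y", call. = FALSE)
  fit <- .gbrt_fit_cpp(X, y, spec$n_trees, spec$learning_rate,
                       spec$max_depth, spec$min_leaf)
  gain <- fit$gain
  imp <- if (sum(gain) > 0) gain / sum(gain) else rep(1 / ncol(X), ncol(X))
  structure(list(fit = fit, features = colnames(X),
                 importances = stats::setNames(imp, colnames(X)),
                 spec = spec),
            class = "gbrt_model")
}

#' @export
predict.gbrt_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  as.numeric(.gbrt_predict_cpp(object$fit, X))
}

#' @export
print.gbrt_model <- function(x, ...) {
  cat(sprintf("<gbrt_model> %d trees, depth %d, eta %.3g, %d features\n",
              x$spec$n_trees, x$spec$max_depth, x$spec$learning_rate,
              length(x$features)))
  invisible(x)
}

# --- model builders for compare_models_cv ---------------------------------

#' OLS model builder
#' @return list with `fit`/`predict` for [compare_models_cv()]
#' @export
model_ols <- function() {
  list(
    fit = function(X, y) {
      X <- .drop_bias(X)
      stats::lm.fit(cbind(`(b)` = 1, X), y)
    },
    predict = function(obj, X) {
      X <- .drop_bias(X)
      co <- obj$coefficients
      co[is.na(co)] <- 0
      as.numeric(cbind(1, X[, names(co)[-1L], drop = FALSE]) %*% co)
    }
  )
}

#' Naive two-input model builder (mRNA + translation only)
#' @param cols names of the two expression columns in the design
#' @return list with `fit`/`predict` for [compare_models_cv()]
#' @export
model_naive <- function(cols = c("mrna", "translation")) {
  base <- model_ols()
  list(
    fit = function(X, y) base$fit(X[, cols, drop = FALSE], y),
    predict = function(obj, X) base$predict(obj, X[, cols, drop = FALSE])
  )
}

#' GBRT model builder
#' @param spec a [model_spec()]
#' @return list with `fit`/`predict` for [compare_models_cv()]
#' @export
model_gbrt <- function(spec = model_spec("gbrt")) {
  list(
    fit = function(X, y) fit_gbrt(X, y, spec),
    predict = function(obj, X) stats::predict(obj, X)
  )
}

.prediction_result <- function(gene_ids, y, yhat, scheme,
                               importances = NULL) {
  r_p <- if (stats::sd(y) == 0 || stats::sd(yhat) == 0) NA_real_ else
    stats::cor(y, yhat)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  structure(list(gene_ids = gene_ids, y = y, yhat = yhat, scheme = scheme,
                 importances = importances, r_p = r_p, r2 = r2),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s, n = %d, r_p = %.3f, R^2 = %.3f\n",
              x$scheme, length(x$y), x$r_p, x$r2))
  invisible(x)
}

#' Naive two-input protein predictor
#'
#' Least-squares fit of protein on \[1, mRNA, translation\], evaluated
#' out-of-sample under the shared k-fold harness.
#'
#' @param mrna,translation,y equal-length complete numeric vectors
#' @param folds CV folds
#' @param seed fold seed
#' @return `prediction_result` with held-out predictions and the mean
#'   per-fold out-of-sample R^2 in `cv_r2`
#' @export
fit_naive <- function(mrna, translation, y, folds = 10L, seed = 1L) {
  n <- length(y)
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  stopifnot(length(mrna) == n, length(translation) == n)
  X <- cbind(mrna = mrna, translation = translation)
  fold <- make_folds(n, folds, seed)
  yhat <- numeric(n)
  fold_r2 <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    co <- stats::lm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr])$coefficients
    pred <- as.numeric(cbind(1, X[!tr, , drop = FALSE]) %*% co)
    yhat[!tr] <- pred
    yte <- y[!tr]
    fold_r2[f] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
  }
  out <- .prediction_result(names(y), y, yhat, sprintf("%d-fold", folds))
  out$cv_r2 <- mean(fold_r2)
  out$cv_r2_sd <- stats::sd(fold_r2)
  out
}

#' Out-of-sample prediction by leave-one-out (or grouped) CV
#'
#' With `fast = FALSE`, the model is refit n times, each gene predicted by
#' the model trained on all others (deterministic). `fast = TRUE` switches
#' to grouped k-fold CV (default 20 folds) and labels the scheme
#' accordingly — an approximation that keeps 1000-tree ensembles tractable.
#'
#' @param X selected-feature design matrix
#' @param y numeric target
#' @param spec a [model_spec()]
#' @param fast use grouped k-fold instead of true LOOCV
#' @param folds fold count in fast mode
#' @param seed fold seed (fast mode only)
#' @return `prediction_result`; `importances` come from a full-data fit
#'   when the model is a tree ensemble
#' @export
loocv_predict <- function(X, y, spec = model_spec("gbrt"), fast = FALSE,
                          folds = 20L, seed = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 10L) stop("need n >= 10", call. = FALSE)
  builder <- switch(spec$kind,
                    gbrt = model_gbrt(spec),
                    ols = model_ols(),
                    naive_linear = model_naive())
  fold <- if (fast) make_folds(n, folds, seed) else seq_len(n)
  k <- length(unique(fold))
  yhat <- numeric(n)
  for (f in unique(fold)) {
    tr <- fold != f
    obj <- builder$fit(X[tr, , drop = FALSE], y[tr])
    yhat[!tr] <- builder$predict(obj, X[!tr, , drop = FALSE])
  }
  imp <- if (spec$kind == "gbrt") fit_gbrt(X, y, spec)$importances else NULL
  scheme <- if (fast) sprintf("grouped-%d-fold", k) else "loocv"
  .prediction_result(rownames(X), y, yhat, scheme, importances = imp)
}

#' Pool per-phase predictions for a headline correlation
#'
#' Concatenates the (y, yhat) pairs of several `prediction_result`s (one per
#' phase) and reports the pooled Pearson correlation and R^2.
#'
#' @param results list of `prediction_result`
#' @return list: `r_p`, `r2`, `n`
#' @export
pool_predictions <- function(results) {
  y <- unlist(lapply(results, `[[`, "y"))
  yhat <- unlist(lapply(results, `[[`, "yhat"))
  list(r_p = stats::cor(y, yhat),
       r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       n = length(y))
}
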