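# Feature selection and the model-comparison harness: the L1 regularisation
# path with 10-fold CV tuning of alpha, recursive feature elimination,
# univariate k-best (ANOVA/regression F), and k-fold model comparison with a
# shared fold partition.
#
# The L1 objective is min { (1/2n) ||Xw - y||^2 + alpha ||w||_1 } (glmnet's
# lambda plays the role of alpha), so the default grid alpha in [1e-3, 1]
# induces the familiar sharp sparsity increase near alpha ~ 0.1 on
# standardised features. Features are z-scored inside each CV fold (fit on
# train, applied to test) to avoid leakage; the bias column is exempt and is
# never reported as selected.

.drop_bias <- function(X) {
  X <- as.matrix(X)
  X[, setdiff(colnames(X), "bias"), drop = FALSE]
}

.zscore_fit <- function(X) {
  list(mean = colMeans(X), sd = apply(X, 2L, stats::sd))
}

.zscore_apply <- function(X, zs) {
  sd <- ifelse(zs$sd > 0, zs$sd, 1)
  sweep(sweep(X, 2L, zs$mean, "-"), 2L, sd, "/")
}

#' Deterministic k-fold partition
#'
#' @param n number of samples
#' @param k number of folds
#' @param seed RNG seed for the shuffle
#' @return integer fold label per sample (1..k)
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k < 2L || k > n) stop("need 2 <= k <= n folds", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# save/restore the global RNG state so package internals never perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default log-spaced alpha grid
#' @param lo,hi grid limits
#' @param n number of points
#' @export
alpha_grid <- function(lo = 1e-3, hi = 1, n = 50L) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Tune the L1 regularisation strength by k-fold CV
#'
#' For every alpha on the grid, computes the cross-validated mean squared
#' error (mean +/- sd over folds) and the number of surviving (nonzero)
#' coefficients from a full-data fit. `alpha_star` is chosen by the 1-SE
#' rule (largest alpha whose mean MSE is within one standard error of the
#' minimum) or as the MSE minimiser.
#'
#' @param X design matrix (bias column tolerated and ignored)
#' @param y numeric target
#' @param grid ascending alpha grid, default [alpha_grid()]
#' @param folds number of CV folds
#' @param seed fold-assignment seed
#' @param rule "1se" (default) or "min"
#' @return list of class `lasso_path`: `alphas`, `mse_mean`, `mse_sd`,
#'   `p_remaining`, `alpha_star`
#' @export
tune_lasso_alpha <- function(X, y, grid = alpha_grid(), folds = 10L,
                             seed = 1L, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  if (length(grid) == 0L) stop("empty alpha grid", call. = FALSE)
  grid <- sort(grid)
  Xf <- .drop_bias(X)
  n <- nrow(Xf)
  fold <- make_folds(n, folds, seed)
  lam_desc <- rev(grid)
  mse <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    zs <- .zscore_fit(Xf[tr, , drop = FALSE])
    Xtr <- .zscore_apply(Xf[tr, , drop = FALSE], zs)
    Xte <- .zscore_apply(Xf[!tr, , drop = FALSE], zs)
    fit <- glmnet::glmnet(Xtr, y[tr], alpha = 1, lambda = lam_desc,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-9)
    pred <- stats::predict(fit, newx = Xte, s = lam_desc, exact = FALSE)
    mse[f, ] <- rev(colMeans((pred - y[!tr])^2))
  }
  mse_mean <- colMeans(mse)
  mse_sd <- apply(mse, 2L, stats::sd)
  zs_all <- .zscore_fit(Xf)
  fit_all <- glmnet::glmnet(.zscore_apply(Xf, zs_all), y, alpha = 1,
                            lambda = lam_desc, standardize = FALSE,
                            intercept = TRUE, thresh = 1e-9)
  nz <- rev(fit_all$df)
  i_min <- which.min(mse_mean)
  alpha_star <- if (rule == "min") {
    grid[i_min]
  } else {
    se <- mse_sd[i_min] / sqrt(folds)
    max(grid[mse_mean <= mse_mean[i_min] + se])
  }
  structure(list(alphas = grid, mse_mean = mse_mean, mse_sd = mse_sd,
                 p_remaining = as.integer(nz), alpha_star = alpha_star,
                 folds = folds, rule = rule),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf(
    "<lasso_path> %d alphas in [%.2g, %.2g], alpha* = %.4g (%s rule), %d features remain\n",
    length(x$alphas), min(x$alphas), max(x$alphas), x$alpha_star, x$rule,
    x$p_remaining[which.min(abs(x$alphas - x$alpha_star))]))
  invisible(x)
}

.selection_result <- function(selector, selected, scores, phase = NA) {
  structure(list(selector = selector, phase = phase,
                 selected = selected, scores = scores),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d features: %s\n", x$selector,
              length(x$selected), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' L1 (lasso) feature selection at a fixed alpha
#'
#' @inheritParams tune_lasso_alpha
#' @param alpha_star regularisation strength, typically from
#'   [tune_lasso_alpha()]
#' @return `selection_result` with the nonzero-coefficient features and
#'   their absolute standardised coefficients as scores
#' @export
lasso_select <- function(X, y, alpha_star) {
  Xf <- .drop_bias(X)
  zs <- .zscore_fit(Xf)
  fit <- glmnet::glmnet(.zscore_apply(Xf, zs), y, alpha = 1,
                        lambda = alpha_star, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-9)
  co <- as.numeric(stats::coef(fit))[-1L]
  names(co) <- colnames(Xf)
  .selection_result("lasso", colnames(Xf)[co != 0], abs(co))
}

#' Recursive feature elimination with an OLS base model
#'
#' Standardised least-squares fit; the feature with the smallest absolute
#' coefficient is dropped, and the model refit, until `k` features remain.
#'
#' @inheritParams tune_lasso_alpha
#' @param k number of features to keep (0 < k < p)
#' @return `selection_result`; scores are elimination ranks (1 = dropped
#'   first, p = most persistent)
#' @export
rfe_select <- function(X, y, k) {
  Xf <- .drop_bias(X)
  p <- ncol(Xf)
  if (k <= 0L || k >= p) stop("need 0 < k < p", call. = FALSE)
  Xz <- .zscore_apply(Xf, .zscore_fit(Xf))
  remaining <- colnames(Xf)
  rank <- stats::setNames(integer(p), colnames(Xf))
  step <- 0L
  while (length(remaining) > k) {
    co <- stats::coef(stats::lm.fit(cbind(1, Xz[, remaining, drop = FALSE]),
                                    y))[-1L]
    co[is.na(co)] <- 0   # aliased (perfectly collinear) features drop first
    weakest <- remaining[order(abs(co), remaining)[1L]]
    step <- step + 1L
    rank[weakest] <- step
    remaining <- setdiff(remaining, weakest)
  }
  co <- stats::coef(stats::lm.fit(cbind(1, Xz[, remaining, drop = FALSE]),
                                  y))[-1L]
  co[is.na(co)] <- 0
  rank[remaining[order(abs(co), remaining)]] <- seq.int(step + 1L, p)
  .selection_result("rfe", remaining, rank)
}

#' Univariate k-best selection (ANOVA / regression F)
#'
#' Scores each feature by the univariate regression F statistic against the
#' target, F = (n - 2) r^2 / (1 - r^2) — equivalent to one-way ANOVA with a
#' single regressor. Optionally the target is discretised into tertiles and
#' a one-way ANOVA F across the three groups is used instead.
#'
#' @inheritParams rfe_select
#' @param discretize use tertile-ANOVA scoring instead of regression F
#' @return `selection_result`; scores are F statistics
#' @export
kbest_select <- function(X, y, k, discretize = FALSE) {
  Xf <- .drop_bias(X)
  p <- ncol(Xf)
  if (k <= 0L || k >= p) stop("need 0 < k < p", call. = FALSE)
  n <- nrow(Xf)
  fstat <- if (!discretize) {
    r <- as.numeric(stats::cor(Xf, y))
    r[is.na(r)] <- 0
    (n - 2) * r^2 / pmax(1 - r^2, .Machine$double.eps)
  } else {
    g <- cut(y, stats::quantile(y, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = FALSE)
    apply(Xf, 2L, function(x) {
      summary(stats::aov(x ~ factor(g)))[[1L]]$`F value`[1L]
    })
  }
  names(fstat) <- colnames(Xf)
  ord <- order(-fstat, colnames(Xf))
  .selection_result("kbest", colnames(Xf)[ord[seq_len(k)]], fstat)
}

#' Compare regression models under a shared k-fold partition
#'
#' Every model sees the identical fold split; reported is the per-fold
#' out-of-sample R^2 (1 - SS_res/SS_tot on the held-out fold) with its mean
#' and sd.
#'
#' @inheritParams tune_lasso_alpha
#' @param models named list of model builders, each a list with `fit(X, y)`
#'   and `predict(obj, X)` — see [model_ols()], [model_naive()],
#'   [model_gbrt()]
#' @return data.frame of class `model_scores` (model, mean_r2, sd_r2, n, p)
#'   with attribute `fold_r2` (folds x models matrix)
#' @export
compare_models_cv <- function(X, y, models, folds = 10L, seed = 1L) {
  if (length(models) < 2L) stop("need >= 2 models", call. = FALSE)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    stop("models must be named", call. = FALSE)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  fold <- make_folds(n, folds, seed)
  if (min(table(fold)) < 2L) stop("fold with < 2 samples", call. = FALSE)
  r2 <- matrix(NA_real_, folds, length(models),
               dimnames = list(NULL, names(models)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (m in names(models)) {
      obj <- models[[m]]$fit(X[tr, , drop = FALSE], y[tr])
      pred <- models[[m]]$predict(obj, X[!tr, , drop = FALSE])
      yte <- y[!tr]
      r2[f, m] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
    }
  }
  out <- data.frame(model = names(models),
                    mean_r2 = colMeans(r2),
                    sd_r2 = apply(r2, 2L, stats::sd),
                    n = n, p = ncol(.drop_bias(X)),
                    row.names = NULL)
  attr(out, "fold_r2") <- r2
  class(out) <- c("model_scores", "data.frame")
  out
}
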