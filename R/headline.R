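# One-call reproduction of the headline statistics on a combined dataset:
# per-phase expression correlations, univariate and naive-baseline R^2,
# 10-fold model comparison (GBRT / OLS / naive), pooled out-of-sample
# Pearson correlation and the per-phase over:under outlier ratios.

#' Reproduce the headline statistics of a combined dataset
#'
#' Runs the full analysis on a combined multi-omics table (gene id, nine
#' expression columns, feature columns): Spearman mRNA-protein and
#' translation-protein correlations per phase, univariate R^2 of protein on
#' mRNA and on translation, 10-fold CV R^2 for the naive two-input linear
#' model, OLS and GBRT on the L1-selected features, pooled out-of-sample
#' Pearson r_p across phases, and the 90th-percentile over:under outlier
#' ratio per phase.
#'
#' @param path combined dataset file (see [load_combined_dataset()])
#' @param fast use grouped 20-fold CV instead of true LOOCV for the pooled
#'   r_p (full LOOCV with 1000-tree ensembles is hours-scale)
#' @param seed seed for fold assignment
#' @param folds folds for the model comparison
#' @return list of class `headline_stats`
#' @export
reproduce_headline <- function(path, fast = TRUE, seed = 1L, folds = 10L) {
  data <- complete_rows(load_combined_dataset(path))
  tabs <- combined_to_tables(data)
  key <- c(G1 = "g1", S = "s", G2M = "g2m")
  corr <- do.call(rbind, lapply(PHASES, function(ph) {
    e <- tabs$expression[tabs$expression$phase == ph, ]
    data.frame(phase = ph,
               r_mp = stats::cor(e$mrna, e$protein, method = "spearman"),
               r_tp = stats::cor(e$translation, e$protein,
                                 method = "spearman"))
  }))
  preds <- list(); ratios <- c(); models <- list()
  for (ph in PHASES) {
    d <- build_feature_matrix(tabs$expression, tabs$features, phase = ph)
    path_l <- tune_lasso_alpha(d$X, d$y, folds = folds, seed = seed)
    sel <- lasso_select(d$X, d$y, path_l$alpha_star)
    keep <- unique(c("mrna", "translation", sel$selected))
    cmp <- compare_models_cv(
      d$X, d$y,
      models = list(
        gbrt = model_gbrt(model_spec("gbrt")),
        ols = model_ols(),
        naive = model_naive()),
      folds = folds, seed = seed)
    models[[ph]] <- cmp
    pred <- loocv_predict(d$X[, keep, drop = FALSE], d$y,
                          model_spec("gbrt"), fast = fast, seed = seed)
    preds[[ph]] <- pred
    y <- stats::setNames(d$y, d$gene_ids)
    yhat <- stats::setNames(pred$yhat, d$gene_ids)
    call <- call_outliers(squared_error(y, yhat), 90)
    ratios[[ph]] <- split_over_under(y, yhat, call$outliers)$ratio
  }
  e_all <- tabs$expression
  uni_r2 <- c(
    mrna = stats::cor(e_all$mrna, e_all$protein)^2,
    translation = stats::cor(e_all$translation, e_all$protein)^2)
  structure(list(
    n = nrow(data), correlations = corr, univariate_r2 = uni_r2,
    model_cv = models, pooled = pool_predictions(preds),
    over_under_ratio = ratios), class = "headline_stats")
}

#' @export
print.headline_stats <- function(x, ...) {
  cat(sprintf("<headline_stats> n = %d complete genes\n", x$n))
  print(x$correlations, row.names = FALSE)
  cat(sprintf("univariate R^2: mRNA %.3f, translation %.3f\n",
              x$univariate_r2[["mrna"]], x$univariate_r2[["translation"]]))
  for (ph in names(x$model_cv)) {
    m <- x$model_cv[[ph]]
    cat(sprintf("%s 10-fold R^2: %s\n", ph,
                paste(sprintf("%s %.3f+/-%.3f", m$model, m$mean_r2,
                              m$sd_r2), collapse = ", ")))
  }
  cat(sprintf("pooled r_p = %.3f (R^2 = %.3f); over:under ratios %s\n",
              x$pooled$r_p, x$pooled$r2,
              paste(sprintf("%s %.2f", names(x$over_under_ratio),
                            unlist(x$over_under_ratio)), collapse = ", ")))
  invisible(x)
}
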