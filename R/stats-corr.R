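# Descriptive statistics: Spearman correlation matrices with per-pair n,
# average-linkage hierarchical clustering of 1 - r distances, and PCA
# explained-variance fractions on the standardised input matrix.

#' Spearman correlation matrix with per-pair sample sizes
#'
#' Rank correlation with average ranks for ties. Deletion is listwise by
#' default (complete rows only) or pairwise-complete per flag; the number of
#' observations actually used is recorded per pair. A constant column has
#' undefined correlation: reported as `NA` with a warning, never as 0.
#'
#' @param columns data.frame or named list of equal-length numeric vectors
#'   (>= 2 columns, >= 3 paired observations)
#' @param pairwise_complete use pairwise-complete observations instead of
#'   listwise deletion
#' @param method "spearman" (default) or "pearson"
#' @return list of class `correlation_matrix`: `r` (symmetric, unit
#'   diagonal), `n_used`, `method`, `labels`
#' @export
spearman_matrix <- function(columns, pairwise_complete = FALSE,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  df <- as.data.frame(columns)
  if (ncol(df) < 2L) stop("need >= 2 columns", call. = FALSE)
  p <- ncol(df)
  labels <- names(df)
  if (!pairwise_complete) df <- df[stats::complete.cases(df), , drop = FALSE]
  r <- matrix(NA_real_, p, p, dimnames = list(labels, labels))
  n_used <- matrix(0L, p, p, dimnames = list(labels, labels))
  diag(r) <- 1
  warned <- FALSE
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      ok <- stats::complete.cases(df[[i]], df[[j]])
      x <- df[[i]][ok]; y <- df[[j]][ok]
      n_used[i, j] <- n_used[j, i] <- length(x)
      if (length(x) < 3L) {
        stop("fewer than 3 paired observations for ",
             labels[i], " vs ", labels[j], call. = FALSE)
      }
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warned <- TRUE
        next
      }
      r[i, j] <- r[j, i] <- stats::cor(x, y, method = method)
    }
  }
  diag(n_used) <- vapply(df, function(v) sum(!is.na(v)), integer(1))
  if (warned) {
    warning("constant column(s): correlation undefined, reported as NA")
  }
  structure(list(r = r, n_used = n_used, method = method, labels = labels),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3L, ...) {
  cat(sprintf("<correlation_matrix> %s, %d variables\n", x$method,
              length(x$labels)))
  print(round(x$r, digits))
  invisible(x)
}

#' Hierarchical clustering order of a correlation matrix
#'
#' Agglomerative clustering on the distance d = 1 - r with average linkage.
#' Ties in distance break deterministically on label order (labels are
#' sorted before clustering so the input column order never matters).
#'
#' @param corr a `correlation_matrix`
#' @param impute replace missing correlations with the column mean distance
#'   instead of failing
#' @return list: `order` (leaf labels in dendrogram order), `merge`, and
#'   `heights` from [stats::hclust()]
#' @export
cluster_order <- function(corr, impute = FALSE) {
  stopifnot(inherits(corr, "correlation_matrix"))
  r <- corr$r
  ord <- order(rownames(r))
  r <- r[ord, ord, drop = FALSE]
  d <- 1 - r
  if (anyNA(d)) {
    if (!impute) {
      stop("correlation matrix has missing cells; set impute = TRUE",
           call. = FALSE)
    }
    for (j in seq_len(ncol(d))) {
      miss <- is.na(d[, j])
      col_mean <- mean(d[!miss, j][d[!miss, j] > 0])
      d[miss, j] <- col_mean
      d[j, miss] <- col_mean
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(order = rownames(r)[hc$order], merge = hc$merge,
       heights = hc$height, hclust = hc)
}

#' PCA explained-variance fractions
#'
#' Columns are standardised (zero mean, unit variance) before the
#' decomposition; constant columns are dropped with a warning. The bias
#' column, if present, is removed first.
#'
#' @param X numeric matrix or data.frame (genes x features, target excluded)
#' @return non-negative fractions summing to 1, non-increasing
#' @export
pca_explained_variance <- function(X) {
  X <- as.matrix(X)
  X <- X[, setdiff(colnames(X), "bias"), drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  v <- pc$sdev^2
  v / sum(v)
}
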