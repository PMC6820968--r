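# Residual-based novelty detection: squared log2 residuals (epsilon),
# percentile outlier calling, the over/under-estimation split, and
# set-overlap analytics across selectors and phases.

#' Squared prediction residuals
#'
#' epsilon_i = (y_i - yhat_i)^2, the novelty-detection statistic.
#'
#' @param y,yhat equal-length finite numeric vectors
#' @return non-negative numeric vector
#' @export
squared_error <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (anyNA(y) || anyNA(yhat) || any(!is.finite(c(y, yhat)))) {
    stop("non-finite values", call. = FALSE)
  }
  (y - yhat)^2
}

#' Call percentile outliers on the squared-error vector
#'
#' Genes with epsilon strictly above the q-th percentile (type-7 linear
#' interpolation). For `q = 5` the complement sense applies: the
#' best-predicted genes, epsilon strictly below the 5th percentile. Ties
#' exactly at the threshold are excluded (strict inequality), so a constant
#' epsilon vector yields an empty set.
#'
#' @param eps named non-negative numeric vector (names = gene ids)
#' @param q percentile in (0, 100); values < 50 select the best-predicted
#'   tail, values >= 50 the worst-predicted tail
#' @return list of class `outlier_call`: `outliers` (gene ids), `threshold`,
#'   `q`, `sense` ("above"/"below")
#' @export
call_outliers <- function(eps, q = 90) {
  if (length(eps) == 0L) stop("empty epsilon vector", call. = FALSE)
  if (q <= 0 || q >= 100) stop("q must lie in (0, 100)", call. = FALSE)
  if (is.null(names(eps))) names(eps) <- as.character(seq_along(eps))
  thr <- as.numeric(stats::quantile(eps, q / 100, type = 7L))
  if (q < 50) {
    sel <- eps < thr
    sense <- "below"
  } else {
    sel <- eps > thr
    sense <- "above"
  }
  structure(list(outliers = names(eps)[sel], threshold = thr, q = q,
                 sense = sense, n = length(eps)),
            class = "outlier_call")
}

#' @export
print.outlier_call <- function(x, ...) {
  cat(sprintf("<outlier_call> q%.4g (%s threshold %.4g): %d / %d genes\n",
              x$q, x$sense, x$threshold, length(x$outliers), x$n))
  invisible(x)
}

#' Split outliers into over- and underestimated sets
#'
#' Overestimated: the model predicts more protein than measured
#' (yhat > y, candidate degradation); underestimated: measured exceeds
#' predicted (y > yhat, candidate stabilising modification). The ratio
#' |over| / |under| is `Inf` when no outlier is underestimated.
#'
#' @param y,yhat named numeric vectors covering all outlier genes
#' @param outliers character vector of outlier gene ids
#' @return list: `overestimated`, `underestimated`, `ratio`
#' @export
split_over_under <- function(y, yhat, outliers) {
  if (!all(outliers %in% names(y)) || !all(outliers %in% names(yhat))) {
    stop("outliers must be a subset of the named genes", call. = FALSE)
  }
  d <- yhat[outliers] - y[outliers]
  if (any(d == 0)) {
    stop("outlier with y == yhat: inconsistent with a positive epsilon ",
         "threshold", call. = FALSE)
  }
  over <- outliers[d > 0]
  under <- outliers[d < 0]
  ratio <- if (length(under) == 0L) Inf else length(over) / length(under)
  list(overestimated = over, underestimated = under, ratio = ratio)
}

#' Overlap regions and Jaccard indices of outlier sets
#'
#' @param sets named list of 2 or 3 character vectors
#' @return list: `regions` (all 2^k - 1 exclusive region cardinalities,
#'   named by set membership like "A&B"), `jaccard` (pairwise matrix)
#' @export
outlier_overlap <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L) stop("need 2 or 3 sets", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(k)]
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  combos <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, paste, collapse = "&", simplify = TRUE)
  }))
  regions <- stats::setNames(integer(length(combos)), combos)
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  jac <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      jac[i, j] <- jac[j, i] <- if (uni == 0L) NA_real_ else inter / uni
    }
  }
  list(regions = regions, jaccard = jac)
}

#' Consensus outliers across feature selectors
#'
#' Genes called outliers by all supplied selectors (the robust set carried
#' into PTM enrichment).
#'
#' @param sets named list of character vectors (one per selector)
#' @return character vector
#' @export
consensus_outliers <- function(sets) {
  Reduce(intersect, sets)
}
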