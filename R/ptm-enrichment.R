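# PTM-site enrichment of outlier sets against a subsampling null: B random
# same-size protein sets drawn from the full universe (outliers included,
# without replacement within each draw by default), an empirical one-sided
# p-value, a Welch/paired t-test battery, and the over/under split contrast.

#' Total PTM sites of a gene record
#'
#' Sum over the five modification types (acetylation, methylation,
#' palmitoylation, phosphorylation, sumoylation); missing counts were filled
#' with zero at construction.
#'
#' @param record a [gene_record()]
#' @return non-negative integer
#' @export
total_ptm <- function(record) {
  cnt <- record$ptm_counts[PTM_TYPES]
  if (any(cnt < 0L)) stop("negative PTM count", call. = FALSE)
  sum(cnt)
}

#' Subsampling null distribution of mean total PTM
#'
#' Draws B subsamples of size k from the per-protein totals of the full
#' universe (no exclusions) and records each subsample mean.
#'
#' @param totals per-protein total PTM counts (the universe)
#' @param k subsample size, typically the outlier-set size
#' @param B number of subsamples
#' @param seed RNG seed
#' @param mode "without_replacement" (default; the draws are subsamples
#'   despite the conventional "bootstrap" label) or "with_replacement"
#' @return list of class `bootstrap_null`: `means`, `B`, `k`, `seed`, `mode`
#' @export
bootstrap_null_means <- function(totals, k, B = 10000L, seed = 1L,
                                 mode = c("without_replacement",
                                          "with_replacement")) {
  mode <- match.arg(mode)
  n <- length(totals)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (mode == "without_replacement" && k > n) {
    stop("k exceeds universe size for sampling without replacement",
         call. = FALSE)
  }
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  replace <- mode == "with_replacement"
  means <- vapply(seq_len(B), function(b) {
    mean(totals[sample.int(n, k, replace = replace)])
  }, numeric(1))
  structure(list(means = means, B = as.integer(B), k = as.integer(k),
                 seed = as.integer(seed), mode = mode,
                 population_mean = mean(totals)),
            class = "bootstrap_null")
}

#' @export
print.bootstrap_null <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_null> B = %d draws of k = %d (%s): mean %.3f, sd %.3f\n",
    x$B, x$k, x$mode, mean(x$means), stats::sd(x$means)))
  invisible(x)
}

#' Empirical one-sided (upper) p-value against a subsampling null
#'
#' p = (1 + #\{null means >= observed\}) / (B + 1), the add-one estimator,
#' so p is never exactly zero.
#'
#' @param observed_mean observed mean total PTM of the outlier set
#' @param null a [bootstrap_null_means()] result
#' @return p in (0, 1]
#' @export
empirical_p <- function(observed_mean, null) {
  stopifnot(inherits(null, "bootstrap_null"))
  (1 + sum(null$means >= observed_mean)) / (null$B + 1)
}

#' Enrichment summary of an outlier set against its null
#'
#' @param outlier_totals total PTM counts of the outlier proteins
#' @param null matching [bootstrap_null_means()] (same k)
#' @return list of class `enrichment_result`: `observed_mean`, `null_mean`,
#'   `null_sd`, `displacement` ((obs - null mean)/null sd), `p`
#' @export
enrichment_result <- function(outlier_totals, null) {
  obs <- mean(outlier_totals)
  mu <- mean(null$means)
  sd <- stats::sd(null$means)
  structure(list(observed_mean = obs, null_mean = mu, null_sd = sd,
                 displacement = (obs - mu) / sd,
                 p = empirical_p(obs, null), k = null$k, B = null$B),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> obs %.3f vs null %.3f +/- %.3f (z = %.2f, p = %.4g)\n",
    x$observed_mean, x$null_mean, x$null_sd, x$displacement, x$p))
  invisible(x)
}

# vectorised Welch two-sample p-values: columns of `draws` vs a fixed sample
.welch_p <- function(x, draws) {
  nx <- length(x); ny <- nrow(draws)
  mx <- mean(x); vx <- stats::var(x)
  my <- colMeans(draws)
  vy <- (colSums(draws^2) - ny * my^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' t-test battery of an outlier set against random same-size draws
#'
#' For each of B random size-k draws from the universe, tests the outlier
#' totals against the draw and reports the fraction of tests with p < 0.05.
#' Default is a Welch two-sample test; `paired = TRUE` pairs the sorted
#' outlier totals with the sorted draw.
#'
#' @param outlier_totals totals of the k outlier proteins
#' @param universe_totals totals of the full universe
#' @param B number of draws
#' @param seed RNG seed
#' @param paired pair by sorted order instead of Welch two-sample
#' @param alpha significance level of the battery
#' @return list: `fraction_significant`, `B`, `alpha`, `paired`
#' @export
ttest_battery <- function(outlier_totals, universe_totals, B = 1000L,
                          seed = 1L, paired = FALSE, alpha = 0.05) {
  k <- length(outlier_totals)
  if (k < 2L) stop("need k >= 2", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(universe_totals)
  draws <- matrix(universe_totals[
    as.vector(vapply(seq_len(B), function(b) sample.int(n, k),
                     integer(k)))], nrow = k)
  if (paired) {
    xs <- sort(outlier_totals)
    draws_s <- apply(draws, 2L, sort)
    d <- draws_s - xs
    md <- colMeans(d)
    sdd <- sqrt((colSums(d^2) - k * md^2) / (k - 1))
    tstat <- md / (sdd / sqrt(k))
    p <- 2 * stats::pt(-abs(tstat), k - 1)
    p[sdd == 0] <- 1   # identical paired samples: no evidence
  } else {
    p <- .welch_p(outlier_totals, draws)
    p[is.na(p)] <- 1
  }
  list(fraction_significant = mean(p < alpha), B = B, alpha = alpha,
       paired = paired)
}

#' PTM enrichment of the over/under outlier split
#'
#' Builds an independent subsampling null at each set's size and returns the
#' pair of enrichment results; on data where stabilised (underestimated)
#' proteins carry elevated PTM rates, the underestimated displacement is
#' expected to exceed the overestimated one.
#'
#' @param over_set,under_set character vectors of gene ids (non-empty)
#' @param totals named per-protein total PTM counts (the universe)
#' @param B subsamples per null
#' @param seed RNG seed (the two nulls use seed and seed + 1)
#' @return list: `over`, `under` (each an `enrichment_result`)
#' @export
split_enrichment <- function(over_set, under_set, totals, B = 10000L,
                             seed = 1L) {
  if (length(over_set) == 0L || length(under_set) == 0L) {
    stop("both outlier sets must be non-empty", call. = FALSE)
  }
  miss <- setdiff(c(over_set, under_set), names(totals))
  if (length(miss) > 0L) {
    stop("totals missing for: ", paste(utils::head(miss, 5L),
                                       collapse = ", "), call. = FALSE)
  }
  null_over <- bootstrap_null_means(totals, length(over_set), B, seed)
  null_under <- bootstrap_null_means(totals, length(under_set), B,
                                     seed + 1L)
  list(over = enrichment_result(totals[over_set], null_over),
       under = enrichment_result(totals[under_set], null_under))
}
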