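# Codon-level sequence features: GC content, codon adaptation index (CAI),
# Wright's effective number of codons (Nc), tRNA adaptation index (tAI) and
# a reference-free relative codon usage bias score (CUB). All metrics depend
# only on codon counts, hence are invariant to codon order and to a trailing
# stop codon.

#' GC content of a nucleotide sequence
#'
#' @param seq non-empty sequence over A/C/G/T (U tolerated)
#' @return (#G + #C) / length, in \[0,1\]
#' @export
gc_content <- function(seq) {
  seq <- normalize_nt(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop("non-ACGT symbol '", chars[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  }
  sum(chars %in% c("G", "C")) / length(chars)
}

# Relative adaptiveness w_c per codon from a usage table: f_c divided by the
# synonymous-family maximum. Zero reference frequencies are floored at 0.5
# per thousand (Sharp-Li convention) so every log is finite.
.cai_weights <- function(table) {
  f <- as.numeric(table)
  names(f) <- names(table)
  f[f == 0] <- 0.5
  w <- stats::setNames(numeric(64L), CODONS)
  for (fam in NC_FAMILIES) {
    w[fam] <- f[fam] / max(f[fam])
  }
  w
}

# Codons that carry no CAI information: stops and single-codon families.
.CAI_EXCLUDED <- c(STOP_CODONS, "ATG", "TGG")

#' Codon adaptation index
#'
#' Geometric mean of relative adaptiveness w_c = f_c / max(f over synonymous
#' codons), over the CDS codons excluding stop codons and the single-codon
#' families Met and Trp.
#'
#' @param cds coding sequence, length divisible by 3
#' @param table a [codon_usage_table()] of reference frequencies per thousand
#' @return CAI in (0,1\]
#' @export
cai <- function(cds, table) {
  stopifnot(inherits(table, "codon_usage_table"))
  cnt <- codon_counts(cds)
  cnt[.CAI_EXCLUDED] <- 0L
  n <- sum(cnt)
  if (n == 0L) {
    stop("CDS has no informative codons (only Met/Trp/stop)", call. = FALSE)
  }
  w <- .cai_weights(table)
  keep <- setdiff(CODONS, .CAI_EXCLUDED)
  exp(sum(cnt[keep] * log(w[keep])) / n)
}

#' Effective number of codons (Nc)
#'
#' Wright's reference-free codon bias statistic. Per synonymous family the
#' homozygosity is estimated as F = (n * sum(p_i^2) - 1) / (n - 1) over the
#' n codon occurrences with proportions p_i; families with n < 2 or F <= 0
#' are omitted. Class means over the 9 two-fold, 1 three-fold, 5 four-fold
#' and 3 six-fold families give Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6. An
#' undefined three-fold (or six-fold) class mean borrows (F2 + F4)/2 (or
#' F4); the result is clamped to \[20, 61\].
#'
#' @param cds coding sequence, length divisible by 3
#' @return Nc in \[20, 61\]
#' @export
effective_number_of_codons <- function(cds) {
  cnt <- codon_counts(cds)
  fhat <- vapply(NC_FAMILIES, function(fam) {
    n <- sum(cnt[fam])
    if (n < 2L) return(NA_real_)
    p <- cnt[fam] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  fhat[!is.na(fhat) & fhat <= 0] <- NA_real_
  cls <- NC_CLASS
  mean_cls <- function(k) {
    v <- fhat[cls == k & !is.na(fhat)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  f2 <- mean_cls(2L); f3 <- mean_cls(3L)
  f4 <- mean_cls(4L); f6 <- mean_cls(6L)
  if (is.na(f2) || is.na(f4)) {
    stop("Nc undefined: too few codons per synonymous family",
         call. = FALSE)
  }
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (is.na(f6)) f6 <- f4
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(max(nc, 20), 61)
}

# Absolute adaptiveness W_c per sense codon under dos Reis wobble rules.
# Within each four-codon box (third base T, C, A, G) the contributing
# anticodons are the Watson-Crick partner plus one wobble partner:
#   NNT <- A34 (WC)  and G34 (G:U wobble)
#   NNC <- G34 (WC)  and A34 (read as inosine, I:C)
#   NNA <- T34 (WC)  and A34 (inosine, I:A)
#   NNG <- C34 (WC)  and T34 (U:G wobble)
.tai_abs_weights <- function(trna) {
  gcn <- trna$copies
  s <- trna$s_params
  W <- stats::setNames(numeric(64L), CODONS)
  anti <- revcomp(CODONS)   # WC anticodon per codon
  gcn_wc <- gcn[anti]
  for (b in seq(1L, 64L, by = 4L)) {
    iT <- b; iC <- b + 1L; iA <- b + 2L; iG <- b + 3L
    W[iT] <- (1 - s["wc_t"]) * gcn_wc[iT] + (1 - s["gu"]) * gcn_wc[iC]
    W[iC] <- (1 - s["wc_c"]) * gcn_wc[iC] + (1 - s["ic"]) * gcn_wc[iT]
    W[iA] <- (1 - s["wc_a"]) * gcn_wc[iA] + (1 - s["ia"]) * gcn_wc[iT]
    W[iG] <- (1 - s["wc_g"]) * gcn_wc[iG] + (1 - s["ug"]) * gcn_wc[iA]
  }
  W[SENSE_CODONS]
}

#' tRNA adaptation index
#'
#' Absolute adaptiveness W_c sums (1 - s_ij) * tGCN_j over the anticodons
#' decoding codon c under wobble rules; relative weights w_c = W_c / max W_c
#' (over sense codons). tAI is the geometric mean of w_c over the CDS codons
#' with stops excluded. Codons with W_c = 0 take the geometric mean of the
#' nonzero weights (dos Reis convention).
#'
#' @param cds coding sequence, length divisible by 3
#' @param trna a [trna_copy_table()]
#' @return tAI in (0,1\]
#' @export
tai <- function(cds, trna) {
  stopifnot(inherits(trna, "trna_copy_table"))
  W <- .tai_abs_weights(trna)
  if (all(W == 0)) stop("all codon weights are zero", call. = FALSE)
  w <- W / max(W)
  gm_nonzero <- exp(mean(log(w[w > 0])))
  w[w == 0] <- gm_nonzero
  cnt <- codon_counts(cds)[SENSE_CODONS]
  n <- sum(cnt)
  if (n == 0L) stop("CDS contains only stop codons", call. = FALSE)
  exp(sum(cnt * log(w)) / n)
}

#' Reference-free relative codon usage bias (CUB)
#'
#' Relative-codon-bias-style score that needs no reference usage table:
#' with positional base frequencies f1, f2, f3 within codons of this CDS,
#' each codon xyz deviates by d = f(xyz) / (f1(x) f2(y) f3(z)) - 1 from the
#' null in which the three positions are independent; the score is
#' exp(mean over codon positions of log(1 + d)) - 1. Zero when the observed
#' codon frequencies factorise exactly (e.g. a single repeated codon).
#'
#' @param cds coding sequence, length divisible by 3
#' @return CUB score (>= -1); depends only on codon counts
#' @export
cub <- function(cds) {
  cnt <- codon_counts(cds)
  L <- sum(cnt)
  used <- cnt > 0L
  fxyz <- cnt[used] / L
  pos_freq <- function(k) {
    base <- substr(names(cnt), k, k)
    v <- tapply(cnt, base, sum)[.BASES]
    v[is.na(v)] <- 0
    names(v) <- .BASES
    v / L
  }
  f1 <- pos_freq(1L); f2 <- pos_freq(2L); f3 <- pos_freq(3L)
  nm <- names(cnt)[used]
  denom <- f1[substr(nm, 1L, 1L)] * f2[substr(nm, 2L, 2L)] *
    f3[substr(nm, 3L, 3L)]
  d1 <- fxyz / denom   # 1 + d, strictly positive for observed codons
  exp(sum(cnt[used] * log(d1)) / L) - 1
}
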