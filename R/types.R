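# Shared domain types. Plain lists/data.frames with light S3 classes and
# validators, in the style of most analysis packages: the containers stay
# transparent (str()-able, subsettable) while constructors enforce the
# invariants every downstream stage relies on.

PTM_TYPES <- c("acetylation", "methylation", "palmitoylation",
               "phosphorylation", "sumoylation")

ANNOTATION_TYPES <- c("exons", "sts", "misc_features", "regulatory",
                      "polyA", "protein_sites", "protein_regions")

PHASES <- c("G1", "S", "G2M")

#' Construct a gene record
#'
#' One gene's sequences, annotation-derived counts and PTM site counts.
#' Missing PTM counts are filled with zero; `validate_cds()` checks that the
#' coding sequence translates to `protein_seq`.
#'
#' @param gene_id HGNC-style symbol (uppercased on construction)
#' @param mrna_seq mRNA sequence (U tolerated, stored as DNA)
#' @param cds_seq coding sequence, length divisible by 3
#' @param protein_seq amino-acid sequence (20-letter alphabet)
#' @param utr5_len,utr3_len non-negative UTR lengths in nt
#' @param annotation_counts named non-negative integers
#'   (exons, sts, misc_features, regulatory, polyA, protein_sites,
#'   protein_regions); missing entries default to 0
#' @param delta_g_5utr 5'-UTR folding energy in kcal/mol (<= 0), an external
#'   input that is carried through, never computed here
#' @param ptm_counts named non-negative integers over the five modification
#'   types; missing entries default to 0
#' @return an object of class `gene_record`
#' @export
gene_record <- function(gene_id, mrna_seq = "", cds_seq = "",
                        protein_seq = "", utr5_len = 0L, utr3_len = 0L,
                        annotation_counts = integer(0),
                        delta_g_5utr = NA_real_,
                        ptm_counts = integer(0)) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  ann <- stats::setNames(integer(length(ANNOTATION_TYPES)), ANNOTATION_TYPES)
  ann[names(annotation_counts)] <- as.integer(annotation_counts)
  ptm <- stats::setNames(integer(length(PTM_TYPES)), PTM_TYPES)
  ptm[names(ptm_counts)] <- as.integer(ptm_counts)
  if (any(ann < 0L) || any(ptm < 0L)) {
    stop("annotation and PTM counts must be non-negative", call. = FALSE)
  }
  if (utr5_len < 0L || utr3_len < 0L) stop("UTR lengths must be >= 0")
  if (!is.na(delta_g_5utr) && delta_g_5utr > 0) {
    stop("delta_g_5utr must be <= 0 kcal/mol", call. = FALSE)
  }
  structure(list(
    gene_id = toupper(gene_id),
    mrna_seq = normalize_nt(mrna_seq),
    cds_seq = normalize_nt(cds_seq),
    protein_seq = toupper(protein_seq),
    utr5_len = as.integer(utr5_len),
    utr3_len = as.integer(utr3_len),
    annotation_counts = ann,
    delta_g_5utr = delta_g_5utr,
    ptm_counts = ptm
  ), class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat("<gene_record>", x$gene_id,
      sprintf("| mRNA %d nt, CDS %d nt, protein %d aa, total PTM %d\n",
              nchar(x$mrna_seq), nchar(x$cds_seq), nchar(x$protein_seq),
              sum(x$ptm_counts)))
  invisible(x)
}

#' Construct a phase-expression table
#'
#' Long-format mean log2 expression: one row per gene x phase with mRNA
#' (microarray), translation (nascent-chain proteomics) and protein (MS)
#' levels. Translation and protein may be missing.
#'
#' @param gene_id,phase,mrna,translation,protein equal-length vectors
#' @return data.frame of class `phase_expression`
#' @export
phase_expression <- function(gene_id, phase, mrna,
                             translation = NA_real_, protein = NA_real_) {
  phase <- as.character(phase)
  if (!all(phase %in% PHASES)) {
    stop("phase must be one of ", paste(PHASES, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(gene_id = toupper(as.character(gene_id)), phase = phase,
                   mrna = as.numeric(mrna),
                   translation = as.numeric(translation),
                   protein = as.numeric(protein),
                   stringsAsFactors = FALSE)
  for (v in c("mrna", "translation", "protein")) {
    bad <- is.infinite(df[[v]])
    if (any(bad)) stop("non-finite ", v, " values", call. = FALSE)
  }
  class(df) <- c("phase_expression", "data.frame")
  df
}

#' Construct a design matrix with bias column
#'
#' @param values numeric matrix (genes x features), no missing entries
#' @param gene_ids row identity
#' @param add_bias prepend a constant column of ones named "bias"
#' @return numeric matrix of class `feature_matrix` with gene_id rownames
#' @export
feature_matrix <- function(values, gene_ids = rownames(values),
                           add_bias = TRUE) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("feature matrix must be complete and finite", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("feature matrix requires unique column names", call. = FALSE)
  }
  if (add_bias && !"bias" %in% colnames(values)) {
    values <- cbind(bias = rep(1, nrow(values)), values)
  }
  rownames(values) <- gene_ids
  class(values) <- c("feature_matrix", class(values))
  values
}

#' Validate and construct a codon usage table
#'
#' @param freq named numeric vector: all 64 codons -> frequency per thousand
#' @return named numeric vector of class `codon_usage_table`, in canonical
#'   codon order
#' @export
codon_usage_table <- function(freq) {
  missing <- setdiff(CODONS, names(freq))
  if (length(missing) > 0L) {
    stop("usage table missing codons: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  freq <- freq[CODONS]
  if (any(freq < 0)) stop("negative codon frequency", call. = FALSE)
  total <- sum(freq)
  if (abs(total - 1000) > 0.5) {
    stop(sprintf("frequencies sum to %.2f, expected 1000 +/- 0.5", total),
         call. = FALSE)
  }
  structure(freq, class = "codon_usage_table")
}

# Default wobble selective constraints s_ij (dos Reis-style): the first four
# entries are the Watson-Crick pairings, then G:U, I:C, I:A and U:G wobble.
DEFAULT_S_PARAMS <- c(wc_t = 0, wc_c = 0, wc_a = 0, wc_g = 0,
                      gu = 0.41, ic = 0.28, ia = 0.9999, ug = 0.68)

#' Validate and construct a tRNA gene-copy-number table
#'
#' @param copies named integer vector: anticodon (DNA triplet) -> gene copy
#'   number; anticodons absent from the genome may be omitted (copy 0)
#' @param s_params wobble selective-constraint values in [0,1]; defaults to
#'   the classic dos Reis vector
#' @return list of class `trna_copy_table` with `copies` (all 64 anticodons)
#'   and `s_params`
#' @export
trna_copy_table <- function(copies, s_params = DEFAULT_S_PARAMS) {
  full <- stats::setNames(integer(64L), CODONS)
  unknown <- setdiff(names(copies), CODONS)
  if (length(unknown) > 0L) {
    stop("invalid anticodon(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full[names(copies)] <- as.integer(copies)
  if (any(full < 0L)) stop("negative copy number", call. = FALSE)
  if (all(full == 0L)) stop("all-zero tRNA copy table", call. = FALSE)
  s <- DEFAULT_S_PARAMS
  s[names(s_params)] <- as.numeric(s_params)
  if (any(s < 0 | s > 1)) stop("s values must lie in [0,1]", call. = FALSE)
  structure(list(copies = full, s_params = s), class = "trna_copy_table")
}
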