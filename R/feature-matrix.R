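# Assembly of the genes x features design matrix: per-gene sequence feature
# computation, merging with phase expression, and the lagged (t-1) design
# used to probe time-delay effects across the cell cycle.

#' Compute the full per-gene sequence feature table
#'
#' Runs every sequence-derived metric on a set of validated gene records.
#' Records whose CDS does not translate to the stated protein are dropped
#' with a warning (they are excluded from all downstream modelling).
#' Annotation counts are scaled by mRNA length (protein_sites and
#' protein_regions by protein length).
#'
#' @param records list of [gene_record()]
#' @param usage a [codon_usage_table()] (for CAI)
#' @param trna a [trna_copy_table()] (for tAI)
#' @return data.frame with `gene_id` plus the canonical feature columns
#' @export
compute_feature_table <- function(records, usage, trna) {
  ok <- vapply(records, validate_cds, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " record(s) failed CDS validation and were dropped")
    records <- records[ok]
  }
  if (length(records) == 0L) stop("no valid records", call. = FALSE)
  rows <- lapply(records, function(r) {
    pp <- protein_properties(r$protein_seq)
    mrna_len <- nchar(r$mrna_seq)
    prot_len <- nchar(r$protein_seq)
    ann <- r$annotation_counts
    per_nt <- scale_counts(ann[c("exons", "sts", "misc_features",
                                 "regulatory", "polyA")], mrna_len)
    per_aa <- scale_counts(ann[c("protein_sites", "protein_regions")],
                           prot_len)
    data.frame(
      gene_id = r$gene_id,
      gc_content = gc_content(r$mrna_seq),
      cai = cai(r$cds_seq, usage),
      nc = effective_number_of_codons(r$cds_seq),
      tai = tai(r$cds_seq, trna),
      cub = cub(r$cds_seq),
      mrna_length = mrna_len,
      cds_length = nchar(r$cds_seq),
      protein_length = prot_len,
      pmw = pp$pmw, pi = pp$pi, aromaticity = pp$aromaticity,
      instability_index = pp$instability_index, gravy = pp$gravy,
      helix_frac = pp$helix_frac, sheet_frac = pp$sheet_frac,
      coil_frac = pp$coil_frac,
      utr5_len = r$utr5_len, utr3_len = r$utr3_len,
      delta_g_5utr = r$delta_g_5utr,
      exons_scaled = per_nt[["exons"]], sts_scaled = per_nt[["sts"]],
      misc_features_scaled = per_nt[["misc_features"]],
      regulatory_scaled = per_nt[["regulatory"]],
      polyA_scaled = per_nt[["polyA"]],
      protein_sites_scaled = per_aa[["protein_sites"]],
      protein_regions_scaled = per_aa[["protein_regions"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Predecessor of a cell-cycle phase
#'
#' @param phase one of G1, S, G2M
#' @param wrap allow G1 -> G2M wrap-around (one full cycle back)
#' @return the preceding phase label
#' @export
phase_predecessor <- function(phase, wrap = FALSE) {
  phase <- match.arg(phase, PHASES)
  prev <- c(G1 = NA_character_, S = "G1", G2M = "S")[[phase]]
  if (is.na(prev)) {
    if (!wrap) {
      stop("G1 has no earlier phase within one cycle; set wrap = TRUE",
           call. = FALSE)
    }
    prev <- "G2M"
  }
  prev
}

#' Build the design matrix and target for one phase
#'
#' Assembles mRNA and translation at the requested phase (or at the
#' preceding phase when `lag = 1`), all feature columns, and a bias column;
#' genes with any missing value are dropped. The target is protein at the
#' requested phase.
#'
#' @param expression a [phase_expression()] table covering the needed phases
#' @param features data.frame with `gene_id` and feature columns (e.g. from
#'   [compute_feature_table()]), or `NULL` for an expression-only design
#' @param phase target phase
#' @param lag 0 (default) or 1; with 1, mRNA/translation come from the
#'   predecessor phase
#' @param wrap allow the G1 predecessor to wrap to G2/M
#' @return list: `X` ([feature_matrix()] with bias), `y` (protein log2
#'   levels), `gene_ids`
#' @export
build_feature_matrix <- function(expression, features = NULL, phase,
                                 lag = 0L, wrap = FALSE) {
  phase <- match.arg(phase, PHASES)
  if (!lag %in% c(0L, 1L)) {
    stop("lag must be 0 or 1 (only three phases)", call. = FALSE)
  }
  src_phase <- if (lag == 1L) phase_predecessor(phase, wrap) else phase
  exp_src <- expression[expression$phase == src_phase, , drop = FALSE]
  exp_tgt <- expression[expression$phase == phase, , drop = FALSE]
  if (nrow(exp_src) == 0L || nrow(exp_tgt) == 0L) {
    stop("expression for phase ", phase, " (and its source phase) required",
         call. = FALSE)
  }
  df <- merge(exp_src[, c("gene_id", "mrna", "translation")],
              exp_tgt[, c("gene_id", "protein")], by = "gene_id")
  if (!is.null(features)) {
    df <- merge(df, features, by = "gene_id")
  }
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no complete rows", call. = FALSE)
  df <- df[order(df$gene_id), , drop = FALSE]
  y <- df$protein
  xcols <- setdiff(names(df), c("gene_id", "protein"))
  X <- feature_matrix(as.matrix(df[, xcols, drop = FALSE]),
                      gene_ids = df$gene_id, add_bias = TRUE)
  list(X = X, y = y, gene_ids = df$gene_id, phase = phase, lag = lag)
}

#' Substitute lagged expression columns into a design
#'
#' Returns the design for `phase` in which the mRNA and translation columns
#' are taken from the preceding phase; the target stays at `phase`.
#' `lag = 0` reproduces the unlagged design exactly.
#'
#' @inheritParams build_feature_matrix
#' @return same structure as [build_feature_matrix()]
#' @export
lagged_design <- function(expression, features = NULL, phase, lag = 1L,
                          wrap = FALSE) {
  build_feature_matrix(expression, features, phase, lag = lag, wrap = wrap)
}

#' Split a combined dataset into expression and feature tables
#'
#' @param data a `combined_dataset` from [load_combined_dataset()]
#' @return list: `expression` (long [phase_expression()]) and `features`
#'   (gene_id + every non-expression column)
#' @export
combined_to_tables <- function(data) {
  phase_key <- c(g1 = "G1", s = "S", g2m = "G2M")
  expr <- do.call(rbind, lapply(names(phase_key), function(p) {
    phase_expression(
      gene_id = data$gene_id, phase = phase_key[[p]],
      mrna = data[[paste0("mrna_", p)]],
      translation = data[[paste0("translation_", p)]],
      protein = data[[paste0("protein_", p)]]
    )
  }))
  feat_cols <- setdiff(names(data), c("gene_id", EXPRESSION_COLS))
  features <- if (length(feat_cols) > 0L) {
    data.frame(gene_id = data$gene_id,
               data[, feat_cols, drop = FALSE],
               stringsAsFactors = FALSE, check.names = FALSE)
  } else NULL
  list(expression = expr, features = features)
}
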