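# Readers/writers for the combined dataset, FASTA sequences, codon usage
# and tRNA copy-number tables, plus the preprocessing rules applied before
# any modelling (longest-transcript choice, CDS validation, count scaling).

# Canonical vocabulary for the combined dataset. Expression columns are
# <level>_<phase>; feature columns use the abbreviations below. Header
# normalisation lowercases, strips punctuation and resolves common aliases
# so supplementary-style exports load without manual renaming.
EXPRESSION_COLS <- as.vector(outer(c("mrna", "translation", "protein"),
                                   c("g1", "s", "g2m"), paste, sep = "_"))

FEATURE_COLS <- c(
  "gc_content", "cai", "nc", "tai", "cub",
  "mrna_length", "cds_length", "protein_length",
  "pmw", "pi", "aromaticity", "instability_index", "gravy",
  "helix_frac", "sheet_frac", "coil_frac",
  "utr5_len", "utr3_len", "delta_g_5utr",
  paste0(ANNOTATION_TYPES, "_scaled")
)

.norm_header <- function(x) {
  x <- tolower(gsub("[^A-Za-z0-9]+", "_", trimws(x)))
  gsub("^_|_$", "", x)
}

.HEADER_ALIASES <- c(
  gene = "gene_id", gene_name = "gene_id", hgnc = "gene_id",
  symbol = "gene_id", gene_symbol = "gene_id",
  g2_m = "g2m", m = "g2m",
  gc = "gc_content", enc = "nc", n_c = "nc",
  length = "mrna_length", seq_length = "mrna_length",
  molecular_weight = "pmw", mw = "pmw",
  isoelectric_point = "pi",
  instability = "instability_index",
  helix = "helix_frac", sheet = "sheet_frac", coil = "coil_frac",
  turn = "coil_frac",
  dg_5utr = "delta_g_5utr", deltag = "delta_g_5utr"
)

.canonical_names <- function(nms) {
  out <- .norm_header(nms)
  hit <- out %in% names(.HEADER_ALIASES)
  out[hit] <- .HEADER_ALIASES[out[hit]]
  # expression aliases like mRNA.G1 / protein_G2.M arrive as mrna_g1 etc.
  out <- sub("_g2_m$", "_g2m", out)
  out <- sub("_m$", "_g2m", out)
  out
}

.sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0L) "\t" else ","
}

#' Load the combined multi-omics dataset
#'
#' Reads a delimited table with one row per gene: a gene identifier, nine
#' expression columns (mean log2 mRNA / translation / protein at G1, S and
#' G2/M) and any number of precomputed feature columns. Header names are
#' normalised to the canonical vocabulary; empty cells and "NA"/"NaN" tokens
#' are treated as missing. The delimiter (tab or comma) is sniffed from the
#' header line.
#'
#' @param path delimited text file
#' @param strict if `TRUE`, an unparseable numeric cell aborts with a
#'   row-level error; otherwise it becomes a flagged missing value
#' @return a `data.frame` of class `combined_dataset`; attribute `complete`
#'   is the logical complete-row flag and `attr(,"n_complete")` its count
#' @export
load_combined_dataset <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  delim <- .sniff_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  names(raw) <- .canonical_names(names(raw))
  required <- c("gene_id", EXPRESSION_COLS)
  absent <- setdiff(required, names(raw))
  if (length(absent) > 0L) {
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  out <- data.frame(gene_id = toupper(trimws(raw$gene_id)),
                    stringsAsFactors = FALSE)
  for (nm in setdiff(names(raw), "gene_id")) {
    x <- trimws(raw[[nm]])
    x[x %in% c("", "NA", "NaN", "nan", "na")] <- NA
    num <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(num)
    if (any(bad)) {
      if (strict) {
        stop("unparseable numeric value in column '", nm, "', row(s) ",
             paste(utils::head(which(bad), 5L), collapse = ", "),
             call. = FALSE)
      }
      num[bad] <- NA_real_
    }
    out[[nm]] <- num
  }
  complete <- stats::complete.cases(out)
  attr(out, "complete") <- complete
  attr(out, "n_complete") <- sum(complete)
  class(out) <- c("combined_dataset", "data.frame")
  out
}

#' @export
print.combined_dataset <- function(x, ...) {
  cat(sprintf("<combined_dataset> %d genes, %d complete rows, %d columns\n",
              nrow(x), attr(x, "n_complete"), ncol(x) - 1L))
  invisible(x)
}

#' Restrict a combined dataset to complete rows
#' @param data a `combined_dataset`
#' @return the complete-row subset (still a `combined_dataset`)
#' @export
complete_rows <- function(data) {
  keep <- stats::complete.cases(data)
  out <- data[keep, , drop = FALSE]
  attr(out, "complete") <- rep(TRUE, nrow(out))
  attr(out, "n_complete") <- nrow(out)
  class(out) <- class(data)
  out
}

#' Pick the longest transcript variant of a gene
#'
#' Among transcript variants sharing a gene id, returns the one with the
#' longest mRNA; ties break deterministically on the lexicographically
#' smallest mRNA sequence so the choice is order-independent.
#'
#' @param variants non-empty list of [gene_record()] with identical gene_id
#' @return a single `gene_record`
#' @export
select_longest_transcript <- function(variants) {
  if (length(variants) == 0L) stop("empty variant list", call. = FALSE)
  ids <- vapply(variants, `[[`, character(1), "gene_id")
  if (length(unique(ids)) != 1L) {
    stop("variants must share one gene_id, got: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  }
  len <- vapply(variants, function(r) nchar(r$mrna_seq), integer(1))
  cand <- which(len == max(len))
  if (length(cand) > 1L) {
    seqs <- vapply(variants[cand], `[[`, character(1), "mrna_seq")
    cand <- cand[order(seqs)[1L]]
  }
  variants[[cand[1L]]]
}

#' Check that a coding sequence translates to its protein
#'
#' `TRUE` iff standard-code translation of `cds_seq` (one trailing stop
#' stripped) equals `protein_seq` exactly. An internal stop codon yields
#' `FALSE`; a CDS whose length is not a multiple of 3 is an error.
#' Records failing this check are excluded from feature computation.
#'
#' @param record a [gene_record()]
#' @return logical
#' @export
validate_cds <- function(record) {
  if (nchar(record$cds_seq) %% 3L != 0L) {
    stop("CDS length not divisible by 3 for ", record$gene_id,
         call. = FALSE)
  }
  aa <- translate_cds(record$cds_seq, strip_stop = TRUE)
  identical(aa, record$protein_seq)
}

#' Scale an annotation count by sequence length
#'
#' Converts counts such as the number of exons into relative frequencies to
#' mitigate sequence-length bias.
#'
#' @param count non-negative count
#' @param length positive sequence length (nt or aa)
#' @return `count / length`
#' @export
scale_counts <- function(count, length) {
  if (any(length <= 0)) stop("length must be > 0", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  count / length
}

#' Read a FASTA file
#'
#' Sequences are uppercased with U normalised to T. Duplicate record ids are
#' an error.
#'
#' @param path FASTA file
#' @return named character vector (id -> sequence), file order preserved
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(normalize_nt(as.character(set)), ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a codon usage table (frequencies per thousand)
#'
#' Two-column delimited text: codon, frequency per thousand. Lines starting
#' with `#` are comments. All 64 codons must be present.
#'
#' @param path file path
#' @return a [codon_usage_table()]
#' @export
read_usage_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("codon", "freq"),
                          colClasses = c("character", "numeric"))
  codon_usage_table(stats::setNames(df$freq, normalize_nt(df$codon)))
}

#' Write a codon usage table
#' @param table a [codon_usage_table()]
#' @param path output file
#' @export
write_usage_table <- function(table, path) {
  writeLines(c("# codon\tfrequency_per_thousand",
               sprintf("%s\t%.6g", names(table), as.numeric(table))), path)
  invisible(path)
}

#' Read a tRNA gene-copy-number table
#'
#' Two-column delimited text: anticodon (DNA triplet), gene copy number.
#' Wobble s parameters may be overridden via `s_params`.
#'
#' @param path file path
#' @param s_params optional named overrides of the wobble constraints
#' @return a [trna_copy_table()]
#' @export
read_trna_table <- function(path, s_params = DEFAULT_S_PARAMS) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("anticodon", "copies"),
                          colClasses = c("character", "integer"))
  trna_copy_table(stats::setNames(df$copies, normalize_nt(df$anticodon)),
                  s_params = s_params)
}

#' Write a tRNA copy-number table
#' @param table a [trna_copy_table()]
#' @param path output file
#' @export
write_trna_table <- function(table, path) {
  nz <- table$copies
  writeLines(c("# anticodon\tgene_copies",
               sprintf("%s\t%d", names(nz), as.integer(nz))), path)
  invisible(path)
}

#' Read a per-protein PTM site-count table
#'
#' Delimited text with a gene id column and one column per modification
#' type; genes absent from the table, or empty cells, count as zero.
#'
#' @param path file path
#' @return data.frame with gene_id and the five PTM count columns
#' @export
read_ptm_table <- function(path) {
  delim <- .sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE)
  names(df) <- .canonical_names(names(df))
  if (!"gene_id" %in% names(df)) {
    stop("PTM table needs a gene id column", call. = FALSE)
  }
  out <- data.frame(gene_id = toupper(as.character(df$gene_id)),
                    stringsAsFactors = FALSE)
  for (p in PTM_TYPES) {
    v <- if (p %in% names(df)) suppressWarnings(as.numeric(df[[p]])) else 0
    v[is.na(v)] <- 0
    if (any(v < 0)) stop("negative PTM count in ", p, call. = FALSE)
    out[[p]] <- as.integer(round(v))
  }
  out
}
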