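# Standard genetic code tables and codon helpers shared by the sequence
# feature metrics. Codons are enumerated with the third base varying fastest
# in T,C,A,G order, giving 16 four-codon boxes that share the first two
# bases; the tRNA-adaptation wobble rules operate box-wise on this layout.

.BASES <- c("T", "C", "A", "G")

.codon_order <- function() {
  as.vector(t(outer(
    as.vector(t(outer(.BASES, .BASES, paste0))),
    .BASES, paste0
  )))
}

#' All 64 DNA codons in T/C/A/G box order
#' @keywords internal
CODONS <- .codon_order()

# Standard genetic code, stops as "*"
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STOP_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
SENSE_CODONS <- setdiff(names(GENETIC_CODE_STD), STOP_CODONS)

AA_ALPHABET <- sort(unique(GENETIC_CODE_STD[SENSE_CODONS]))

# Synonymous-family degeneracy classes for Wright's effective number of
# codons. Six-fold amino acids (Leu, Ser, Arg) form their own class;
# Ile is the single three-fold family; Met and Trp are single-codon.
NC_FAMILIES <- local({
  aa <- GENETIC_CODE_STD[SENSE_CODONS]
  split(names(aa), aa)
})
NC_CLASS <- vapply(NC_FAMILIES, length, integer(1))

#' Normalize a nucleotide string: uppercase, U -> T
#' @keywords internal
normalize_nt <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

#' Split a CDS into its codons
#'
#' @param cds a nucleotide string whose length is a multiple of 3
#' @return character vector of codons
#' @keywords internal
split_codons <- function(cds) {
  cds <- normalize_nt(cds)
  n <- nchar(cds)
  if (n == 0L) stop("empty CDS", call. = FALSE)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not a multiple of 3", call. = FALSE)
  }
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Tabulate codon counts over the 64-codon alphabet
#' @keywords internal
codon_counts <- function(cds) {
  cod <- split_codons(cds)
  bad <- !(cod %in% names(GENETIC_CODE_STD))
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(cod[bad]), collapse = ", "),
         call. = FALSE)
  }
  cnt <- table(factor(cod, levels = CODONS))
  stats::setNames(as.integer(cnt), CODONS)
}

#' Reverse complement of a DNA string
#' @keywords internal
revcomp <- function(seq) {
  comp <- chartr("ACGT", "TGCA", normalize_nt(seq))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a CDS under the standard genetic code
#'
#' Translation stops silently exclude a single trailing stop codon; an
#' internal stop yields a "*" in the output (callers decide how to treat it).
#'
#' @param cds nucleotide string, length divisible by 3
#' @param strip_stop drop one trailing stop codon before translating
#' @return amino-acid string
#' @export
translate_cds <- function(cds, strip_stop = TRUE) {
  cod <- split_codons(cds)
  if (strip_stop && length(cod) > 0L &&
      cod[length(cod)] %in% STOP_CODONS) {
    cod <- cod[-length(cod)]
  }
  aa <- GENETIC_CODE_STD[cod]
  if (anyNA(aa)) {
    stop("invalid codon(s): ",
         paste(unique(cod[is.na(aa)]), collapse = ", "), call. = FALSE)
  }
  paste(aa, collapse = "")
}
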