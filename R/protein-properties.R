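# ProtParam-class physicochemical properties computed from the amino-acid
# sequence: average molecular weight, isoelectric point (Bjellqvist pKa,
# bisection), aromaticity, Guruprasad instability index, Kyte-Doolittle
# GRAVY and the classic helix/sheet/coil residue-set fractions.

# Average residue masses (free amino acids; one water is subtracted per
# peptide bond) and the mass of water, in Daltons.
AA_MASS <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.201,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
)
WATER_MASS <- 18.0153

KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Bjellqvist pKa set (ExPASy convention), including residue-specific
# terminal corrections.
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_CTERM_RESIDUE <- c(D = 4.55, E = 4.75)
PKA_NTERM_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                       V = 7.44, E = 7.7)

HELIX_SET <- c("V", "I", "Y", "F", "W", "L")
SHEET_SET <- c("E", "M", "A", "L")
COIL_SET  <- c("N", "P", "G", "S")

# Guruprasad dipeptide instability weights (DIWV): rows = first
# residue, cols = second residue of each dipeptide.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))

.aa_chars <- function(protein_seq) {
  s <- toupper(protein_seq)
  if (nchar(s) == 0L) stop("empty protein sequence", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(AA_MASS))
  if (length(bad) > 0L) {
    stop("unknown residue '", chars[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  }
  chars
}

#' Net charge of a protein at a given pH
#'
#' Bjellqvist pKa model with residue-specific terminal corrections; the
#' charge is strictly decreasing in pH, which the pI bisection relies on.
#'
#' @param protein_seq amino-acid string
#' @param pH pH value(s)
#' @return net charge (vectorised over `pH`)
#' @export
charge_at_ph <- function(protein_seq, pH) {
  chars <- .aa_chars(protein_seq)
  cnt <- table(factor(chars, levels = names(AA_MASS)))
  pos_pk <- PKA_POSITIVE
  first <- chars[1L]
  if (first %in% names(PKA_NTERM_RESIDUE)) {
    pos_pk["Nterm"] <- PKA_NTERM_RESIDUE[first]
  }
  neg_pk <- PKA_NEGATIVE
  last <- chars[length(chars)]
  if (last %in% names(PKA_CTERM_RESIDUE)) {
    neg_pk["Cterm"] <- PKA_CTERM_RESIDUE[last]
  }
  pos_n <- c(Nterm = 1, cnt[c("K", "R", "H")])
  neg_n <- c(Cterm = 1, cnt[c("D", "E", "C", "Y")])
  vapply(pH, function(p) {
    sum(pos_n / (1 + 10^(p - pos_pk))) - sum(neg_n / (1 + 10^(neg_pk - p)))
  }, numeric(1))
}

.isoelectric_point <- function(protein_seq, tol = 0.01) {
  lo <- 0; hi <- 14
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (charge_at_ph(protein_seq, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical properties of a protein sequence
#'
#' @param protein_seq non-empty 20-letter amino-acid string (length >= 2,
#'   required by the dipeptide-based instability index)
#' @return named list: `pmw` (Da, average masses), `pi` (pH), `aromaticity`
#'   (fraction of F/W/Y), `instability_index` (Guruprasad), `gravy`
#'   (Kyte-Doolittle mean), and the `helix_frac`/`sheet_frac`/`coil_frac`
#'   secondary-structure residue-set fractions
#' @export
protein_properties <- function(protein_seq) {
  chars <- .aa_chars(protein_seq)
  L <- length(chars)
  if (L < 2L) {
    stop("instability index needs length >= 2", call. = FALSE)
  }
  dipep <- cbind(chars[-L], chars[-1L])
  list(
    pmw = sum(AA_MASS[chars]) - (L - 1L) * WATER_MASS,
    pi = .isoelectric_point(protein_seq),
    aromaticity = mean(chars %in% c("F", "W", "Y")),
    instability_index = (10 / L) * sum(DIWV[dipep]),
    gravy = mean(KYTE_DOOLITTLE[chars]),
    helix_frac = mean(chars %in% HELIX_SET),
    sheet_frac = mean(chars %in% SHEET_SET),
    coil_frac = mean(chars %in% COIL_SET)
  )
}
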