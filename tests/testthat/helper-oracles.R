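# Independent brute-force oracles for the codon metrics, written directly
# from their definitions with plain loops. They share only the universal
# genetic-code constant with the implementation under test, never its
# computation path.

GC_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_codons <- function(cds) {
  n <- nchar(cds)
  vapply(seq(1, n, 3), function(i) substr(cds, i, i + 2), character(1))
}

oracle_cai <- function(cds, freq) {
  # freq: named per-thousand vector over 64 codons
  f <- freq
  f[f == 0] <- 0.5
  logsum <- 0; n <- 0
  for (cod in oracle_codons(cds)) {
    aa <- GC_TABLE[[cod]]
    if (aa %in% c("*", "M", "W")) next
    fam <- names(GC_TABLE)[GC_TABLE == aa]
    logsum <- logsum + log(f[[cod]] / max(f[fam]))
    n <- n + 1
  }
  exp(logsum / n)
}

oracle_nc <- function(cds) {
  cods <- oracle_codons(cds)
  aas <- setdiff(unique(GC_TABLE), "*")
  fhat <- c(); size <- c()
  for (aa in aas) {
    fam <- names(GC_TABLE)[GC_TABLE == aa]
    cnt <- vapply(fam, function(c) sum(cods == c), numeric(1))
    n <- sum(cnt)
    if (n < 2) next
    Fv <- (n * sum((cnt / n)^2) - 1) / (n - 1)
    if (Fv <= 0) next
    fhat <- c(fhat, Fv); size <- c(size, length(fam))
  }
  cls_mean <- function(k) if (any(size == k)) mean(fhat[size == k]) else NA
  f2 <- cls_mean(2); f3 <- cls_mean(3); f4 <- cls_mean(4); f6 <- cls_mean(6)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (is.na(f6)) f6 <- f4
  min(max(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 20), 61)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_tai <- function(cds, copies, s = c(gu = 0.41, ic = 0.28,
                                          ia = 0.9999, ug = 0.68)) {
  # copies: named anticodon -> tGCN (missing = 0)
  gcn <- function(ac) if (ac %in% names(copies)) copies[[ac]] else 0
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  W <- numeric(0)
  for (cod in sense) {
    stem <- substr(cod, 1, 2)
    third <- substr(cod, 3, 3)
    wc <- gcn(oracle_revcomp(cod))
    W[[cod]] <- switch(third,
      T = wc + (1 - s[["gu"]]) * gcn(oracle_revcomp(paste0(stem, "C"))),
      C = wc + (1 - s[["ic"]]) * gcn(oracle_revcomp(paste0(stem, "T"))),
      A = wc + (1 - s[["ia"]]) * gcn(oracle_revcomp(paste0(stem, "T"))),
      G = wc + (1 - s[["ug"]]) * gcn(oracle_revcomp(paste0(stem, "A"))))
  }
  w <- W / max(W)
  gm <- exp(mean(log(w[w > 0])))
  w[w == 0] <- gm
  logsum <- 0; n <- 0
  for (cod in oracle_codons(cds)) {
    if (GC_TABLE[[cod]] == "*") next
    logsum <- logsum + log(w[[cod]]); n <- n + 1
  }
  exp(logsum / n)
}

oracle_cub <- function(cds) {
  cods <- oracle_codons(cds)
  L <- length(cods)
  tab <- table(cods)
  base_freq <- function(pos) {
    b <- table(substr(cods, pos, pos))
    as.numeric(b[c("T", "C", "A", "G")]) -> v
    names(v) <- c("T", "C", "A", "G"); v[is.na(v)] <- 0
    v / L
  }
  f1 <- base_freq(1); f2 <- base_freq(2); f3 <- base_freq(3)
  acc <- 0
  for (cod in cods) {
    d1 <- (sum(cods == cod) / L) /
      (f1[[substr(cod, 1, 1)]] * f2[[substr(cod, 2, 2)]] *
         f3[[substr(cod, 3, 3)]])
    acc <- acc + log(d1)
  }
  exp(acc / L) - 1
}

# random valid CDS over sense codons (no internal stops), optional stop tail
random_cds <- function(n_codons, seed, stop_tail = FALSE) {
  set.seed(seed)
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  cds <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  if (stop_tail) cds <- paste0(cds, sample(c("TAA", "TAG", "TGA"), 1))
  cds
}

# gene records constructed by translation (validate_cds TRUE by design)
random_records <- function(n, seed, n_codons = 60) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cds <- random_cds(n_codons, seed * 1000 + i, stop_tail = TRUE)
    gene_record(sprintf("FX%03d", i), mrna_seq = cds, cds_seq = cds,
                protein_seq = translate_cds(cds))
  })
}

# a tiny uniform codon usage table (per thousand)
uniform_usage <- function() {
  codon_usage_table(setNames(rep(1000 / 64, 64), names(GC_TABLE)))
}

# small synthetic combined dataset on disk; returns path
write_fixture_combined <- function(n = 5, seed = 1, dir = tempdir(),
                                   sep = "\t") {
  sim <- simulate_dataset(simulation_config(n_genes = n), seed = seed)
  wide <- write_combined_dataset(sim)
  path <- file.path(dir, sprintf("combined_fix_%d_%d.tsv", n, seed))
  utils::write.table(wide, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  path
}
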