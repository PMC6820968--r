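# sequence_features: codon metrics, protein properties, design assembly

test_that("gc_content handles the base cases and rejects bad symbols", {
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("ATNX"), "position 3")
})

test_that("CAI matches hand values and the brute-force oracle", {
  # all-optimal CDS: every codon is its family's maximum -> CAI = 1
  ut <- uniform_usage()
  freq <- setNames(as.numeric(ut), names(ut))
  freq[c("GGT", "GCT", "CCT", "ACT")] <- freq[c("GGT", "GCT", "CCT", "ACT")] + 5
  freq <- 1000 * freq / sum(freq)
  tab <- codon_usage_table(freq)
  best <- paste(c("GGT", "GCT", "CCT", "ACT"), collapse = "")
  expect_equal(cai(best, tab), 1.0)

  # toy: f(GGT)=20, f(GGA)=10, f(GGC)=f(GGG)=5 -> CDS GGT GGT GGA
  freq2 <- setNames(rep(1000 / 64, 64), names(freq))
  freq2[c("GGT", "GGA", "GGC", "GGG")] <- c(20, 10, 5, 5)
  freq2 <- 1000 * freq2 / sum(freq2)
  tab2 <- codon_usage_table(freq2)
  # family max rescaling is scale-free: w = (1, 1, 0.5)
  expect_equal(cai("GGTGGTGGA", tab2), exp((log(1) + log(1) + log(0.5)) / 3),
               tolerance = 1e-12)

  # stop-codon invariance and brute-force equality on random toys
  for (s in 1:5) {
    cds <- random_cds(10, seed = 100 + s)
    expect_equal(cai(cds, tab2), oracle_cai(cds, freq2), tolerance = 1e-9)
    expect_equal(cai(paste0(cds, "TAA"), tab2), cai(cds, tab2))
  }
  expect_error(cai("ATGTGG", tab2), "informative")
})

test_that("Nc matches Wright's statistic and its limits", {
  # one codon per amino-acid family, many times -> every F = 1 -> Nc = 20
  one_per_family <- paste(strrep(c(
    "TTT", "TTA", "TCT", "TAT", "TGT", "TGG", "CCT", "CAT", "CAA", "CGT",
    "ATT", "ATG", "ACT", "AAT", "AAA", "GTT", "GCT", "GAT", "GAA", "GGT"),
    4), collapse = "")
  expect_equal(effective_number_of_codons(one_per_family), 20)

  # hand check: one two-fold family at proportions (3/4, 1/4), n = 4
  # F = (4 * 0.625 - 1) / 3 = 0.5
  cds <- paste(c(rep("TTT", 3), "TTC",
                 strrep(c("TTA", "TCT", "CCT", "CAT", "CGT", "ATT", "ACT",
                          "AAT", "GTT", "GCT", "GAT", "GGT", "CAA", "AAA",
                          "GAA", "TAT", "TGT"), 2)), collapse = "")
  expect_equal(effective_number_of_codons(cds), oracle_nc(cds),
               tolerance = 1e-9)

  # long uniform-usage CDS approaches 61
  long_cds <- random_cds(10000, seed = 42)
  expect_lt(abs(effective_number_of_codons(long_cds) - 61), 1.5)

  # brute-force equality on random medium CDSs
  for (s in 1:5) {
    cds <- random_cds(80, seed = 200 + s)
    expect_equal(effective_number_of_codons(cds), oracle_nc(cds),
                 tolerance = 1e-9)
  }
  expect_error(effective_number_of_codons("TTT"), "undefined")
})

test_that("tAI matches the wobble-rule oracle and its limits", {
  # every W equal -> tAI = 1 for any CDS: uniform copies over all anticodons
  tt_eq <- trna_copy_table(setNames(rep(3L, 64), names(GC_TABLE)),
                           s_params = c(gu = 1, ic = 1, ia = 1, ug = 1))
  expect_equal(tai(random_cds(20, 7), tt_eq), 1.0)

  # two-codon toy: w = (1, 0.5) used once each -> sqrt(0.5)
  # GGT is decoded by anticodon ACC (WC); GGC by GCC (WC) + ACC (wobble off)
  tt2 <- trna_copy_table(c(ACC = 4L, GCC = 2L),
                         s_params = c(gu = 1, ic = 1, ia = 1, ug = 1))
  expect_equal(tai("GGTGGC", tt2), sqrt(0.5), tolerance = 1e-12)

  # permutation invariance
  expect_equal(tai("GGCGGT", tt2), tai("GGTGGC", tt2))

  # brute-force equality with default wobble s on random tables
  set.seed(31)
  for (s in 1:5) {
    copies <- setNames(rpois(64, 4), names(GC_TABLE))
    copies[copies == 0] <- copies[copies == 0] + 1L
    tt <- trna_copy_table(copies)
    cds <- random_cds(10, seed = 300 + s)
    expect_equal(tai(cds, tt),
                 oracle_tai(cds, copies), tolerance = 1e-9)
  }
  expect_error(trna_copy_table(setNames(rep(0L, 64), names(GC_TABLE))))
})

test_that("CUB is zero under factorisation and matches brute force", {
  expect_equal(cub("AAAAAAAAA"), 0)
  expect_equal(cub("ATGGAT"), oracle_cub("ATGGAT"), tolerance = 1e-12)
  for (s in 1:5) {
    cds <- random_cds(12, seed = 400 + s)
    expect_equal(cub(cds), oracle_cub(cds), tolerance = 1e-9)
    # order invariance: reverse the codon order
    cods <- oracle_codons(cds)
    expect_equal(cub(paste(rev(cods), collapse = "")), cub(cds),
                 tolerance = 1e-12)
  }
  expect_error(cub(""), "empty")
})

test_that("protein properties match trivial constants", {
  expect_equal(protein_properties("IIII")$gravy, 4.5)
  expect_equal(protein_properties("RRRR")$gravy, -4.5)
  expect_equal(protein_properties("FWY")$aromaticity, 1.0)
  expect_equal(protein_properties("AAAA")$aromaticity, 0.0)
  p <- protein_properties("VIYFWL")
  expect_equal(p$helix_frac, 1.0)
  expect_equal(protein_properties("EMAL")$sheet_frac, 1.0)
  expect_equal(protein_properties("NPGS")$coil_frac, 1.0)
  expect_error(protein_properties("AXA"), "unknown residue")
  expect_error(protein_properties("A"), "length >= 2")
})

test_that("protein properties agree with the frozen ProtParam panel", {
  # 20-peptide oracle panel computed offline with an established ProtParam
  # implementation; tolerances: 0.1 Da / 0.05 pH / 0.05 units
  panel <- read.csv(test_path("protparam_panel.csv"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(panel))) {
    p <- protein_properties(panel$seq[i])
    expect_equal(p$pmw, panel$pmw[i], tolerance = 0.1 / panel$pmw[i])
    expect_lt(abs(p$pi - panel$pi[i]), 0.05)
    expect_lt(abs(p$instability_index - panel$instab[i]), 0.05)
    expect_lt(abs(p$gravy - panel$gravy[i]), 1e-9)
    expect_lt(abs(p$aromaticity - panel$arom[i]), 1e-9)
  }
})

test_that("codon metrics are invariant to sequence duplication", {
  ut <- uniform_usage()
  tt <- synthetic_trna_table(1)
  for (s in 1:3) {
    cds <- random_cds(50, seed = 500 + s)
    dub <- paste0(cds, cds)
    expect_equal(cai(dub, ut), cai(cds, ut), tolerance = 1e-12)
    expect_equal(tai(dub, tt), tai(cds, tt), tolerance = 1e-12)
    expect_equal(cub(dub), cub(cds), tolerance = 1e-12)
    aa <- translate_cds(cds)
    expect_equal(protein_properties(paste0(aa, aa))$gravy,
                 protein_properties(aa)$gravy, tolerance = 1e-12)
  }
})

test_that("feature matrix assembly drops incomplete genes and is faithful", {
  sim <- simulate_dataset(simulation_config(n_genes = 10), seed = 21)
  feat <- compute_feature_table(sim$records, sim$usage, sim$trna)
  d <- build_feature_matrix(sim$expression, feat, phase = "G1")
  expect_equal(nrow(d$X), 10L)
  expect_false(anyNA(d$X))
  expect_true(all(d$X[, "bias"] == 1))

  # column-wise equality with per-gene recomputation
  r5 <- sim$records[[5]]
  row5 <- which(d$gene_ids == r5$gene_id)
  expect_equal(unname(d$X[row5, "cai"]), cai(r5$cds_seq, sim$usage))
  expect_equal(unname(d$X[row5, "gravy"]),
               protein_properties(r5$protein_seq)$gravy)
  expect_equal(unname(d$X[row5, "cds_length"]), nchar(r5$cds_seq))

  # two genes with missing translation are excluded
  expr <- sim$expression
  expr$translation[expr$phase == "G1" &
                     expr$gene_id %in% d$gene_ids[1:2]] <- NA
  d2 <- build_feature_matrix(expr, feat, phase = "G1")
  expect_equal(nrow(d2$X), 8L)

  # target is protein at the requested phase
  g1 <- sim$expression[sim$expression$phase == "G1", ]
  expect_equal(unname(d$y), g1$protein[match(d$gene_ids, g1$gene_id)])
})
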