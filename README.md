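# omicslier

Integrative multi-omics modelling of protein abundance across the human
cell cycle, with residual-based detection of post-translationally regulated
proteins.

## The problem

Transcript (mRNA) abundance is only a modest proxy for protein abundance
(Spearman r_s ≈ 0.47–0.49 in synchronized HeLa cells), while the
translatome — nascent-chain (PUNCH-P-style) measurements of proteins being
synthesized — correlates substantially better (r_s ≈ 0.66–0.67). The gap
that remains after accounting for translation is largely post-translational:
regulated degradation and stabilizing modifications. `omicslier` operationalises
this as a novelty-detection problem:

1. predict each protein's mean log2 abundance per cell-cycle phase (G1, S,
   G2/M) from mRNA, translation and ~25 sequence-derived features;
2. flag the genes the model cannot predict — the upper percentiles of the
   squared residual ε_i = (y_i − ŷ_i)² — as candidate post-translationally
   regulated proteins (overestimated ⇒ candidate degradation;
   underestimated ⇒ candidate stabilizing modification);
3. test outlier sets for enrichment of post-translational modification (PTM)
   sites against a null of B = 10000 random same-size protein subsamples.

## What is implemented

- **Sequence features**: GC content; codon adaptation index (CAI, geometric
  mean of relative adaptiveness against a "frequencies per thousand" usage
  table, Sharp–Li zero floor); Wright's effective number of codons (Nc);
  tRNA adaptation index (tAI, dos Reis wobble weights over gene copy
  numbers); a reference-free relative codon usage bias score (CUB);
  ProtParam-class protein properties (average molecular weight, Bjellqvist
  isoelectric point, aromaticity, Guruprasad instability index,
  Kyte–Doolittle GRAVY, helix/sheet/coil residue-set fractions).
- **Feature selection**: the L1 (lasso) path
  min{(1/2n)‖Xw−y‖² + α‖w‖₁} over α ∈ [10⁻³, 1] with 10-fold CV and the
  1-SE rule; recursive feature elimination; univariate k-best (regression
  F / tertile ANOVA).
- **Predictors**: naive two-input linear baseline (mRNA + translation), OLS,
  and gradient-boosted regression trees (T = 1000 trees, learning rate
  η = 0.01, depth 3) — implemented in compiled code, deterministic, with
  gain-based feature importances; leave-one-out CV (exact, or grouped
  20-fold in `fast` mode); time-lagged (t−1) designs.
- **Outliers**: percentile calls on ε (5th/90th/95th/97.5th/99th),
  over/under split, Venn-region and Jaccard overlap, consensus across
  selectors.
- **PTM enrichment**: subsampling null of mean total PTM sites, empirical
  one-sided p, Welch/paired t-test battery, over-vs-under split contrast.
- **Synthetic data**: a seed-deterministic generator (sequences, expression
  chain calibrated to the correlations above, Poisson PTM counts, injected
  degraded/stabilized outliers with ground truth) so the entire pipeline is
  testable with no downloads.

## Worked example

```r
library(omicslier)
sim      <- simulate_dataset(simulation_config(n_genes = 1000), seed = 42)
features <- compute_feature_table(sim$records, sim$usage, sim$trna)
design   <- build_feature_matrix(sim$expression, features, phase = "S")

path <- tune_lasso_alpha(design$X, design$y, seed = 42)
path
#> <lasso_path> 50 alphas in [0.001, 1], alpha* = 0.1207 (1se rule), 7 features remain
sel <- lasso_select(design$X, design$y, path$alpha_star)
sel
#> <selection_result> lasso: 7 features: mrna, translation, cai, cub,
#>   cds_length, protein_length, pmw

pred <- loocv_predict(design$X[, sel$selected], design$y,
                      model_spec("gbrt"), fast = TRUE, seed = 42)
pred
#> <prediction_result> grouped-20-fold, n = 1000, r_p = 0.907, R^2 = 0.823
sort(pred$importances, decreasing = TRUE)[1:4]
#> translation         cub  cds_length        mrna
#>   0.3190557   0.2177630   0.1790739   0.1522568

eps  <- setNames(squared_error(design$y, pred$yhat), design$gene_ids)
call <- call_outliers(eps, q = 90)
call
#> <outlier_call> q90 (above threshold 2.994): 100 / 1000 genes
split <- split_over_under(setNames(design$y, design$gene_ids),
                          setNames(pred$yhat, design$gene_ids),
                          call$outliers)
split$ratio          # overestimated : underestimated
#> 1.5

totals <- setNames(vapply(sim$records, total_ptm, numeric(1)),
                   vapply(sim$records, `[[`, character(1), "gene_id"))
enr <- split_enrichment(split$overestimated, split$underestimated,
                        totals, B = 5000, seed = 42)
enr$under
#> <enrichment_result> obs 14.250 vs null 8.242 +/- 0.491 (z = 12.23, p = 0.0002)
enr$over
#> <enrichment_result> obs 8.317 vs null 8.247 +/- 0.393 (z = 0.18, p = 0.4385)
```

Reading the output: the boosted-tree model predicts held-out S-phase protein
levels with Pearson r_p = 0.907; translation dominates the importances. Of
the 100 worst-predicted genes (ε above its 90th percentile), overestimated
outnumber underestimated 1.5:1, and the *underestimated* set carries a mean
total PTM count 12 null-sd above the subsampling null (p ≈ 2×10⁻⁴) while the
overestimated set does not — exactly the degradation/stabilization asymmetry
the generator injected (stabilized genes draw PTM counts at twice the
baseline Poisson rate).

## Command line

```sh
omicslier simulate --n 3000 --seed 1 --outdir data/
omicslier load     --data data/combined.tsv
omicslier select   --data data/combined.tsv --phase S --method lasso --out sel.json
omicslier predict  --data data/combined.tsv --phase S --fast --seed 1 --out pred.tsv
omicslier outliers --pred pred.tsv --q 90 --out outliers.tsv
omicslier ptm      --outliers outliers.tsv --ptm ptm.tsv --B 10000 --seed 1 --out enrich.json
```

(the launcher is installed at `inst/cli/omicslier`; run it with `Rscript` or
put it on PATH).

See `vignettes/omicslier-methods.Rmd` for the model, its assumptions, the
synthetic world's design and the package's numerical conventions.
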