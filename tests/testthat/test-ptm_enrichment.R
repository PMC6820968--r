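# ptm_enrichment: subsampling null, empirical p, t-test battery, split

test_that("total_ptm sums the five modification types", {
  r <- gene_record("P1", ptm_counts = c(phosphorylation = 3,
                                        acetylation = 1))
  expect_equal(total_ptm(r), 4L)
  expect_equal(total_ptm(gene_record("P2")), 0L)
  set.seed(4)
  for (i in 1:5) {
    cnt <- setNames(rpois(5, 3), omicslier:::PTM_TYPES)
    expect_equal(total_ptm(gene_record("PX", ptm_counts = cnt)), sum(cnt))
  }
})

test_that("subsampling null has the right limits and moments", {
  set.seed(10)
  totals <- rpois(400, 6)
  # k = universe size without replacement: every mean is the population mean
  full <- bootstrap_null_means(totals, k = 400, B = 50, seed = 1)
  expect_true(all(abs(full$means - mean(totals)) < 1e-12))
  # k = 1: null sd approximates the population sd
  one <- bootstrap_null_means(totals, k = 1, B = 10000, seed = 2)
  expect_lt(abs(sd(one$means) - sd(totals)) / sd(totals), 0.05)
  # null mean tracks the population mean for any k
  mid <- bootstrap_null_means(totals, k = 40, B = 10000, seed = 3)
  expect_lt(abs(mean(mid$means) - mean(totals)),
            4 * sd(mid$means) / sqrt(10000))
  expect_error(bootstrap_null_means(totals, k = 401, B = 10), "universe")
  # with replacement allows k > n
  wr <- bootstrap_null_means(totals, k = 500, B = 10, seed = 1,
                             mode = "with_replacement")
  expect_length(wr$means, 10L)
  # seed-reproducible bit for bit
  expect_identical(bootstrap_null_means(totals, 40, 100, seed = 9)$means,
                   bootstrap_null_means(totals, 40, 100, seed = 9)$means)
})

test_that("empirical p: add-one estimator, exact count, monotonicity", {
  null <- bootstrap_null_means(rpois(200, 5), k = 20, B = 100, seed = 5)
  expect_equal(empirical_p(max(null$means) + 1, null), 1 / 101)
  # brute-force count equality on the B = 100 fixture
  obs <- median(null$means)
  expect_equal(empirical_p(obs, null),
               (1 + sum(null$means >= obs)) / 101)
  # monotone non-increasing in the observed mean
  grid <- seq(min(null$means), max(null$means), length.out = 20)
  ps <- vapply(grid, empirical_p, numeric(1), null = null)
  expect_true(all(diff(ps) <= 0))
  # observed at the population mean: p near one half
  sym <- bootstrap_null_means(rnorm(2000, 10), k = 50, B = 2000, seed = 7)
  expect_lt(abs(empirical_p(sym$population_mean, sym) - 0.5), 0.05)
})

test_that("t-test battery: type-I calibration, power, degenerate case", {
  set.seed(21)
  universe <- rpois(1000, 8)
  # exchangeable outlier sets: the battery's rejection rate, averaged over
  # set draws, calibrates to ~alpha (a single set's fraction varies widely
  # because the set's own mean is random)
  fracs <- vapply(1:40, function(s) {
    set.seed(s + 300)
    ttest_battery(universe[sample(1000, 60)], universe, B = 200,
                  seed = s)$fraction_significant
  }, numeric(1))
  expect_gt(mean(fracs), 0.02)
  expect_lt(mean(fracs), 0.09)
  # strong shift: essentially always significant
  same <- universe[sample(1000, 60)]
  shifted <- same + 5 * sd(universe)
  expect_gt(ttest_battery(shifted, universe, B = 200,
                          seed = 3)$fraction_significant, 0.99)
  # identical paired samples: p = 1, fraction 0
  const_universe <- rep(4, 100)
  expect_equal(ttest_battery(rep(4, 10), const_universe, B = 50, seed = 1,
                             paired = TRUE)$fraction_significant, 0)
  expect_error(ttest_battery(5, universe, B = 10), "k >= 2")
})

test_that("vectorised Welch p-values agree with stats::t.test", {
  set.seed(33)
  x <- rpois(30, 6)
  draws <- matrix(rpois(30 * 5, 7), 30, 5)
  mine <- omicslier:::.welch_p(x, draws)
  ref <- apply(draws, 2, function(d) t.test(x, d)$p.value)
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("split enrichment separates elevated-rate sets", {
  set.seed(44)
  totals <- setNames(rpois(600, 6), sprintf("g%03d", 1:600))
  over <- under <- names(totals)[1:40]
  # identical sets: displacements agree up to the two nulls' Monte-Carlo
  # error (independent seeds, B = 4000)
  res <- split_enrichment(over, under, totals, B = 4000, seed = 5)
  expect_lt(abs(res$over$displacement - res$under$displacement), 0.15)
  expect_error(split_enrichment(character(0), under, totals), "non-empty")
  expect_error(split_enrichment(c(over, "nope"), under, totals), "missing")
  # generator ground truth: stabilized genes carry 2x Poisson rates, so the
  # under-set displacement exceeds the over-set in nearly all seeded runs
  wins <- vapply(1:20, function(s) {
    sim <- simulate_dataset(simulation_config(n_genes = 300), seed = s)
    totals <- setNames(vapply(sim$records, total_ptm, numeric(1)),
                       vapply(sim$records, `[[`, character(1), "gene_id"))
    lab <- setNames(sim$truth$label, sim$truth$gene_id)
    over <- names(lab)[lab == "degraded"]
    under <- names(lab)[lab == "stabilized"]
    r <- split_enrichment(over, under, totals, B = 500, seed = s)
    r$under$displacement > r$over$displacement
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
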