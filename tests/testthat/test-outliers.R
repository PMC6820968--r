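# outliers: epsilon, percentile calling, over/under split, overlaps

test_that("squared_error is the elementwise definition", {
  expect_equal(squared_error(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(squared_error(2, 5), 9)
  set.seed(3)
  y <- rnorm(40); yh <- rnorm(40)
  expect_equal(squared_error(y, yh), (y - yh)^2)
  expect_error(squared_error(1:3, 1:2), "length")
  expect_error(squared_error(c(1, NA), c(1, 2)), "finite")
})

test_that("percentile calling is exact on distinct values", {
  eps <- setNames(sample(seq(0.01, 1, length.out = 100)),
                  sprintf("g%03d", 1:100))
  call <- call_outliers(eps, 90)
  expect_length(call$outliers, 10L)
  expect_true(all(eps[call$outliers] > call$threshold))
  # all-equal epsilon: strict inequality yields the empty set
  expect_length(call_outliers(setNames(rep(0.5, 20), 1:20), 90)$outliers, 0L)
  # q97.5 on n = 1000: 25 +/- 1
  set.seed(6)
  eps2 <- setNames(rexp(1000), sprintf("h%04d", 1:1000))
  expect_lte(abs(length(call_outliers(eps2, 97.5)$outliers) - 25), 1)
  # q5 inverts to the best-predicted tail
  low <- call_outliers(eps2, 5)
  expect_length(low$outliers, 50L)
  expect_true(all(eps2[low$outliers] < low$threshold))
  expect_equal(low$sense, "below")
  expect_error(call_outliers(numeric(0), 90), "empty")
  expect_error(call_outliers(eps2, 100), "\\(0, 100\\)")
})

test_that("outlier calling commutes with monotone transforms of epsilon", {
  set.seed(9)
  eps <- setNames(rexp(200), sprintf("m%03d", 1:200))
  a <- call_outliers(eps, 95)$outliers
  b <- call_outliers(sqrt(eps) + 2, 95)$outliers
  expect_setequal(a, b)
})

test_that("over/under split and ratio", {
  y <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8, 9), letters[1:9])
  yhat <- y + c(1, 1, 1, 1, 1, 1, -1, -1, -1)   # 6 over, 3 under
  sp <- split_over_under(y, yhat, letters[1:9])
  expect_length(sp$overestimated, 6L)
  expect_length(sp$underestimated, 3L)
  expect_equal(sp$ratio, 2.0)
  sp2 <- split_over_under(y, y + 1, letters[1:9])
  expect_equal(sp2$ratio, Inf)
  expect_error(split_over_under(y, yhat, c("a", "zz")), "subset")
  expect_error(split_over_under(y, y, "a"), "inconsistent")
})

test_that("overlap regions and Jaccard are correct in the forced cases", {
  s <- sprintf("g%02d", 1:10)
  same <- outlier_overlap(list(A = s, B = s, C = s))
  expect_equal(unname(same$regions["A&B&C"]), 10L)
  expect_true(all(same$regions[names(same$regions) != "A&B&C"] == 0L))
  expect_true(all(same$jaccard == 1))
  disj <- outlier_overlap(list(A = s[1:5], B = s[6:10]))
  expect_equal(unname(disj$regions[c("A", "B", "A&B")]), c(5L, 5L, 0L))
  expect_equal(disj$jaccard["A", "B"], 0)
})

test_that("random same-size sets overlap at the hypergeometric rate", {
  trip <- vapply(1:1000, function(s) {
    set.seed(s)
    sets <- lapply(1:3, function(i) sample(3500, 350))
    length(Reduce(intersect, sets))
  }, numeric(1))
  # expectation n * 0.1^3 = 3.5
  expect_lt(abs(mean(trip) - 3.5), 0.5)
})

test_that("consensus outliers is the plain intersection", {
  s <- sprintf("g%02d", 1:10)
  expect_setequal(consensus_outliers(list(a = s, b = s, c = s)), s)
  expect_length(consensus_outliers(list(a = s, b = character(0), c = s)), 0L)
  expect_setequal(consensus_outliers(list(a = s[1:6], b = s[4:9],
                                          c = s[5:10])), s[5:6])
})

test_that("persistent injected outliers overlap across phases; q5 does not", {
  sim <- simulate_dataset(simulation_config(n_genes = 600), seed = 23)
  spec <- model_spec("ols")
  sets90 <- list(); sets05 <- list()
  for (ph in c("G1", "S", "G2M")) {
    d <- build_feature_matrix(sim$expression, NULL, phase = ph)
    pred <- loocv_predict(d$X, d$y, spec, fast = TRUE, seed = 1)
    eps <- setNames(squared_error(d$y, pred$yhat), d$gene_ids)
    sets90[[ph]] <- call_outliers(eps, 90)$outliers
    sets05[[ph]] <- call_outliers(eps, 5)$outliers
  }
  n <- 600
  triple90 <- length(Reduce(intersect, sets90))
  triple05 <- length(Reduce(intersect, sets05))
  chance90 <- n * 0.1^3          # 0.6 genes
  # persistent delta-injected outliers push q90 far above chance
  expect_gt(triple90, 10 * chance90)
  # best-predicted 5% behaves like random sampling (allow noise headroom)
  expect_lte(triple05, 5)
})
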