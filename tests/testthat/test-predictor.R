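# predictor: naive baseline, GBRT, LOOCV, lagged designs

test_that("naive two-input predictor: exact fit and null calibration", {
  set.seed(8)
  n <- 300
  m <- rnorm(n); t <- rnorm(n)
  res <- fit_naive(m, t, y = t)
  expect_equal(res$cv_r2, 1, tolerance = 1e-9)
  # independent-noise target: out-of-sample R^2 stays near zero
  null_r2 <- vapply(1:50, function(s) {
    set.seed(s + 100)
    fit_naive(rnorm(1000), rnorm(1000), rnorm(1000), seed = s)$cv_r2
  }, numeric(1))
  expect_true(all(null_r2 <= 0.05))
  expect_error(fit_naive(1:3, 1:3, 1:3), "n >= 4")
})

test_that("GBRT importances are normalised and concentrate correctly", {
  set.seed(12)
  n <- 400
  x <- rnorm(n)
  y <- sin(x) + 0.1 * rnorm(n)
  m1 <- fit_gbrt(cbind(only = x), y)
  expect_equal(unname(m1$importances["only"]), 1.0)
  # twin columns: combined importance matches the single-column case
  m2 <- fit_gbrt(cbind(a = x, b = x), y)
  expect_equal(sum(m2$importances), 1, tolerance = 1e-9)
  expect_equal(sum(m2$importances[c("a", "b")]), 1, tolerance = 1e-9)
  # importances sum to 1 on an arbitrary fit
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  m3 <- fit_gbrt(X, y)
  expect_equal(sum(m3$importances), 1, tolerance = 1e-9)
  expect_error(fit_gbrt(cbind(a = c(1, NA, 3)), 1:3), "missing")
})

test_that("GBRT is bit-reproducible and spec guards hold", {
  set.seed(2)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(200, 0, 0.2)
  s <- model_spec("gbrt", n_trees = 200)
  p1 <- predict(fit_gbrt(X, y, s), X)
  p2 <- predict(fit_gbrt(X, y, s), X)
  expect_identical(p1, p2)
  expect_error(model_spec("gbrt", n_trees = 0), "n_trees")
  expect_error(model_spec("gbrt", learning_rate = 0), "learning_rate")
})

test_that("LOOCV: exactness on linear data, ordering invariance, edge cases", {
  set.seed(3)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- 2 * X[, 1] - X[, 2] + 1
  rownames(X) <- sprintf("g%02d", 1:n)
  res <- loocv_predict(X, y, model_spec("ols"))
  expect_equal(res$yhat, y, tolerance = 1e-9)
  expect_equal(res$scheme, "loocv")
  # invariance to gene ordering (true LOOCV)
  perm <- sample(n)
  res_p <- loocv_predict(X[perm, ], y[perm], model_spec("ols"))
  expect_equal(res_p$yhat[match(rownames(X), rownames(X)[perm])], res$yhat,
               tolerance = 1e-9)
  # constant target: correlation undefined, reported as missing
  resc <- loocv_predict(X, rep(5, n), model_spec("ols"))
  expect_true(is.na(resc$r_p))
  expect_error(loocv_predict(X[1:5, ], y[1:5], model_spec("ols")),
               "n >= 10")
})

test_that("adding a pure-noise column does not inflate GBRT accuracy", {
  set.seed(17)
  n <- 250
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.4)
  spec <- model_spec("gbrt")
  base <- loocv_predict(X, y, spec, fast = TRUE, folds = 10, seed = 5)
  noisy <- loocv_predict(cbind(X, junk = rnorm(n)), y, spec, fast = TRUE,
                         folds = 10, seed = 5)
  expect_lte(noisy$r_p - base$r_p, 0.02)
})

test_that("lagged designs substitute the predecessor phase columns", {
  sim <- simulate_dataset(simulation_config(n_genes = 40), seed = 19)
  d0 <- build_feature_matrix(sim$expression, NULL, phase = "S")
  dlag <- lagged_design(sim$expression, NULL, phase = "S", lag = 1)
  dg1 <- build_feature_matrix(sim$expression, NULL, phase = "G1")
  # lag = 0 is the identity
  expect_identical(lagged_design(sim$expression, NULL, phase = "S",
                                 lag = 0)$X, d0$X)
  # lagged S design carries G1 expression columns
  shared <- intersect(dlag$gene_ids, dg1$gene_ids)
  expect_equal(dlag$X[shared, "mrna"], dg1$X[shared, "mrna"])
  # target remains S-phase protein
  expect_equal(dlag$y[match(shared, dlag$gene_ids)],
               d0$y[match(shared, d0$gene_ids)])
  expect_error(build_feature_matrix(sim$expression, NULL, phase = "G1",
                                    lag = 1), "wrap")
  expect_s3_class(
    try_wrap <- build_feature_matrix(sim$expression, NULL, phase = "G1",
                                     lag = 1, wrap = TRUE)$X,
    "feature_matrix")
  expect_error(build_feature_matrix(sim$expression, NULL, phase = "S",
                                    lag = 2), "lag")
})

test_that("lagged and unlagged outlier sets overlap on a static chain", {
  # time-independent chain: gene effects fully shared across phases
  overlaps <- vapply(1:10, function(s) {
    sim <- simulate_dataset(simulation_config(n_genes = 600,
                                              phase_share = 1), seed = s)
    spec <- model_spec("ols")
    d0 <- build_feature_matrix(sim$expression, NULL, phase = "S")
    d1 <- lagged_design(sim$expression, NULL, phase = "S", lag = 1)
    o0 <- call_outliers(setNames(squared_error(
      d0$y, loocv_predict(d0$X, d0$y, spec, fast = TRUE, seed = s)$yhat),
      d0$gene_ids), 90)$outliers
    o1 <- call_outliers(setNames(squared_error(
      d1$y, loocv_predict(d1$X, d1$y, spec, fast = TRUE, seed = s)$yhat),
      d1$gene_ids), 90)$outliers
    length(intersect(o0, o1)) / length(o0)
  }, numeric(1))
  expect_gte(mean(overlaps), 0.8)
})

test_that("pooled predictions aggregate phases", {
  r1 <- structure(list(y = c(1, 2, 3), yhat = c(1, 2, 3)), class = "prediction_result")
  r2 <- structure(list(y = c(4, 5), yhat = c(4, 5)), class = "prediction_result")
  pooled <- pool_predictions(list(r1, r2))
  expect_equal(pooled$r_p, 1)
  expect_equal(pooled$n, 5L)
})
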