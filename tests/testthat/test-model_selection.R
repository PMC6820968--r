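# model_selection: alpha tuning, the three selectors, CV model comparison

make_linear_world <- function(n = 200, p = 20, k = 3, noise = 0.5,
                              seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(rep(2, k), rep(0, p - k))
  list(X = X, y = as.numeric(X %*% beta + rnorm(n, 0, noise)),
       true = paste0("f", 1:k))
}

test_that("alpha at the grid maximum zeroes every coefficient", {
  w <- make_linear_world(seed = 2)
  y <- scale(w$y)[, 1]   # unit scale so alpha = 1 dominates
  path <- tune_lasso_alpha(w$X, y, grid = c(0.01, 0.1, 1), folds = 5)
  expect_equal(path$p_remaining[length(path$alphas)], 0L)
  # p_remaining non-increasing in alpha
  expect_true(all(diff(path$p_remaining) <= 0))
  expect_error(tune_lasso_alpha(w$X, y, grid = numeric(0)), "empty")
})

test_that("lasso support recovery: true features survive at alpha_star", {
  hits <- vapply(1:50, function(s) {
    w <- make_linear_world(n = 150, p = 20, k = 3, seed = s)
    path <- tune_lasso_alpha(w$X, w$y, grid = alpha_grid(n = 25L),
                             folds = 10, seed = s)
    sel <- lasso_select(w$X, w$y, path$alpha_star)
    all(w$true %in% sel$selected)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a perfect predictor column is selected by all three methods", {
  set.seed(9)
  n <- 120
  X <- cbind(matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("n", 1:5))),
             target_copy = 0)
  y <- rnorm(n)
  X[, "target_copy"] <- y
  expect_true("target_copy" %in% lasso_select(X, y, 0.05)$selected)
  expect_true("target_copy" %in% rfe_select(X, y, k = 2)$selected)
  expect_true("target_copy" %in% kbest_select(X, y, k = 2)$selected)
  expect_error(rfe_select(X, y, k = 0), "0 < k < p")
  expect_error(kbest_select(X, y, k = 6), "0 < k < p")
})

test_that("pure-noise columns are selected near-uniformly", {
  p <- 8; k <- 2
  counts_kbest <- counts_rfe <- setNames(numeric(p), paste0("f", 1:p))
  for (s in 1:200) {
    set.seed(s + 7000)
    X <- matrix(rnorm(120 * p), 120, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    y <- rnorm(120)
    sk <- kbest_select(X, y, k)$selected
    sr <- rfe_select(X, y, k)$selected
    counts_kbest[sk] <- counts_kbest[sk] + 1
    counts_rfe[sr] <- counts_rfe[sr] + 1
  }
  # expected 200 * k / p = 50 selections per column; generous band
  expect_true(all(counts_kbest > 25 & counts_kbest < 80))
  expect_true(all(counts_rfe > 25 & counts_rfe < 80))
})

test_that("duplicated informative columns behave as documented", {
  set.seed(4)
  n <- 200
  x <- rnorm(n)
  X <- cbind(inf = x, twin = x, noise1 = rnorm(n), noise2 = rnorm(n),
             noise3 = rnorm(n), noise4 = rnorm(n))
  y <- 2 * x + rnorm(n, 0, 0.3)
  # kbest ranks both twins on top
  expect_setequal(kbest_select(X, y, 2)$selected, c("inf", "twin"))
  # rfe keeps at least one twin among the survivors
  expect_true(length(intersect(rfe_select(X, y, 2)$selected,
                               c("inf", "twin"))) >= 1)
  # lasso keeps the pair's total weight without inflating it
  sel <- lasso_select(X, y, 0.05)
  expect_lte(sum(sel$scores[c("inf", "twin")]), 2.3)
  expect_true(any(c("inf", "twin") %in% sel$selected))
})

test_that("model comparison shares folds and scores sanely", {
  w <- make_linear_world(n = 150, p = 5, k = 2, noise = 0, seed = 6)
  const_model <- list(fit = function(X, y) mean(y),
                      predict = function(obj, X) rep(obj, nrow(X)))
  scores <- compare_models_cv(
    w$X, w$y, models = list(ols = model_ols(), const = const_model),
    folds = 10, seed = 3)
  expect_equal(scores$mean_r2[scores$model == "ols"], 1, tolerance = 1e-9)
  expect_lte(scores$mean_r2[scores$model == "const"], 0.02)
  expect_error(compare_models_cv(w$X, w$y,
                                 models = list(ols = model_ols())),
               ">= 2 models")
})
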