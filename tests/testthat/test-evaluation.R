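test_that("Pearson correlation matches the closed forms", {
  y <- c(0, 0, 1, 1)
  expect_equal(pearson_r(y, y), 1)
  expect_equal(pearson_r(1 - y, y), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), y), sqrt(4 / 5), tolerance = 1e-12)
  expect_warning(r0 <- pearson_r(rep(2, 5), c(0, 1, 0, 1, 0)), "constant")
  expect_equal(r0, 0)
  expect_error(pearson_r(1:2, 0:1), "3 subjects")
})

test_that("AUC equals the normalised Mann-Whitney U on random draws", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(10:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    sc <- round(rnorm(n), sample(0:1, 1))  # ties included
    # pairwise enumeration oracle
    pos <- sc[y == 1]; neg <- sc[y == 0]
    u <- 0
    for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(auc_score(sc, y), u / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("AUC is antisymmetric under label flips and monotone-invariant", {
  set.seed(1)
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  sc <- rnorm(50)
  expect_equal(auc_score(sc, 1 - y), 1 - auc_score(sc, y))
  expect_equal(auc_score(exp(2 * sc) + 5, y), auc_score(sc, y))
})

test_that("stratified folds balance classes and cv_auc hits 1 on separable data", {
  set.seed(2)
  y <- rep(c(0, 1), c(30, 20))
  f <- stratified_folds(y, k = 10, seed = 3)
  expect_true(all(table(f, y)[, "1"] == 2))
  expect_true(all(table(f, y)[, "0"] == 3))
  x <- cbind(y + rnorm(50, sd = 0.01), rnorm(50))
  for (m in c("LR", "SVM", "DA", "KNN")) {
    r <- cv_auc(x, y, m, k = 5, seed = 1)
    expect_equal(r$mean_auc, 1)
    expect_equal(r$n_folds_used, 5)
  }
})

test_that("every registry model produces finite scores and learns a signal", {
  set.seed(3)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 4), n)
  x[, 1] <- x[, 1] + 1.5 * y
  for (m in names(model_registry())) {
    r <- suppressWarnings(cv_auc(x, y, m, k = 5, seed = 2))
    expect_true(is.finite(r$mean_auc), info = m)
    expect_gt(r$mean_auc, 0.6)
  }
})

test_that("label-independent features give null AUC for logistic regression", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rep(c(0, 1), each = 100)
    x <- matrix(rnorm(200 * 5), 200)
    suppressWarnings(cv_auc(x, y, "LR", k = 10, seed = s)$mean_auc)
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.10)
  expect_true(all(abs(aucs - 0.5) < 0.15))
})

test_that("benchmark reports conserve sets and flag selection optimism", {
  set.seed(4)
  y <- rep(c(0, 1), each = 20)
  x <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 1] <- x[, 1] + y
  sets <- list(one = x[, 1, drop = FALSE], all = x)
  r <- suppressWarnings(benchmark(sets, y, models = c("LR", "NB", "DT"),
                                  k = 5, seed = 1))
  expect_equal(dim(r$auc), c(3L, 2L))
  expect_equal(unname(r$best), unname(apply(r$auc, 2, max)))
  expect_equal(sum(r$folds$set == "one"), 3 * 5)
  expect_match(r$caveat, "selection optimism")
  r2 <- suppressWarnings(benchmark(sets, y, models = c("LR", "NB", "DT"),
                                   k = 5, seed = 1))
  expect_identical(r$auc, r2$auc)  # determinism
})

test_that("a fold whose test split lacks a class is skipped with a warning", {
  y <- c(rep(0, 18), rep(1, 2))
  x <- cbind(rnorm(20))
  expect_warning(r <- cv_auc(x, y, "NB", k = 4, seed = 1), "single class")
  expect_lt(r$n_folds_used, 4)
})
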