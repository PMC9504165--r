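test_that("range normalization follows the printed formula", {
  x <- cbind(a = c(0, 1), b = c(5, 5))
  expect_warning(n <- normalize_features(x), "constant")
  expect_equal(unname(n[, "a"]), c(-0.5, 0.5))
  expect_equal(unname(n[, "b"]), c(0, 0))
  x2 <- cbind(f = c(1, 2, 3, 6))
  n2 <- normalize_features(x2)
  expect_equal(unname(n2[, 1]), c(-0.4, -0.2, 0, 0.6))  # mean 3, range 5
  # every non-constant column: zero mean, value range exactly 1
  set.seed(1)
  x3 <- matrix(rnorm(20 * 8) * rep(10^(0:7), each = 20), 20)
  n3 <- normalize_features(x3)
  expect_equal(unname(colMeans(n3)), rep(0, 8))
  expect_equal(unname(apply(n3, 2, function(c) diff(range(c)))), rep(1, 8))
  # z-score variant
  nz <- normalize_features(x3, method = "zscore")
  expect_equal(unname(apply(nz, 2, sd)), rep(1, 8))
})

test_that("the Levene + t-test filter keeps signal and drops identical features", {
  set.seed(2)
  y <- rep(c(0, 1), each = 20)
  same <- rep(c(rnorm(20)), 2)  # identical in both groups
  signal <- y + rnorm(40, sd = 0.01)
  noise <- matrix(rnorm(40 * 5), 40)
  x <- cbind(same = same, signal = signal, noise)
  colnames(x) <- c("same", "signal", paste0("n", 1:5))
  res <- significance_filter(normalize_features(x), y)
  expect_true("signal" %in% res$selected)
  expect_false("same" %in% res$selected)
  expect_equal(res$t_p[["same"]], 1)
  expect_lt(res$t_p[["signal"]], 1e-6)
  # permutation oracle for the planted feature
  tstat <- function(v, g) {
    d <- mean(v[g == 1]) - mean(v[g == 0])
    d / sqrt(var(v[g == 1]) / 20 + var(v[g == 0]) / 20)
  }
  obs <- abs(tstat(signal, y))
  perm <- replicate(1e4, abs(tstat(signal, sample(y))))
  expect_lte(mean(perm >= obs), 1e-3)
  expect_error(significance_filter(x[c(1, 21, 22), ], c(0, 1, 1)), "2 subjects")
})

test_that("the filter agrees with stats::t.test under both variance regimes", {
  set.seed(3)
  y <- rep(c(0, 1), each = 15)
  x <- cbind(eqv = rnorm(30) + 0.8 * y,
             hetv = rnorm(30, sd = ifelse(y == 1, 3, 0.5)) + y)
  res <- significance_filter(x, y, alpha = 1)  # keep everything, compare p
  p_pool <- t.test(x[y == 1, "eqv"], x[y == 0, "eqv"], var.equal = TRUE)$p.value
  p_welch <- t.test(x[y == 1, "hetv"], x[y == 0, "hetv"])$p.value
  if (res$equal_var[["eqv"]])
    expect_equal(res$t_p[["eqv"]], p_pool, tolerance = 1e-12)
  expect_false(res$equal_var[["hetv"]])  # strong heteroscedasticity
  expect_equal(res$t_p[["hetv"]], p_welch, tolerance = 1e-12)
})

test_that("lowering alpha never enlarges the surviving set", {
  set.seed(4)
  y <- rep(c(0, 1), each = 12)
  x <- matrix(rnorm(24 * 60), 24,
              dimnames = list(NULL, paste0("f", 1:60)))
  x[, 1:5] <- x[, 1:5] + y
  prev <- NULL
  for (a in c(0.2, 0.1, 0.05, 0.01)) {
    cur <- significance_filter(x, y, alpha = a)$selected
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("Lasso recovers a planted feature and matches coordinate descent", {
  set.seed(5)
  n <- 60
  y <- rep(c(0, 1), length.out = n)
  x <- matrix(rnorm(n * 51), n)
  x[, 26] <- y  # planted: exactly the response
  colnames(x) <- paste0("f", 1:51)
  res <- lasso_select(x, y, seed = 7)
  expect_true("f26" %in% res$selected)
  # coordinate-descent oracle refit at the chosen penalty (glmnet scale)
  cd <- cd_lasso(x, y, res$lambda)
  sel_cd <- names(cd$beta)[abs(cd$beta) > 1e-8]
  expect_true("f26" %in% sel_cd)
  expect_equal(sort(res$selected), sort(sel_cd))
  common <- intersect(res$selected, sel_cd)
  expect_equal(res$coefficients[common], cd$beta[common], tolerance = 1e-4)
})

test_that("full shrinkage yields the empty selection and support shrinks along the path", {
  set.seed(6)
  n <- 40
  y <- rep(c(0, 1), each = 20)
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
  x[, 1] <- x[, 1] + 2 * y
  res_inf <- lasso_select(x, y, seed = 1, lambda_grid = c(1e6, 2e6))
  expect_length(res_inf$selected, 0)
  expect_warning(empty <- lasso_select(x[, 0], y), "empty candidate")
  expect_length(empty$selected, 0)
  # weakly decreasing support along an increasing lambda path
  fit <- glmnet::glmnet(x, y, lambda = sort(10^seq(-3, 1, length.out = 20),
                                            decreasing = TRUE),
                        standardize = FALSE)
  supp <- colSums(abs(as.matrix(fit$beta)) > 1e-8)
  expect_true(all(diff(rev(supp)) <= 1e-9 + 0))
})

test_that("experiment groups obey the combination algebra", {
  set.seed(7)
  n <- 40
  y <- rep(c(0, 1), each = 20)
  x <- matrix(rnorm(n * 40), n, dimnames = list(NULL, paste0("f", 1:40)))
  x[, 1:14] <- x[, 1:14] + y * rep(runif(14, 0.8, 1.6), each = n)
  sel <- endpoint_selection(x, y, seed = 3)
  g <- sel$groups
  expect_named(g$A, c("t_test", "lasso", "PCA", "ICA", "TSNE", "UMAP",
                      "ISOMAP"))
  nl <- length(sel$lasso$selected)
  for (m in c("PCA", "ICA", "TSNE", "UMAP", "ISOMAP")) {
    expect_equal(ncol(g$B[[paste0("lasso+", m)]]), nl + 10)
    cm <- g$C[[paste0(m, "_lasso")]]
    dm <- g$D[[paste0("lasso+", m, "_lasso")]]
    if (is.null(cm)) {
      expect_equal(ncol(dm), nl)  # empty group_C propagates to Lasso-only
    } else {
      expect_true(all(colnames(cm) %in% colnames(sel$reducers[[m]])))
      expect_equal(ncol(dm), nl + ncol(cm))
      expect_true(all(colnames(dm) %in%
                        c(sel$lasso$selected, colnames(cm))))
    }
    expect_true(all(sel$lasso$selected %in%
                      colnames(g$B[[paste0("lasso+", m)]])))
  }
  sets <- group_sets(g)
  expect_true(all(c("A.lasso", "B.lasso+PCA", "D.lasso+PCA_lasso") %in%
                    names(sets)))
})
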