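#' Normalize a feature matrix
#'
#' Range normalization `(x - mean) / (max - min)` per column (the printed
#' operational formula; every non-constant column ends up centred with value
#' range exactly 1). Constant columns are mapped to all zeros with a warning.
#' A z-score variant is available for sensitivity analyses.
#'
#' @param x Numeric matrix (subjects x features), >= 2 rows.
#' @param method `"range"` (default) or `"zscore"`.
#' @return The normalized matrix with attribute `norm_params` (per-column
#'   mean, max, min).
#' @export
normalize_features <- function(x, method = c("range", "zscore")) {
  method <- match.arg(method)
  stop_if_not(nrow(x) >= 2, "need at least 2 subjects")
  mu <- colMeans(x)
  mx <- apply(x, 2, max)
  mn <- apply(x, 2, min)
  den <- if (method == "range") mx - mn else apply(x, 2, sd)
  const <- den <= 0 | !is.finite(den)
  if (any(const))
    warning(sum(const), " constant feature column(s) normalized to zero")
  den[const] <- 1
  out <- sweep(sweep(x, 2, mu), 2, den, "/")
  out[, const] <- 0
  attr(out, "norm_params") <- list(mean = mu, max = mx, min = mn,
                                   method = method)
  out
}

# Vectorised two-group statistics for every column of x.
group_stats <- function(x, g1) {
  n1 <- sum(g1); n0 <- sum(!g1)
  x1 <- x[g1, , drop = FALSE]; x0 <- x[!g1, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2, m0)^2) / (n0 - 1)
  list(n1 = n1, n0 = n0, m1 = m1, m0 = m0, v1 = v1, v0 = v0, x1 = x1, x0 = x0)
}

#' Significance filter: Levene test then t-test per feature
#'
#' For every feature, the Brown-Forsythe (median-centred) Levene test decides
#' variance homogeneity across the two classes; homogeneous features get the
#' pooled-variance two-sample t-test, the rest the Welch t-test. Features with
#' two-sided t-test p below `alpha` survive. No multiple-testing correction is
#' applied (raw p < 0.05 is the operating rule); Benjamini-Hochberg can be
#' switched on for sensitivity analyses.
#'
#' @param x Normalized feature matrix (subjects x features).
#' @param labels Binary vector (both classes with >= 2 subjects).
#' @param alpha Significance level (default 0.05).
#' @param levene_alpha Homogeneity level for the Levene gate (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A list of class `significance_result`: `levene_p`, `equal_var`,
#'   `t_p`, `selected` (surviving feature names), `alpha`.
#' @export
significance_filter <- function(x, labels, alpha = 0.05,
                                levene_alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  g1 <- labels == 1
  stop_if_not(sum(g1) >= 2 && sum(!g1) >= 2,
              "both classes need at least 2 subjects")
  st <- group_stats(x, g1)
  n1 <- st$n1; n0 <- st$n0; N <- n1 + n0
  # Brown-Forsythe: one-way ANOVA F on |x - group median|
  z1 <- abs(sweep(st$x1, 2, apply(st$x1, 2, median)))
  z0 <- abs(sweep(st$x0, 2, apply(st$x0, 2, median)))
  zm1 <- colMeans(z1); zm0 <- colMeans(z0)
  zm <- (n1 * zm1 + n0 * zm0) / N
  ssb <- n1 * (zm1 - zm)^2 + n0 * (zm0 - zm)^2
  ssw <- colSums(sweep(z1, 2, zm1)^2) + colSums(sweep(z0, 2, zm0)^2)
  Fst <- ifelse(ssw > 0, (N - 2) * ssb / ssw, 0)
  levene_p <- pf(Fst, 1, N - 2, lower.tail = FALSE)
  levene_p[ssw == 0 & ssb == 0] <- 1
  equal_var <- levene_p >= levene_alpha
  # pooled t
  sp2 <- ((n1 - 1) * st$v1 + (n0 - 1) * st$v0) / (N - 2)
  se_p <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t_pooled <- ifelse(se_p > 0, (st$m1 - st$m0) / se_p, 0)
  p_pooled <- 2 * pt(abs(t_pooled), N - 2, lower.tail = FALSE)
  # Welch t
  se_w <- sqrt(st$v1 / n1 + st$v0 / n0)
  t_welch <- ifelse(se_w > 0, (st$m1 - st$m0) / se_w, 0)
  df_w <- ifelse(se_w > 0,
                 se_w^4 / ((st$v1 / n1)^2 / (n1 - 1) +
                             (st$v0 / n0)^2 / (n0 - 1)), N - 2)
  p_welch <- 2 * pt(abs(t_welch), df_w, lower.tail = FALSE)
  t_p <- ifelse(equal_var, p_pooled, p_welch)
  t_p[se_p == 0 & se_w == 0] <- 1  # identical in both groups
  if (adjust == "BH") t_p <- stats::p.adjust(t_p, "BH")
  keep <- t_p < alpha
  structure(list(levene_p = levene_p, equal_var = equal_var, t_p = t_p,
                 selected = colnames(x)[keep], alpha = alpha),
            class = "significance_result")
}

#' Lasso selection of outstanding features
#'
#' Minimises the L1-penalised squared loss
#' `sum_i (y_i - b0 - sum_j b_j x_ij)^2 + lambda * sum_j |b_j|` over a
#' 50-point logarithmic lambda grid in `[1e-4, 10]`, choosing lambda by
#' internal 10-fold cross-validation; features with coefficient magnitude
#' above 1e-8 at the chosen lambda form the selected ("outstanding") set.
#'
#' @param x Normalized feature matrix restricted to the significant features.
#' @param labels Binary response.
#' @param seed Seed for the internal CV fold assignment.
#' @param lambda_grid Penalty grid (descending order is handled internally).
#' @param nfolds Internal CV folds (default 10).
#' @return A list of class `selection_result`: `method`, `selected`,
#'   `coefficients` (named, selected features only), `lambda`.
#' @export
lasso_select <- function(x, labels, seed = 1L,
                         lambda_grid = 10^seq(log10(1e-4), log10(10),
                                              length.out = 50),
                         nfolds = 10) {
  if (is.null(dim(x)) || ncol(x) == 0) {
    warning("empty candidate set: Lasso selection returns no features")
    return(structure(list(method = "lasso", selected = character(0),
                          coefficients = numeric(0), lambda = NA_real_),
                     class = "selection_result"))
  }
  y <- as.numeric(labels)
  lam <- sort(lambda_grid, decreasing = TRUE)
  if (ncol(x) == 1) {
    # glmnet needs >= 2 columns; duplicate and halve the coefficient path
    xx <- cbind(x, x)
    fit <- glmnet::glmnet(xx, y, family = "gaussian", lambda = lam,
                          standardize = FALSE)
    cv_lam <- lam[which.min(colMeans((y - predict(fit, xx))^2))]
    b <- coef(fit, s = cv_lam)[-1]
    beta <- sum(b)
    sel <- abs(beta) > 1e-8
    return(structure(list(method = "lasso",
                          selected = colnames(x)[sel],
                          coefficients = setNames(beta[sel], colnames(x)[sel]),
                          lambda = cv_lam),
                     class = "selection_result"))
  }
  foldid <- with_seed(derive_seed(seed, "lasso_cv"),
                      sample(rep_len(seq_len(nfolds), length(y))))
  cv <- glmnet::cv.glmnet(x, y, family = "gaussian", lambda = lam,
                          standardize = FALSE, foldid = foldid)
  b <- as.numeric(coef(cv, s = "lambda.min"))[-1]
  sel <- abs(b) > 1e-8
  structure(list(method = "lasso", selected = colnames(x)[sel],
                 coefficients = setNames(b[sel], colnames(x)[sel]),
                 lambda = cv$lambda.min),
            class = "selection_result")
}

#' Assemble the four experimental groups of feature sets
#'
#' Group A holds the seven standalone sets (the significant-feature set, the
#' Lasso set, and the five reducer embeddings). Group B concatenates the Lasso
#' set with each reducer embedding. Group C re-runs Lasso on each reducer's 10
#' components. Group D concatenates the Lasso set with each group-C selection;
#' an empty group-C member makes the corresponding group-D set the Lasso set
#' alone (with a warning). `+` is column concatenation with de-duplication.
#'
#' @param x_ttest Normalized matrix restricted to the significant features.
#' @param lasso_res A `selection_result` from [lasso_select()] on `x_ttest`.
#' @param reducers Named list of subjects x 10 embeddings from
#'   [reduce_dimensions()].
#' @param labels Binary endpoint vector (used for the group-C Lasso runs).
#' @param seed Seed for the group-C Lasso CV.
#' @return A list of class `experiment_groups` with elements `A`, `B`, `C`,
#'   `D`, each a named list of feature matrices, plus `group_C_selected`
#'   (component names per reducer).
#' @export
build_groups <- function(x_ttest, lasso_res, reducers, labels, seed = 1L) {
  x_lasso <- x_ttest[, lasso_res$selected, drop = FALSE]
  A <- c(list(t_test = x_ttest, lasso = x_lasso), reducers)
  B <- lapply(reducers, function(r) cbind(x_lasso, r))
  names(B) <- paste0("lasso+", names(reducers))
  Csel <- list(); C <- list()
  for (m in names(reducers)) {
    r <- lasso_select(reducers[[m]], labels,
                      seed = derive_seed(seed, "groupC", m))
    Csel[[m]] <- r$selected
    if (length(r$selected) == 0) {
      warning("no ", m, " components survived the group-C Lasso")
      C[[paste0(m, "_lasso")]] <- NULL
    } else {
      C[[paste0(m, "_lasso")]] <- reducers[[m]][, r$selected, drop = FALSE]
    }
  }
  D <- list()
  for (m in names(reducers)) {
    cm <- C[[paste0(m, "_lasso")]]
    D[[paste0("lasso+", m, "_lasso")]] <-
      if (is.null(cm)) x_lasso else cbind(x_lasso, cm)
  }
  structure(list(A = A, B = B, C = C, D = D, group_C_selected = Csel),
            class = "experiment_groups")
}

#' Flatten experiment groups into one named list of feature sets
#'
#' @param groups An `experiment_groups` object.
#' @param which Which groups to include (subset of `c("A","B","C","D")`).
#' @return Named list of feature matrices; names are prefixed `A.`, `B.`, ...
#' @export
group_sets <- function(groups, which = c("A", "B", "C", "D")) {
  out <- list()
  for (g in which)
    for (nm in names(groups[[g]]))
      out[[paste0(g, ".", nm)]] <- groups[[g]][[nm]]
  out
}
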