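# Fold-safe evaluation: normalization, significance filtering, Lasso and the
# reducers are re-fitted inside each training fold, and held-out subjects are
# mapped through the trained transforms, so no label or distribution
# information leaks across folds.

# map test rows through a training-fold reducer. PCA/ICA are exact linear
# maps; the manifold methods (t-SNE, UMAP, Isomap) have no parametric
# out-of-sample extension and use k-NN barycentric interpolation of the
# training embedding (a standard heuristic).
oos_embed <- function(method, xtr, xte, emb, k = 5) {
  if (method %in% c("PCA", "ICA")) {
    # components are linear in the centred data: solve the map on train rows
    ctr <- colMeans(xtr)
    A <- cbind(1, sweep(xtr, 2, ctr))
    B <- qr.solve(qr(A, LAPACK = TRUE), emb)
    cbind(1, sweep(xte, 2, ctr)) %*% B
  } else {
    D <- as.matrix(dist(rbind(xte, xtr)))[seq_len(nrow(xte)),
                                          -seq_len(nrow(xte)), drop = FALSE]
    out <- matrix(0, nrow(xte), ncol(emb))
    for (i in seq_len(nrow(xte))) {
      nb <- order(D[i, ])[seq_len(min(k, ncol(D)))]
      w <- 1 / (D[i, nb] + 1e-8)
      out[i, ] <- colSums(emb[nb, , drop = FALSE] * w) / sum(w)
    }
    colnames(out) <- colnames(emb)
    out
  }
}

#' Fold-safe cross-validated benchmark
#'
#' The honest counterpart of [benchmark()]: for every fold, feature
#' normalization, the Levene + t-test filter, the Lasso selection and the
#' reducers are fitted on the training folds only, and the held-out subjects
#' are pushed through those trained transforms before scoring. Use this to
#' verify the null calibration of the evaluation harness.
#'
#' @param features Raw (unnormalized) subjects x features matrix.
#' @param labels Binary endpoint vector.
#' @param sets Which feature sets to score: `"lasso"` and/or reducer names.
#' @param models Model ids.
#' @param k Folds.
#' @param seed Seed.
#' @param alpha Significance level of the in-fold filter.
#' @param n_components Reducer output dimension.
#' @return A `benchmark_report` with `mode = "fold-safe"`.
#' @export
benchmark_fold_safe <- function(features, labels,
                                sets = c("lasso", "PCA", "ICA", "TSNE",
                                         "UMAP", "ISOMAP"),
                                models = names(model_registry()),
                                k = 10, seed = 0L, alpha = 0.05,
                                n_components = 10) {
  reg <- model_registry(models)
  fold <- stratified_folds(labels, k, seed)
  fold_auc <- array(NA_real_, c(length(reg), length(sets), k),
                    dimnames = list(names(reg), sets, NULL))
  red_names <- intersect(sets, c("PCA", "ICA", "TSNE", "UMAP", "ISOMAP"))
  for (f in seq_len(k)) {
    te <- fold == f
    if (length(unique(labels[te])) < 2) {
      warning("fold ", f, " has a single class in the test split; skipped")
      next
    }
    ytr <- labels[!te]; yte <- labels[te]
    xtr_raw <- features[!te, , drop = FALSE]
    xte_raw <- features[te, , drop = FALSE]
    # in-fold normalization (train statistics only)
    mu <- colMeans(xtr_raw)
    den <- apply(xtr_raw, 2, max) - apply(xtr_raw, 2, min)
    cz <- den <= 0; den[cz] <- 1
    xtr <- sweep(sweep(xtr_raw, 2, mu), 2, den, "/"); xtr[, cz] <- 0
    xte <- sweep(sweep(xte_raw, 2, mu), 2, den, "/"); xte[, cz] <- 0
    # in-fold significance filter (fall back to the 10 smallest p-values if
    # nothing survives, so downstream sets are never empty)
    sig <- suppressWarnings(significance_filter(xtr, ytr, alpha = alpha))
    keep <- sig$selected
    if (length(keep) == 0)
      keep <- colnames(xtr)[order(sig$t_p)[seq_len(min(10, ncol(xtr)))]]
    xtr_s <- xtr[, keep, drop = FALSE]
    xte_s <- xte[, keep, drop = FALSE]
    fold_sets_tr <- list(); fold_sets_te <- list()
    if ("lasso" %in% sets) {
      las <- suppressWarnings(
        lasso_select(xtr_s, ytr, seed = derive_seed(seed, "lasso", f)))
      if (length(las$selected)) {
        fold_sets_tr$lasso <- xtr_s[, las$selected, drop = FALSE]
        fold_sets_te$lasso <- xte_s[, las$selected, drop = FALSE]
      } else {
        fold_sets_tr$lasso <- NULL  # constant score below
        fold_sets_te$lasso <- NULL
      }
    }
    for (m in red_names) {
      emb <- reduce_dimensions(xtr_s, m, n_components,
                               seed = derive_seed(seed, "red", m))
      fold_sets_tr[[m]] <- emb
      fold_sets_te[[m]] <- oos_embed(m, xtr_s, xte_s, emb)
    }
    for (s in sets) {
      empty <- is.null(fold_sets_tr[[s]]) && s == "lasso"
      for (mn in names(reg)) {
        sc <- if (empty) rep(0, sum(te)) else {
          dc <- drop_constant(fold_sets_tr[[s]], fold_sets_te[[s]])
          if (is.null(dc)) rep(0, sum(te)) else {
            mfit <- reg[[mn]]$fit(dc$tr, ytr,
                                  derive_seed(seed, "fit", mn, s, f))
            reg[[mn]]$score(mfit, dc$te)
          }
        }
        fold_auc[mn, s, f] <- auc_score(sc, yte)
      }
    }
  }
  auc <- apply(fold_auc, c(1, 2), mean, na.rm = TRUE)
  folds <- do.call(rbind, lapply(seq_len(k), function(f) {
    data.frame(model = rep(rownames(auc), length(sets)),
               set = rep(colnames(auc), each = nrow(auc)),
               fold = f, auc = as.numeric(fold_auc[, , f]))
  }))
  structure(list(auc = auc, folds = folds,
                 best = apply(auc, 2, max, na.rm = TRUE),
                 mode = "fold-safe", caveat = NULL, seed = seed),
            class = "benchmark_report")
}
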