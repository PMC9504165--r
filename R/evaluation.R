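#' Pearson correlation between a feature and binary labels
#'
#' @param feature Numeric vector (>= 3 subjects).
#' @param labels Binary vector of the same length.
#' @return Correlation in `[-1, 1]`; a constant feature returns 0 with a
#'   warning.
#' @export
pearson_r <- function(feature, labels) {
  stop_if_not(length(feature) >= 3, "need at least 3 subjects")
  if (sd(feature) == 0 || sd(labels) == 0) {
    warning("constant input: Pearson correlation set to 0")
    return(0)
  }
  cor(feature, labels)
}

#' Area under the ROC curve of a score vector
#'
#' Computed as the normalised Mann-Whitney U statistic of the scores (ties
#' get average ranks, contributing 1/2).
#'
#' @param scores Continuous scores, higher = more positive.
#' @param labels Binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  stop_if_not(n1 > 0 && n0 > 0, "AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Seeded stratified k-fold assignment
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Seed.
#' @return Integer fold id per subject (1..k), stratified by class.
#' @export
stratified_folds <- function(labels, k = 10, seed = 0L) {
  fold <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# drop columns that are constant on the training rows (they break several
# fitters and carry no information)
drop_constant <- function(xtr, xte) {
  keep <- apply(xtr, 2, function(c) max(c) > min(c))
  if (!any(keep)) return(NULL)
  list(tr = xtr[, keep, drop = FALSE], te = xte[, keep, drop = FALSE])
}

# AdaBoost over decision stumps; the score is the weighted vote. Stumps are
# fitted by exhaustive threshold search with weighted-error cumsums.
best_stump <- function(x, yy, w, ords) {
  n <- nrow(x)
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    o <- ords[, j]
    xs <- x[o, j]
    wp <- cumsum(w[o] * (yy[o] == 1))   # positives at or below cut
    wn <- cumsum(w[o] * (yy[o] == -1))
    Wp <- wp[n]; Wn <- wn[n]
    valid <- which(xs[-n] < xs[-1])     # cuts between distinct values
    if (!length(valid)) next
    err_right_pos <- wp[valid] + (Wn - wn[valid])  # left -1 / right +1
    errs <- pmin(err_right_pos, 1 - err_right_pos)
    b <- which.min(errs)
    if (errs[b] < best$err)
      best <- list(err = errs[b], feature = j,
                   threshold = (xs[valid[b]] + xs[valid[b] + 1]) / 2,
                   polarity = if (err_right_pos[b] <= 1 - err_right_pos[b])
                     1 else -1)
  }
  best
}

fit_adaboost <- function(x, y, n_rounds = 50) {
  yy <- ifelse(y == 1, 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  ords <- apply(x, 2, order)
  stumps <- list()
  for (m in seq_len(n_rounds)) {
    st <- best_stump(x, yy, w, ords)
    if (!is.finite(st$err)) break
    pred <- st$polarity * ifelse(x[, st$feature] > st$threshold, 1, -1)
    err <- min(max(sum(w * (pred != yy)), 1e-10), 1 - 1e-10)
    st$alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- st
    if (err <= 1e-8) break
    w <- w * exp(-st$alpha * yy * pred)
    w <- w / sum(w)
  }
  list(stumps = stumps)
}

predict_adaboost <- function(model, x) {
  s <- rep(0, nrow(x))
  for (st in model$stumps)
    s <- s + st$alpha * st$polarity * ifelse(x[, st$feature] > st$threshold,
                                             1, -1)
  s
}

#' The ten-classifier model registry
#'
#' Radial-kernel SVM with probability outputs, decision tree, AdaBoost
#' (SAMME over stumps), single-hidden-layer neural network (size 8, weight
#' decay 0.01), random forest (200 trees), k-nearest neighbours (k = 5),
#' cross-validated ridge logistic regression, linear discriminant analysis,
#' gradient boosting (100 trees, depth 3, learning rate 0.1) and Gaussian
#' naive Bayes. Every model yields a continuous score usable for AUC.
#'
#' @param ids Model identifiers to return (default all ten).
#' @return Named list of model specs, each with `fit(x, y, seed)` and
#'   `score(model, x)` functions.
#' @export
model_registry <- function(ids = c("SVM", "DT", "Ada", "NN", "RF", "KNN",
                                   "LR", "DA", "GBDT", "NB")) {
  reg <- list(
    SVM = list(
      fit = function(x, y, seed) {
        with_seed(seed, e1071::svm(x, factor(y, levels = c(0, 1)),
                                   kernel = "radial", probability = TRUE))
      },
      score = function(m, x) {
        p <- attr(predict(m, x, probability = TRUE), "probabilities")
        p[, "1"]
      }),
    DT = list(
      fit = function(x, y, seed) {
        df <- data.frame(x, check.names = FALSE)
        names(df) <- paste0("V", seq_len(ncol(df)))
        df$.y <- factor(y, levels = c(0, 1))
        rpart::rpart(.y ~ ., data = df, method = "class")
      },
      score = function(m, x) {
        df <- data.frame(x, check.names = FALSE)
        names(df) <- paste0("V", seq_len(ncol(df)))
        predict(m, df, type = "prob")[, "1"]
      }),
    Ada = list(
      fit = function(x, y, seed) fit_adaboost(x, y),
      score = function(m, x) predict_adaboost(m, x)),
    NN = list(
      fit = function(x, y, seed) {
        with_seed(seed, nnet::nnet(x, as.numeric(y), size = 8, decay = 0.01,
                                   maxit = 200, entropy = TRUE, trace = FALSE,
                                   MaxNWts = 100000))
      },
      score = function(m, x) as.numeric(predict(m, x))),
    RF = list(
      fit = function(x, y, seed) {
        with_seed(seed,
                  randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                             ntree = 200))
      },
      score = function(m, x) predict(m, x, type = "prob")[, "1"]),
    KNN = list(
      fit = function(x, y, seed) list(x = x, y = factor(y, levels = c(0, 1))),
      score = function(m, x) {
        pred <- class::knn(m$x, x, m$y, k = min(5, nrow(m$x)), prob = TRUE)
        pr <- attr(pred, "prob")
        ifelse(pred == "1", pr, 1 - pr)
      }),
    LR = list(
      fit = function(x, y, seed) {
        if (ncol(x) < 2) {
          df <- data.frame(v = x[, 1], .y = y)
          structure(list(fit = glm(.y ~ v, df, family = binomial()),
                         type = "glm"), class = "lr_model")
        } else {
          foldid <- with_seed(derive_seed(seed, "lrcv"),
                              sample(rep_len(1:5, length(y))))
          structure(list(fit = glmnet::cv.glmnet(x, y, family = "binomial",
                                                 alpha = 0, foldid = foldid,
                                                 nlambda = 20),
                         type = "glmnet"), class = "lr_model")
        }
      },
      score = function(m, x) {
        if (m$type == "glm")
          as.numeric(predict(m$fit, data.frame(v = x[, 1]), type = "link"))
        else
          as.numeric(predict(m$fit, x, s = "lambda.min", type = "link"))
      }),
    DA = list(
      fit = function(x, y, seed) {
        tryCatch(MASS::lda(x, grouping = factor(y, levels = c(0, 1))),
                 error = function(e) NULL)
      },
      score = function(m, x) {
        if (is.null(m)) return(rep(0, nrow(x)))
        predict(m, x)$posterior[, "1"]
      }),
    GBDT = list(
      fit = function(x, y, seed) {
        dtr <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
        with_seed(seed,
                  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                                   max_depth = 3, eta = 0.1,
                                                   nthread = 1),
                                     data = dtr, nrounds = 100, verbose = 0))
      },
      score = function(m, x) predict(m, xgboost::xgb.DMatrix(x))),
    NB = list(
      fit = function(x, y, seed) {
        df <- data.frame(x, check.names = FALSE)
        names(df) <- paste0("V", seq_len(ncol(df)))
        e1071::naiveBayes(df, factor(y, levels = c(0, 1)))
      },
      score = function(m, x) {
        df <- data.frame(x, check.names = FALSE)
        names(df) <- paste0("V", seq_len(ncol(df)))
        p <- predict(m, df, type = "raw")[, "1"]
        p[!is.finite(p)] <- 0.5
        p
      })
  )
  reg[ids]
}

#' Cross-validated AUC for one feature set and one model
#'
#' Stratified seeded k-fold split; per fold the model is fitted on the
#' training folds and its continuous scores on the held-out subjects yield a
#' fold AUC. The mean over usable folds is returned (folds whose test split
#' has one class are skipped with a warning); `pooled = TRUE` instead pools
#' all held-out scores into a single AUC.
#'
#' @param x Feature matrix (subjects x columns).
#' @param labels Binary labels (each class should have at least `k` members
#'   for fully stratified folds).
#' @param model A single entry of [model_registry()], or a model id string.
#' @param k Folds (default 10).
#' @param seed Seed for folds and any model randomness.
#' @param pooled Pool held-out scores instead of averaging fold AUCs.
#' @return List with `mean_auc`, `fold_aucs`, `n_folds_used`.
#' @export
cv_auc <- function(x, labels, model, k = 10, seed = 0L, pooled = FALSE) {
  if (is.character(model)) model <- model_registry(model)[[1]]
  x <- as.matrix(x)
  fold <- stratified_folds(labels, k, seed)
  fold_aucs <- rep(NA_real_, k)
  scores_all <- rep(NA_real_, length(labels))
  for (f in seq_len(k)) {
    te <- fold == f
    if (length(unique(labels[te])) < 2 || sum(te) == 0) {
      warning("fold ", f, " has a single class in the test split; skipped")
      next
    }
    dc <- drop_constant(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    if (is.null(dc)) { sc <- rep(0, sum(te)) } else {
      m <- model$fit(dc$tr, labels[!te], derive_seed(seed, "fit", f))
      sc <- model$score(m, dc$te)
    }
    scores_all[te] <- sc
    fold_aucs[f] <- auc_score(sc, labels[te])
  }
  used <- !is.na(fold_aucs)
  if (!any(used)) stop("all folds skipped: cannot compute CV AUC",
                       call. = FALSE)
  mean_auc <- if (pooled)
    auc_score(scores_all[!is.na(scores_all)],
              labels[!is.na(scores_all)])
  else mean(fold_aucs[used])
  list(mean_auc = mean_auc, fold_aucs = fold_aucs, n_folds_used = sum(used))
}

#' Benchmark feature sets across the ten models
#'
#' Fills a models x feature-sets grid of 10-fold cross-validated AUCs, with
#' best-AUC summaries per set. The same stratified fold assignment is used in
#' every cell so sets and models are compared on identical splits. In
#' full-cohort mode (selection fitted on the full cohort before CV) the
#' report carries a selection-optimism caveat: with many (model, set) cells,
#' the best null AUC exceeds 0.5 systematically.
#'
#' @param sets Named list of feature matrices over the same subjects.
#' @param labels Binary endpoint vector.
#' @param models Model ids (default all ten).
#' @param k Folds.
#' @param seed Seed.
#' @param mode `"full-cohort"` (selection preceded CV) or `"fold-safe"`
#'   (labelling only; the fold-safe computation itself is
#'   [benchmark_fold_safe()]).
#' @param pooled Pool fold scores instead of averaging.
#' @return Object of class `benchmark_report`: `auc` (models x sets matrix),
#'   `folds` (long data.frame), `best` (per set), `mode`, `caveat`.
#' @export
benchmark <- function(sets, labels, models = names(model_registry()),
                      k = 10, seed = 0L, mode = "full-cohort",
                      pooled = FALSE) {
  reg <- model_registry(models)
  auc <- matrix(NA_real_, length(reg), length(sets),
                dimnames = list(names(reg), names(sets)))
  folds <- list()
  for (s in names(sets))
    for (m in names(reg)) {
      r <- cv_auc(sets[[s]], labels, reg[[m]], k = k,
                  seed = derive_seed(seed, "cell", m, s), pooled = pooled)
      auc[m, s] <- r$mean_auc
      folds[[paste(m, s)]] <- data.frame(model = m, set = s,
                                         fold = seq_along(r$fold_aucs),
                                         auc = r$fold_aucs)
    }
  best <- apply(auc, 2, max, na.rm = TRUE)
  caveat <- if (mode == "full-cohort")
    paste("selection preceded cross-validation (full-cohort mode):",
          "best-of-grid AUCs carry selection optimism and exceed 0.5",
          "on null data") else NULL
  structure(list(auc = auc, folds = do.call(rbind, folds), best = best,
                 mode = mode, caveat = caveat, seed = seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark (", x$mode, " mode), models x feature sets AUC:\n", sep = "")
  print(round(x$auc, 3))
  cat("\nBest AUC per set:\n")
  print(round(x$best, 3))
  if (!is.null(x$caveat)) cat("\nCaveat: ", x$caveat, "\n", sep = "")
  invisible(x)
}
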