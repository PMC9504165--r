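#!/usr/bin/env Rscript
# Stage 4: ten-model, ten-fold cross-validated AUC benchmark.
#
# Every feature set in groups A-D is scored by all ten classifiers on
# identical stratified folds (full-cohort mode: selection preceded CV, so
# the report carries the selection-optimism caveat). Grids go to
# results/report_<endpoint>.csv, fold-level AUCs to folds_<endpoint>.csv.

library(dynradiomics)

seed <- 1L
out <- "results"
features <- as.matrix(read.csv(file.path(out, "features.csv"),
                               check.names = FALSE)[, -1])
tab <- read.csv(file.path(out, "cohort.csv"))

endpoints <- c(stroke_detection = "stroke", nihss_evaluation = "impairment",
               outcome_prediction = "poor_outcome")
best <- list()
for (ep in names(endpoints)) {
  y <- tab[[endpoints[[ep]]]]
  if (min(table(y)) < 4) { cat(ep, ": class too small, skipped\n"); next }
  sel <- suppressWarnings(
    endpoint_selection(features, y, seed = derive_seed(seed, ep)))
  sets <- group_sets(sel$groups)
  rep_ <- suppressWarnings(
    benchmark(sets, y, k = 10, seed = derive_seed(seed, ep, "eval")))
  write.csv(data.frame(model = rownames(rep_$auc), rep_$auc,
                       check.names = FALSE),
            file.path(out, paste0("report_", ep, ".csv")), row.names = FALSE)
  write.csv(rep_$folds, file.path(out, paste0("folds_", ep, ".csv")),
            row.names = FALSE)
  best[[ep]] <- rep_$best
  cat("\n==", ep, "best AUC per feature set ==\n")
  print(round(rep_$best, 3))
  cat("caveat:", rep_$caveat, "\n")
}
jsonlite::write_json(lapply(best, as.list), file.path(out, "best_auc.json"),
                     auto_unbox = TRUE, digits = NA)
cat("\nwrote report_<endpoint>.csv, folds_<endpoint>.csv, best_auc.json\n")
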