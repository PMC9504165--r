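#!/usr/bin/env Rscript
# Stage 3: feature selection per endpoint.
#
# For each of the three endpoints: range normalization, the Levene + t-test
# significance filter (raw p < 0.05), Lasso selection of the outstanding DRF,
# the five 10-component reducer embeddings, and the group A-D assembly.
# Selected names, coefficients and Pearson correlations go to
# results/selection_<endpoint>.json.

library(dynradiomics)

seed <- 1L
out <- "results"
features <- as.matrix(read.csv(file.path(out, "features.csv"),
                               check.names = FALSE)[, -1])
tab <- read.csv(file.path(out, "cohort.csv"))

endpoints <- c(stroke_detection = "stroke", nihss_evaluation = "impairment",
               outcome_prediction = "poor_outcome")
for (ep in names(endpoints)) {
  y <- tab[[endpoints[[ep]]]]
  if (min(table(y)) < 2) { cat(ep, ": class too small, skipped\n"); next }
  sel <- suppressWarnings(
    endpoint_selection(features, y, seed = derive_seed(seed, ep)))
  rvals <- vapply(sel$lasso$selected, function(f)
    suppressWarnings(pearson_r(sel$normalized[, f], y)), 0)
  cat(sprintf("%s: %d significant DRF, %d outstanding (Lasso), |r| in [%.3f, %.3f]\n",
              ep, length(sel$significance$selected),
              length(sel$lasso$selected),
              if (length(rvals)) min(abs(rvals)) else NA,
              if (length(rvals)) max(abs(rvals)) else NA))
  jsonlite::write_json(
    list(endpoint = ep,
         n_significant = length(sel$significance$selected),
         lasso_selected = sel$lasso$selected,
         lasso_lambda = sel$lasso$lambda,
         group_C_selected = sel$groups$group_C_selected,
         pearson_r = as.list(rvals)),
    file.path(out, paste0("selection_", ep, ".json")),
    auto_unbox = TRUE, digits = NA)
}
cat("wrote selection_<endpoint>.json under", out, "\n")
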