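ENDPOINTS <- c(stroke_detection = "stroke",
               nihss_evaluation = "impairment",
               outcome_prediction = "poor_outcome")

#' Demo-scale extraction configuration
#'
#' The full 18-type x 6-family configuration is reserved for single-subject
#' runs; cohort-level experiments use all six feature families on the
#' original image type, sampled at every second timepoint (93 features x 25
#' timepoints per subject). This keeps the complete family roster — whose
#' texture-dominated composition is what separates supervised from
#' unsupervised selection — while bounding a 120-subject extraction at desk
#' scale.
#'
#' @param n_timepoints Length of the acquisition the subset refers to.
#' @return A [drf_config()].
#' @export
drf_config_demo <- function(n_timepoints = 50) {
  drf_config(image_types = "original",
             timepoints = seq(0, n_timepoints - 1, by = 2))
}

#' Run the per-endpoint selection cascade
#'
#' Normalization, Levene + t-test significance filter, Lasso selection of
#' outstanding features, the five reducer embeddings, and the group A-D
#' assembly, in the order the analysis prescribes (all fitted on the full
#' cohort: full-cohort mode).
#'
#' @param features Raw subjects x features matrix.
#' @param labels Binary endpoint vector.
#' @param alpha Significance level.
#' @param n_components Reducer output dimension.
#' @param seed Seed (reducer default seed 12 is derived per method).
#' @param reducer_seed Seed passed to the seeded reducers (default 12).
#' @return A list with `normalized`, `significance`, `lasso`, `reducers`,
#'   `groups`.
#' @export
endpoint_selection <- function(features, labels, alpha = 0.05,
                               n_components = 10, seed = 1L,
                               reducer_seed = 12L) {
  xn <- suppressWarnings(normalize_features(features))
  sig <- significance_filter(xn, labels, alpha = alpha)
  sel <- sig$selected
  if (length(sel) < n_components + 1) {
    warning("fewer than ", n_components + 1, " significant features; ",
            "using the ", n_components + 1, " smallest p-values")
    sel <- colnames(xn)[order(sig$t_p)[seq_len(n_components + 1)]]
  }
  x_t <- xn[, sel, drop = FALSE]
  las <- lasso_select(x_t, labels, seed = derive_seed(seed, "lasso"))
  reds <- reduce_all(x_t, n_components = n_components, seed = reducer_seed)
  groups <- suppressWarnings(
    build_groups(x_t, las, reds, labels, seed = derive_seed(seed, "groups")))
  list(normalized = xn, significance = sig, lasso = las, reducers = reds,
       groups = groups)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Default run configuration
#'
#' @param n_subjects,prevalence Cohort composition.
#' @param seed Master seed, fanned out deterministically to every stage.
#' @param acq Acquisition parameters (list passed to [acquisition_spec()]).
#' @param ranges Lesion ranges (list passed to [lesion_ranges()]).
#' @param extraction Extraction config (list passed to [drf_config()]), plus
#'   `smooth_passes`.
#' @param selection `alpha`, `n_components`, `reducer_seed`, `mode`.
#' @param evaluation `models`, `k`.
#' @param endpoints Endpoints to analyse.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 40, prevalence = 0.5, seed = 1L,
                       acq = list(), ranges = list(),
                       extraction = list(image_types = "original",
                                         families = c("firstorder", "glcm"),
                                         smooth_passes = 3),
                       selection = list(alpha = 0.05, n_components = 10,
                                        reducer_seed = 12,
                                        mode = "full-cohort"),
                       evaluation = list(models = c("SVM", "DT", "Ada", "NN",
                                                    "RF", "KNN", "LR", "DA",
                                                    "GBDT", "NB"), k = 10),
                       endpoints = names(ENDPOINTS)) {
  structure(list(n_subjects = n_subjects, prevalence = prevalence,
                 seed = seed, acq = acq, ranges = ranges,
                 extraction = extraction, selection = selection,
                 evaluation = evaluation, endpoints = endpoints),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are errors, not warnings.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, y)
}

#' Run the full pipeline: simulate, preprocess, extract, select, evaluate
#'
#' Executes every stage in order under a single master seed and writes all
#' artifacts (cohort table, DRF table, per-endpoint selection summaries and
#' AUC reports, run manifest with the config hash) under `out_dir`.
#' Deterministic: two runs with the same config produce identical reports.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_images Also write every subject as NIfTI (off by default:
#'   image volumes are large and reproducible from the seed).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `features`, `table`, per-endpoint results
#'   and the manifest.
#' @export
run_all <- function(config = run_config(), out_dir, write_images = FALSE,
                    verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  say <- function(...) if (verbose) message(...)
  acq <- do.call(acquisition_spec, config$acq)
  ranges <- do.call(lesion_ranges, config$ranges)
  ext <- config$extraction
  drfc <- drf_config(image_types = ext$image_types %||% "all",
                     families = ext$families %||% FAMILY_TAGS,
                     bin_width = ext$bin_width %||% 25)
  say("stage simulate+extract: ", config$n_subjects, " subjects")
  co <- extract_cohort(config$n_subjects, config$prevalence, acq, ranges,
                       seed = config$seed, config = drfc,
                       smooth_passes = ext$smooth_passes %||% 3)
  if (write_images) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    coh <- generate_cohort(config$n_subjects, config$prevalence, acq, ranges,
                           seed = config$seed)
    for (id in names(coh$subjects))
      write_subject(coh$subjects[[id]], file.path(img_dir, id))
  }
  tab <- co$table
  write.csv(cbind(tab, config_hash = hash),
            file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = rownames(co$features), co$features,
                       check.names = FALSE),
            file.path(out_dir, "features.csv"), row.names = FALSE)
  results <- list()
  for (ep in config$endpoints) {
    y <- tab[[ENDPOINTS[[ep]]]]
    if (length(unique(y)) < 2 || min(table(y)) < 2) {
      say("endpoint ", ep, ": a class has < 2 subjects; skipped")
      next
    }
    say("stage select+evaluate: ", ep)
    sel <- endpoint_selection(co$features, y,
                              alpha = config$selection$alpha %||% 0.05,
                              n_components = config$selection$n_components %||% 10,
                              seed = derive_seed(config$seed, ep),
                              reducer_seed = config$selection$reducer_seed %||% 12)
    sets <- group_sets(sel$groups)
    rep_ <- benchmark(sets, y, models = config$evaluation$models,
                      k = config$evaluation$k %||% 10,
                      seed = derive_seed(config$seed, ep, "eval"),
                      mode = config$selection$mode %||% "full-cohort")
    write.csv(data.frame(model = rownames(rep_$auc), rep_$auc,
                         check.names = FALSE),
              file.path(out_dir, paste0("report_", ep, ".csv")),
              row.names = FALSE)
    write.csv(rep_$folds, file.path(out_dir, paste0("folds_", ep, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(endpoint = ep,
           n_significant = length(sel$significance$selected),
           lasso_selected = sel$lasso$selected,
           lasso_coefficients = as.list(sel$lasso$coefficients),
           group_C_selected = sel$groups$group_C_selected,
           pearson_r_lasso = if (length(sel$lasso$selected))
             setNames(as.list(vapply(sel$lasso$selected, function(f)
               suppressWarnings(pearson_r(sel$normalized[, f], y)), 0)),
               sel$lasso$selected) else list()),
      file.path(out_dir, paste0("selection_", ep, ".json")),
      auto_unbox = TRUE, digits = NA)
    results[[ep]] <- list(selection = sel, report = rep_)
  }
  manifest <- list(config = unclass(config), config_hash = hash,
                   seed = config$seed,
                   mode = config$selection$mode %||% "full-cohort",
                   caveat = results[[1]]$report$caveat %||% NULL,
                   best_auc = lapply(results, function(r)
                     as.list(r$report$best)))
  jsonlite::write_json(manifest, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(list(features = co$features, table = tab, manifest = manifest),
              results))
}

#' Planted-signal cohort benchmark for one endpoint
#'
#' Generates a synthetic cohort, runs the selection cascade and scores the
#' Lasso set, each standalone reducer set and each group-D combination with
#' every model. Used to check that supervised selection dominates the
#' standalone reducer embeddings when a real lesion signal is present.
#'
#' @param seed Master seed.
#' @param n_subjects,prevalence Cohort composition.
#' @param acq,ranges Generator settings.
#' @param config Extraction configuration.
#' @param endpoint One of `"stroke"`, `"impairment"`, `"poor_outcome"`.
#' @param models Model ids.
#' @param k Folds.
#' @return List with `best` (best AUC per set), `auc` (full grid) and the
#'   selection object.
#' @export
benchmark_synthetic_cohort <- function(seed, n_subjects = 120,
                                       prevalence = 0.5,
                                       acq = acquisition_spec(),
                                       ranges = lesion_ranges(),
                                       config = drf_config_demo(),
                                       endpoint = "stroke",
                                       models = names(model_registry()),
                                       k = 10) {
  co <- extract_cohort(n_subjects, prevalence, acq, ranges, seed = seed,
                       config = config)
  y <- co$table[[endpoint]]
  sel <- endpoint_selection(co$features, y, seed = derive_seed(seed, "sel"))
  sets <- c(group_sets(sel$groups, "A")[paste0("A.", c("lasso", "PCA", "ICA",
                                                       "TSNE", "UMAP",
                                                       "ISOMAP"))],
            group_sets(sel$groups, "D"))
  rep_ <- benchmark(sets, y, models = models, k = k,
                    seed = derive_seed(seed, "eval"))
  list(best = rep_$best, auc = rep_$auc, selection = sel, table = co$table)
}
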