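FAMILY_TAGS <- c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")

family_feature_names <- function(family) {
  switch(family,
         firstorder = FIRSTORDER_NAMES,
         glcm = GLCM_NAMES,
         glrlm = GLRLM_NAMES,
         glszm = GLSZM_NAMES,
         gldm = GLDM_NAMES,
         ngtdm = NGTDM_NAMES)
}

#' Extraction configuration
#'
#' @param image_types Image types to compute; `"all"` expands to the full
#'   18-type bank of [image_type_names()].
#' @param families Feature families, a subset of
#'   `c("firstorder","glcm","glrlm","glszm","gldm","ngtdm")`.
#' @param log_sigmas LoG scales in mm.
#' @param bin_width Fixed discretization bin width (intensity units).
#' @param gldm_alpha GLDM dependence tolerance.
#' @param timepoints 0-based timepoint indices to extract (`NULL` = all).
#'   Feature names keep the original timepoint index.
#' @return A list of class `drf_config`.
#' @export
drf_config <- function(image_types = "all", families = FAMILY_TAGS,
                       log_sigmas = 1:5, bin_width = 25, gldm_alpha = 0,
                       timepoints = NULL) {
  if (identical(image_types, "all"))
    image_types <- image_type_names(log_sigmas)
  stop_if_not(all(families %in% FAMILY_TAGS), "unknown feature family")
  structure(list(image_types = image_types, families = families,
                 log_sigmas = log_sigmas, bin_width = bin_width,
                 gldm_alpha = gldm_alpha, timepoints = timepoints),
            class = "drf_config")
}

#' Number of features per timepoint for a configuration
#'
#' @param config A [drf_config()].
#' @return Integer count (1674 for the full configuration).
#' @export
n_features_per_timepoint <- function(config = drf_config()) {
  per_family <- vapply(config$families,
                       function(f) length(family_feature_names(f)), 0L)
  length(config$image_types) * sum(per_family)
}

extract_one_volume <- function(volume3d, mask, spacing, config) {
  bank <- filter_bank(volume3d, spacing, mask,
                      image_types = config$image_types,
                      log_sigmas = config$log_sigmas)
  vv <- prod(spacing)
  out <- numeric(0)
  for (ty in names(bank)) {
    img <- bank[[ty]]
    vals <- numeric(0)
    if ("firstorder" %in% config$families) {
      f <- first_order_features(img[mask], bin_width = config$bin_width,
                                voxel_volume = vv)
      vals <- c(vals, setNames(f, paste0("firstorder_", names(f))))
    }
    tex <- setdiff(config$families, "firstorder")
    if (length(tex)) {
      gray <- discretize(img, mask, config$bin_width)
      for (fam in tex) {
        f <- switch(fam,
                    glcm = glcm_features(gray),
                    glrlm = glrlm_features(gray),
                    glszm = glszm_features(gray),
                    gldm = gldm_features(gray, alpha = config$gldm_alpha),
                    ngtdm = ngtdm_features(gray))
        vals <- c(vals, setNames(f, paste0(fam, "_", names(f))))
      }
    }
    out <- c(out, setNames(vals, paste0(ty, "_", names(vals))))
  }
  out
}

#' Extract dynamic radiomics features for one subject
#'
#' Splits the 4D series into its N 3D timepoints, applies the filter bank to
#' each, computes every requested feature family on each image type, and
#' concatenates in time order. Features are named
#' `<imagetype>_<family>_<feature>_<n>` with `n` the 0-based timepoint index
#' (e.g. `log-sigma-1-0-mm-3D_firstorder_Skewness_17` is computed on the 17th
#' 3D image). With the full configuration this yields 1674 features per
#' timepoint and 83,700 for N = 50.
#'
#' @param volume4d Preprocessed 4D array (S x H x W x N).
#' @param mask Logical 3D brain mask (non-empty).
#' @param spacing Voxel size in mm.
#' @param config A [drf_config()].
#' @return Named numeric vector of length
#'   `N * n_features_per_timepoint(config)`.
#' @export
extract_drf <- function(volume4d, mask, spacing = c(1, 1, 1),
                        config = drf_config()) {
  d <- dim(volume4d)
  stop_if_not(length(d) == 4, "volume4d must be a 4D array")
  mask <- array(mask > 0, dim = d[1:3])
  if (!any(mask)) stop("empty mask", call. = FALSE)
  tps <- if (is.null(config$timepoints)) seq_len(d[4]) - 1L
         else as.integer(config$timepoints)
  stop_if_not(all(tps >= 0 & tps < d[4]), "timepoint index out of range")
  out <- vector("list", length(tps))
  for (ii in seq_along(tps)) {
    tt <- tps[ii]
    v <- extract_one_volume(volume4d[, , , tt + 1], mask, spacing, config)
    out[[ii]] <- setNames(v, paste0(names(v), "_", tt))
  }
  unlist(out)
}

#' Family tag of each DRF column name
#'
#' @param names Character vector of DRF names.
#' @return Factor of family tags.
#' @export
drf_family <- function(names) {
  m <- regmatches(names,
                  regexpr("(firstorder|glcm|glrlm|glszm|gldm|ngtdm)", names))
  factor(m, levels = FAMILY_TAGS)
}

#' Generate a cohort and extract its DRF table, one subject at a time
#'
#' Streams over the cohort plan of [generate_cohort()] (same seeds, lesions
#' and labels), generating, preprocessing and extracting each subject before
#' discarding its image, so memory stays bounded for large cohorts.
#'
#' @inheritParams generate_cohort
#' @param config A [drf_config()].
#' @param smooth_passes Temporal smoothing passes (default 3).
#' @param verbose Print a progress line per subject.
#' @return A list with `features` (subjects x features matrix) and `table`
#'   (the cohort label table).
#' @export
extract_cohort <- function(n_subjects, prevalence = 0.5,
                           acq = acquisition_spec(),
                           ranges = lesion_ranges(), seed = 1L,
                           config = drf_config(), smooth_passes = 3,
                           label_cfg = label_config(), verbose = FALSE) {
  plan <- cohort_plan(n_subjects, prevalence, acq, ranges, seed, label_cfg)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- plan[[i]]
    s <- generate_subject(acq, p$lesion, seed = p$seed, label_cfg = label_cfg)
    pp <- preprocess_subject(s, passes = smooth_passes)
    rows[[i]] <- extract_drf(pp$volume4d, pp$mask, s$spacing, config)
    if (verbose) message("extracted ", p$id, " (", i, "/", n_subjects, ")")
  }
  feats <- do.call(rbind, rows)
  rownames(feats) <- vapply(plan, `[[`, "", "id")
  list(features = feats, table = plan_table(plan))
}
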