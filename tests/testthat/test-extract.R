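small_subject <- function(seed = 1, lesion = NULL) {
  acq <- acquisition_spec(shape = c(8, 10, 10), n_timepoints = 21,
                          spacing = c(2, 1, 1))
  generate_subject(acq, lesion, seed = seed)
}

test_that("the full configuration yields 1674 uniquely named features per timepoint", {
  s <- small_subject()
  cfg <- drf_config(timepoints = c(0, 17))
  v <- extract_drf(s$volume4d, s$brain_mask, s$spacing, cfg)
  expect_length(v, 2 * 1674)
  expect_equal(anyDuplicated(names(v)), 0)
  expect_true(all(is.finite(v)))
  expect_equal(n_features_per_timepoint(drf_config()), 1674L)
  # family sizes per timepoint: counts x 18 image types
  fam <- table(drf_family(names(v)))
  expect_equal(unname(fam[c("firstorder", "glcm", "glrlm", "glszm", "gldm",
                            "ngtdm")]),
               2L * 18L * c(18L, 24L, 16L, 16L, 14L, 5L),
               ignore_attr = TRUE)
  # the DRF naming convention, with the timepoint index as suffix
  expect_true("log-sigma-1-0-mm-3D_firstorder_Skewness_17" %in% names(v))
  expect_true("wavelet-HHL_glszm_ZoneEntropy_0" %in% names(v))
})

test_that("the timepoint suffix indexes the source volume", {
  s <- small_subject()
  cfg <- drf_config(image_types = "original", families = "firstorder",
                    timepoints = 17)
  v <- extract_drf(s$volume4d, s$brain_mask, s$spacing, cfg)
  direct <- first_order_features(s$volume4d[, , , 18][s$brain_mask],
                                 voxel_volume = prod(s$spacing))
  expect_equal(unname(v), unname(direct))
  expect_identical(names(v), paste0("original_firstorder_",
                                    FIRSTORDER_NAMES, "_17"))
})

test_that("extraction is bit-reproducible and rejects bad inputs", {
  s <- small_subject()
  cfg <- drf_config(image_types = c("original", "wavelet-LLL"),
                    families = c("firstorder", "ngtdm"), timepoints = 0:2)
  v1 <- extract_drf(s$volume4d, s$brain_mask, s$spacing, cfg)
  v2 <- extract_drf(s$volume4d, s$brain_mask, s$spacing, cfg)
  expect_identical(v1, v2)
  expect_error(extract_drf(s$volume4d, array(FALSE, dim(s$brain_mask)),
                           s$spacing, cfg), "empty")
  expect_error(extract_drf(s$volume4d, s$brain_mask, s$spacing,
                           drf_config(timepoints = 99)), "out of range")
})

test_that("cohort extraction matches the per-subject path and its own plan", {
  acq <- acquisition_spec(shape = c(8, 10, 10), n_timepoints = 21)
  cfg <- drf_config(image_types = "original", families = "firstorder",
                    timepoints = c(0, 10, 20))
  co <- extract_cohort(6, 0.5, acq, seed = 4, config = cfg)
  expect_equal(dim(co$features), c(6L, 3L * 18L))
  expect_equal(sum(co$table$stroke), 3)
  # labels agree with generate_cohort under the same seed
  gc <- generate_cohort(6, 0.5, acq, seed = 4, keep_images = FALSE)
  expect_identical(co$table, gc$table)
  # features agree with manual generation of one subject
  s3 <- generate_subject(acq, seed = co$table$seed[3])
  pp <- preprocess_subject(s3)
  if (co$table$stroke[3] == 0) {
    v <- extract_drf(pp$volume4d, pp$mask, s3$spacing, cfg)
    expect_equal(unname(co$features[3, ]), unname(v))
  }
})
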