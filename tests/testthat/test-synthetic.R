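test_that("gamma-variate concentration has the analytic peak and boundary values", {
  kin <- bolus_kinetics(amplitude = 2, arrival = 5, shape = 3, scale = 1.5)
  expect_equal(bolus_concentration(kin$arrival, kin), 0)
  expect_equal(bolus_concentration(c(0, 2, 5), kin), c(0, 0, 0))
  kin0 <- bolus_kinetics(amplitude = 0)
  expect_equal(bolus_concentration(seq(0, 40, 0.5), kin0),
               rep(0, length(seq(0, 40, 0.5))))
  # grid-search oracle for the maximiser: t0 + alpha * beta
  tg <- seq(0, 40, 0.01)
  cv <- bolus_concentration(tg, kin)
  expect_true(all(is.finite(cv)) && all(cv >= 0))
  expect_equal(tg[which.max(cv)], kin$arrival + kin$shape * kin$scale,
               tolerance = 0.011)
})

test_that("signal time course is bounded by baseline and deepens with amplitude", {
  kin <- bolus_kinetics(amplitude = 1.2, arrival = 8)
  s <- signal_timecourse(100, kin, 50)
  expect_length(s, 50)
  expect_true(all(s <= 100 + 1e-12))
  expect_equal(s[1:8], rep(100, 8))  # before arrival C = 0
  expect_equal(signal_timecourse(50, bolus_kinetics(amplitude = 0), 30),
               rep(50, 30))
  k0 <- bolus_kinetics(); k0$coupling <- 0
  expect_equal(signal_timecourse(50, k0, 30), rep(50, 30))
  # doubling the amplitude strictly deepens the minimum (direct evaluation)
  kin2 <- bolus_kinetics(amplitude = 2.4, arrival = 8)
  expect_lt(min(signal_timecourse(100, kin2, 50)), min(s))
  expect_error(signal_timecourse(0, kin, 10), "S0")
  expect_error(bolus_kinetics(shape = -1), "shape")
  expect_error(bolus_kinetics(scale = 0), "scale")
})

test_that("subject generation is deterministic and respects the lesion contract", {
  acq <- acquisition_spec(shape = c(8, 16, 16), n_timepoints = 22)
  s1 <- generate_subject(acq, seed = 5)
  s2 <- generate_subject(acq, seed = 5)
  expect_identical(s1$volume4d, s2$volume4d)
  expect_identical(s1$labels, s2$labels)
  expect_false(any(s1$lesion_mask))
  expect_equal(s1$labels[["stroke"]], 0L)
  les <- lesion_spec(center = c(4, 8, 8), radii = c(2, 3, 3))
  sl <- generate_subject(acq, les, seed = 5)
  expect_true(any(sl$lesion_mask))
  expect_true(all(which(sl$lesion_mask) %in% which(sl$brain_mask)))
  expect_equal(sl$labels[["stroke"]], 1L)
  # lesion entirely outside the brain errors
  expect_error(generate_subject(acq, lesion_spec(c(1, 1, 1), c(0.5, 0.5, 0.5)),
                                seed = 5), "outside")
})

test_that("noise-free lesion tissue shows a strictly shallower mean signal drop", {
  acq <- acquisition_spec(shape = c(10, 20, 20), n_timepoints = 30,
                          noise_sd = 0)
  les <- lesion_spec(center = c(5, 10, 10), radii = c(2, 4, 4),
                     amplitude_factor = 0.3)
  s <- generate_subject(acq, les, seed = 3)
  lesvox <- s$lesion_mask
  normvox <- s$brain_mask & !s$lesion_mask
  lm <- apply(s$volume4d, 4, function(v) mean(v[lesvox]))
  nm <- apply(s$volume4d, 4, function(v) mean(v[normvox]))
  # compare relative drops (baselines differ by texture)
  expect_gt(min(lm / lm[1]), min(nm / nm[1]))
})

test_that("every voxel stays below baseline plus noise allowance", {
  acq <- acquisition_spec(shape = c(8, 16, 16), n_timepoints = 25,
                          noise_sd = 1.5)
  s <- generate_subject(acq, seed = 11)
  base <- s$volume4d[, , , 1]
  for (tt in c(5, 12, 20)) {
    dev <- s$volume4d[, , , tt] - base
    expect_true(all(dev[s$brain_mask] <= 5 * 2 * acq$noise_sd))
  }
})

test_that("label assignment follows the severity thresholds and couples outcome to stroke", {
  cfg <- label_config(nihss_noise = 0, mrs_noise = 0)
  expect_equal(unname(assign_labels(NULL, 1, cfg)), c(0L, 0L, 0L))
  big <- lesion_spec(c(5, 5, 5), c(2, 2, 2), severity = 10)
  expect_equal(unname(assign_labels(big, 1, cfg)), c(1L, 1L, 1L))
  # Monte-Carlo: P(poor | stroke) > P(poor | no stroke) over 1000 draws
  les <- lesion_spec(c(5, 5, 5), c(2, 2, 2), severity = 1)
  draws_s <- vapply(1:1000, function(i)
    assign_labels(les, i)[["poor_outcome"]], 0L)
  draws_n <- vapply(1:1000, function(i)
    assign_labels(NULL, i)[["poor_outcome"]], 0L)
  expect_gt(mean(draws_s), mean(draws_n))
})

test_that("cohorts hit the requested prevalence exactly and are reproducible", {
  acq <- acquisition_spec(shape = c(8, 16, 16), n_timepoints = 21)
  co <- generate_cohort(10, 0.5, acq, seed = 2, keep_images = FALSE)
  expect_equal(sum(co$table$stroke), 5)
  co0 <- generate_cohort(8, 0, acq, seed = 2, keep_images = FALSE)
  expect_equal(sum(co0$table$stroke), 0)
  # the study composition: 78 of 156 images stroke-positive
  co156 <- generate_cohort(156, 0.5, acq, seed = 9, keep_images = FALSE)
  expect_equal(sum(co156$table$stroke), 78)
  expect_equal(nrow(co156$table), 156)
  co156b <- generate_cohort(156, 0.5, acq, seed = 9, keep_images = FALSE)
  expect_identical(co156$table, co156b$table)
  expect_error(generate_cohort(3, 0.5, acq), "4 subjects")
})

test_that("NIfTI round trip preserves volumes, masks and spacing", {
  acq <- acquisition_spec(shape = c(8, 16, 16), n_timepoints = 21)
  s <- generate_subject(acq, lesion_spec(c(4, 8, 8), c(2, 3, 3)), seed = 4)
  pre <- file.path(tempdir(), "subj")
  write_subject(s, pre)
  r <- read_subject(pre)
  expect_equal(dim(r$volume4d), dim(s$volume4d))
  expect_equal(as.numeric(r$volume4d), as.numeric(s$volume4d),
               tolerance = 1e-6)
  expect_identical(which(r$brain_mask), which(s$brain_mask))
  expect_identical(which(r$lesion_mask), which(s$lesion_mask))
  expect_equal(unname(r$spacing), s$spacing, tolerance = 1e-6)
})
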