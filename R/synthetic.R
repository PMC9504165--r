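#' Acquisition specification for a synthetic DSC-PWI series
#'
#' Describes the geometry and noise of one simulated 4D acquisition. The
#' defaults mirror a routine DSC-PWI protocol (50 measurements, 5 mm slices)
#' at a grid size small enough for desk-scale experiments.
#'
#' @param shape Integer vector `(slices, height, width)`; every dimension must
#'   be at least 8.
#' @param n_timepoints Number of 3D measurements; at least 21 so the reference
#'   volume (first ten + last ten) is well defined.
#' @param spacing Voxel size in mm, `(slice, row, column)`.
#' @param baseline_intensity Pre-bolus signal level `S0` (arbitrary units).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param texture_sd Relative amplitude of the smooth spatial texture field
#'   multiplying the baseline (0 disables texture).
#' @param texture_scale Correlation length of the texture field, in voxels.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(shape = c(16L, 32L, 32L), n_timepoints = 50L,
                             spacing = c(5, 1.8, 1.8),
                             baseline_intensity = 100, noise_sd = 2,
                             texture_sd = 0.12, texture_scale = 3) {
  stop_if_not(length(shape) == 3 && all(shape >= 8),
              "all spatial dimensions must be >= 8")
  stop_if_not(n_timepoints >= 21,
              "n_timepoints must be >= 21 (reference volume needs disjoint first/last ten)")
  stop_if_not(all(spacing > 0), "spacing must be positive")
  stop_if_not(noise_sd >= 0, "noise_sd must be non-negative")
  stop_if_not(baseline_intensity > 0, "baseline_intensity must be positive")
  structure(list(shape = as.integer(shape),
                 n_timepoints = as.integer(n_timepoints),
                 spacing = as.numeric(spacing),
                 baseline_intensity = baseline_intensity,
                 noise_sd = noise_sd, texture_sd = texture_sd,
                 texture_scale = texture_scale),
            class = "acquisition_spec")
}

#' Gamma-variate bolus kinetics
#'
#' Parameters of the canonical gamma-variate concentration curve
#' `C(t) = A (t - t0)^alpha exp(-(t - t0)/beta)` for `t > t0` (0 otherwise),
#' whose peak sits at `t0 + alpha * beta`, together with the exponential
#' signal coupling `S(t) = S0 exp(-k C(t))` of DSC-MRI. The default coupling
#' `k` is scaled so the peak of `k * C` equals `A`, i.e. `A` is the peak
#' signal-attenuation exponent.
#'
#' Population kinetics vary between subjects (cardiac output, injection
#' timing and dispersion differ between patients): per subject the amplitude
#' and scale are multiplied by log-normal factors with coefficients of
#' variation `amplitude_cv` / `scale_cv` and the arrival is shifted by a
#' Gaussian with sd `arrival_sd`. Set these to zero for identical kinetics
#' across subjects.
#'
#' @param amplitude Dimensionless bolus amplitude `A >= 0`.
#' @param arrival Bolus arrival time `t0` (timepoint index, >= 0).
#' @param shape Gamma shape `alpha > 0`.
#' @param scale Gamma scale `beta > 0` (timepoints).
#' @param coupling Signal coupling `k > 0`; default normalises the peak.
#' @param amplitude_cv,arrival_sd,scale_cv Between-subject variability of the
#'   kinetic parameters.
#' @return An object of class `bolus_kinetics`.
#' @export
bolus_kinetics <- function(amplitude = 1.2, arrival = 8, shape = 3,
                           scale = 1.5, coupling = NULL,
                           amplitude_cv = 0.25, arrival_sd = 1.5,
                           scale_cv = 0.2) {
  stop_if_not(amplitude >= 0, "amplitude must be >= 0")
  stop_if_not(arrival >= 0, "arrival must be >= 0")
  stop_if_not(shape > 0, "shape must be positive")
  stop_if_not(scale > 0, "scale must be positive")
  if (is.null(coupling))  # peak of C is (alpha*beta)^alpha * exp(-alpha) * A
    coupling <- exp(shape) * (shape * scale)^(-shape)
  stop_if_not(coupling > 0, "coupling must be positive")
  structure(list(amplitude = amplitude, arrival = arrival, shape = shape,
                 scale = scale, coupling = coupling,
                 amplitude_cv = amplitude_cv, arrival_sd = arrival_sd,
                 scale_cv = scale_cv),
            class = "bolus_kinetics")
}

#' Lesion specification
#'
#' An ellipsoidal ischemic sub-region with an attenuated and slowed bolus
#' response: the intensity drop of ischemic tissue is shallower
#' (`amplitude_factor < 1`), later (`delay_shift > 0`) and more dispersed
#' (`dispersion_factor > 1`) than normal tissue.
#'
#' @param center Voxel coordinates of the lesion centre (length 3).
#' @param radii Ellipsoid semi-axes in voxels (length 3).
#' @param amplitude_factor Multiplier in `(0, 1]` on the bolus amplitude.
#' @param delay_shift Added bolus arrival delay in timepoints (>= 0).
#' @param dispersion_factor Multiplier `>= 1` on the gamma scale.
#' @param severity Dimensionless severity score `>= 0` driving the synthetic
#'   clinical labels.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radii, amplitude_factor = 0.4,
                        delay_shift = 2, dispersion_factor = 1.5,
                        severity = 1) {
  stop_if_not(amplitude_factor > 0 && amplitude_factor <= 1,
              "amplitude_factor must be in (0, 1]")
  stop_if_not(delay_shift >= 0, "delay_shift must be >= 0")
  stop_if_not(dispersion_factor >= 1, "dispersion_factor must be >= 1")
  stop_if_not(severity >= 0, "severity must be >= 0")
  stop_if_not(length(center) == 3 && length(radii) == 3 && all(radii > 0),
              "center and radii must be length-3, radii positive")
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 amplitude_factor = amplitude_factor,
                 delay_shift = delay_shift,
                 dispersion_factor = dispersion_factor, severity = severity),
            class = "lesion_spec")
}

#' Gamma-variate bolus concentration
#'
#' @param t Timepoints (numeric vector, >= 0).
#' @param kin A [bolus_kinetics()] object.
#' @return `C(t)`, zero for `t <= t0`, finite and non-negative.
#' @export
bolus_concentration <- function(t, kin) {
  stop_if_not(all(t >= 0), "t must be >= 0")
  dt <- t - kin$arrival
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- kin$amplitude * dt[pos]^kin$shape * exp(-dt[pos] / kin$scale)
  out
}

#' Bolus-attenuated signal time course
#'
#' DSC convention: contrast concentration lowers the measured signal,
#' `S(t) = S0 exp(-k C(t))`, so `S(t) <= S0` with equality where `C(t) = 0`.
#'
#' @param S0 Baseline intensity (> 0).
#' @param kin A [bolus_kinetics()] object.
#' @param n Number of timepoints (signal evaluated at `t = 0..n-1`).
#' @return Numeric vector of `n` intensities.
#' @export
signal_timecourse <- function(S0, kin, n) {
  stop_if_not(n >= 1, "n must be >= 1")
  stop_if_not(S0 > 0, "S0 must be positive")
  S0 * exp(-kin$coupling * bolus_concentration(seq_len(n) - 1, kin))
}

ellipsoid_mask <- function(shape, center, radii) {
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - center[a]) / radii[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  array(d2 <= 1, dim = shape)
}

# Smooth spatial texture: seeded white noise blurred with an isotropic
# Gaussian of `scale` voxels, rescaled to zero mean / unit sd over the grid.
texture_field <- function(shape, scale) {
  f <- array(rnorm(prod(shape)), dim = shape)
  k <- gaussian_kernel_1d(scale, 1)
  for (ax in 0:2)
    f <- conv_axis(f, k, axis = ax, mode = "replicate")
  (f - mean(f)) / max(sd(f), .Machine$double.eps)
}

#' Generate one synthetic DSC-PWI subject
#'
#' Builds an ellipsoidal brain inside the grid, multiplies the baseline by a
#' smooth seeded texture field, and lets every brain voxel follow a
#' gamma-variate bolus with voxel-jittered kinetics. Lesion voxels respond
#' with attenuated amplitude, delayed arrival and dispersed scale. Additive
#' Gaussian noise completes the measurement model. Fully deterministic for a
#' fixed seed.
#'
#' @param acq An [acquisition_spec()].
#' @param lesion A [lesion_spec()] or `NULL` for a lesion-free subject.
#' @param seed Integer seed.
#' @param kin A [bolus_kinetics()] object (population-level kinetics).
#' @param label_cfg A [label_config()] controlling the synthetic clinical
#'   labels.
#' @return An object of class `synthetic_subject` with elements `volume4d`
#'   (S x H x W x N array), `brain_mask`, `lesion_mask`, `labels`
#'   (named binary vector: stroke, impairment, poor_outcome), `spacing`,
#'   `acq`, `lesion`, `seed`.
#' @export
generate_subject <- function(acq = acquisition_spec(), lesion = NULL,
                             seed = 1L, kin = bolus_kinetics(),
                             label_cfg = label_config()) {
  shp <- acq$shape
  n <- acq$n_timepoints
  brain <- ellipsoid_mask(shp, (shp + 1) / 2, (shp - 2) / 2)
  lesion_mask <- array(FALSE, dim = shp)
  if (!is.null(lesion)) {
    lesion_mask <- ellipsoid_mask(shp, lesion$center, lesion$radii) & brain
    if (!any(lesion_mask))
      stop("lesion ellipsoid lies entirely outside the brain mask",
           call. = FALSE)
  }
  with_seed(seed, {
    # between-subject kinetic and baseline variability
    subj_A <- kin$amplitude * exp(rnorm(1, sd = kin$amplitude_cv) -
                                    kin$amplitude_cv^2 / 2)
    subj_t0 <- max(kin$arrival + rnorm(1, sd = kin$arrival_sd), 0)
    subj_beta <- kin$scale * exp(rnorm(1, sd = kin$scale_cv) -
                                   kin$scale_cv^2 / 2)
    subj_S0 <- acq$baseline_intensity * exp(rnorm(1, sd = 0.1) - 0.005)
    tex <- texture_field(shp, acq$texture_scale)
    baseline <- subj_S0 * pmax(1 + acq$texture_sd * tex, 0.1)
    nvox <- sum(brain)
    idx <- which(brain)
    les <- lesion_mask[brain]  # lesion flag per brain voxel
    # voxel-jittered kinetics around the subject-level values
    A <- subj_A * pmax(1 + 0.1 * rnorm(nvox), 0.05)
    t0 <- pmax(subj_t0 + 0.5 * rnorm(nvox), 0)
    beta <- subj_beta * pmax(1 + 0.1 * rnorm(nvox), 0.2)
    if (!is.null(lesion)) {
      A[les] <- A[les] * lesion$amplitude_factor
      t0[les] <- t0[les] + lesion$delay_shift
      beta[les] <- beta[les] * lesion$dispersion_factor
    }
    tgrid <- matrix(0:(n - 1), nvox, n, byrow = TRUE)
    dt <- tgrid - t0
    C <- array(0, dim(dt))
    pos <- dt > 0
    C[pos] <- (A * (dt^kin$shape))[pos] * exp(-dt / beta)[pos]
    sig <- baseline[idx] * exp(-kin$coupling * C)
    vol <- array(rep(baseline, n), dim = c(shp, n))
    for (tt in seq_len(n)) {
      v3 <- vol[, , , tt]
      v3[idx] <- sig[, tt]
      vol[, , , tt] <- v3
    }
    if (acq$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), sd = acq$noise_sd), dim = dim(vol))
    labels <- assign_labels(lesion, noise_seed = derive_seed(seed, "labels"),
                            thresholds = label_cfg)
    structure(list(volume4d = vol, brain_mask = brain,
                   lesion_mask = lesion_mask, labels = labels,
                   spacing = acq$spacing, acq = acq, lesion = lesion,
                   seed = seed),
              class = "synthetic_subject")
  })
}

#' Label-generation configuration
#'
#' Monotone noisy transforms mapping latent lesion severity to a synthetic
#' NIHSS (neurological impairment = NIHSS > 0) and a synthetic 90-day mRS
#' (poor outcome = mRS > 2). Scales and noise levels control how strongly the
#' clinical labels correlate with lesion presence and severity.
#'
#' The defaults are calibrated so that, at the default severity range and 50%
#' lesion prevalence, the cohort marginals approximate the study's ground
#' truth distribution (about half the cohort stroke-positive, roughly 40%
#' impaired and 35% with a poor outcome).
#'
#' @param nihss_scale,nihss_offset,nihss_noise Slope, offset and Gaussian
#'   noise of the synthetic NIHSS score.
#' @param mrs_scale,mrs_offset,mrs_noise Slope, offset and noise of the
#'   synthetic mRS score.
#' @return A list of class `label_config`.
#' @export
label_config <- function(nihss_scale = 4.5, nihss_offset = -2,
                         nihss_noise = 1.5,
                         mrs_scale = 3.2, mrs_offset = -0.4, mrs_noise = 0.8) {
  structure(list(nihss_scale = nihss_scale, nihss_offset = nihss_offset,
                 nihss_noise = nihss_noise,
                 mrs_scale = mrs_scale, mrs_offset = mrs_offset,
                 mrs_noise = mrs_noise),
            class = "label_config")
}

#' Assign the three binary endpoint labels
#'
#' `stroke` is 1 iff a lesion is present. A latent severity score (lesion
#' severity plus noise) is mapped to a synthetic NIHSS in 0..42 (impairment =
#' NIHSS > 0) and a synthetic mRS in 0..6 (poor outcome = mRS > 2).
#'
#' @param lesion A [lesion_spec()] or `NULL`.
#' @param noise_seed Integer seed for the label noise.
#' @param thresholds A [label_config()].
#' @return Named integer vector `(stroke, impairment, poor_outcome)`.
#' @export
assign_labels <- function(lesion = NULL, noise_seed = 1L,
                          thresholds = label_config()) {
  sev <- if (is.null(lesion)) 0 else lesion$severity
  with_seed(noise_seed, {
    nihss <- round(sev * thresholds$nihss_scale + thresholds$nihss_offset +
                     rnorm(1, sd = thresholds$nihss_noise))
    mrs <- round(sev * thresholds$mrs_scale + thresholds$mrs_offset +
                   rnorm(1, sd = thresholds$mrs_noise))
    nihss <- min(max(nihss, 0), 42)
    mrs <- min(max(mrs, 0), 6)
    c(stroke = as.integer(!is.null(lesion)),
      impairment = as.integer(nihss > 0),
      poor_outcome = as.integer(mrs > 2))
  })
}

#' Ranges for per-subject lesion sampling
#'
#' Each element may be a single value (held fixed) or a length-2 range sampled
#' uniformly per subject. `radii_frac` is the lesion semi-axis as a fraction
#' of the brain semi-axis.
#'
#' @param radii_frac,amplitude_factor,delay_shift,dispersion_factor,severity
#'   Scalars or `(min, max)` ranges.
#' @return A list of class `lesion_ranges`.
#' @export
lesion_ranges <- function(radii_frac = c(0.2, 0.35), amplitude_factor = 0.4,
                          delay_shift = c(1, 3), dispersion_factor = c(1.2, 1.8),
                          severity = c(0.4, 2)) {
  structure(list(radii_frac = radii_frac, amplitude_factor = amplitude_factor,
                 delay_shift = delay_shift,
                 dispersion_factor = dispersion_factor, severity = severity),
            class = "lesion_ranges")
}

sample_range <- function(r) if (length(r) == 1) r else runif(1, r[1], r[2])

# Deterministic per-subject plan (lesion specs, seeds, labels) shared by
# generate_cohort() and extract_cohort() so both agree on every subject.
cohort_plan <- function(n_subjects, prevalence, acq, ranges, seed,
                        label_cfg = label_config()) {
  stop_if_not(n_subjects >= 4, "need at least 4 subjects to cross-validate")
  stop_if_not(prevalence >= 0 && prevalence <= 1,
              "prevalence must be in [0, 1]")
  n_les <- round(n_subjects * prevalence)
  with_seed(derive_seed(seed, "plan"), {
    has_lesion <- rep(FALSE, n_subjects)
    has_lesion[sample.int(n_subjects, n_les)] <- TRUE
    shp <- acq$shape
    brad <- (shp - 2) / 2
    plan <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      lesion <- NULL
      if (has_lesion[i]) {
        rf <- sample_range(ranges$radii_frac)
        radii <- pmax(rf * brad, 1.5)
        # centre placed so the ellipsoid stays well inside the brain
        ctr <- (shp + 1) / 2 + (runif(3, -0.5, 0.5)) * (brad - radii)
        lesion <- lesion_spec(center = ctr, radii = radii,
                              amplitude_factor = sample_range(ranges$amplitude_factor),
                              delay_shift = sample_range(ranges$delay_shift),
                              dispersion_factor = sample_range(ranges$dispersion_factor),
                              severity = sample_range(ranges$severity))
      }
      sseed <- derive_seed(seed, "subject", i)
      plan[[i]] <- list(id = sprintf("S%03d", i), lesion = lesion,
                        seed = sseed,
                        labels = assign_labels(lesion,
                                               derive_seed(sseed, "labels"),
                                               label_cfg))
    }
    plan
  })
}

plan_table <- function(plan) {
  data.frame(subject_id = vapply(plan, `[[`, "", "id"),
             stroke = vapply(plan, function(p) p$labels[["stroke"]], 0L),
             impairment = vapply(plan, function(p) p$labels[["impairment"]], 0L),
             poor_outcome = vapply(plan, function(p) p$labels[["poor_outcome"]], 0L),
             seed = vapply(plan, function(p) as.integer(p$seed), 0L),
             stringsAsFactors = FALSE)
}

#' Generate a seeded cohort of synthetic subjects
#'
#' Exactly `round(n_subjects * prevalence)` subjects carry lesions; per-subject
#' seeds are derived deterministically from the master seed.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param prevalence Fraction of lesion-positive subjects in `[0, 1]`.
#' @param acq An [acquisition_spec()] shared by all subjects.
#' @param ranges A [lesion_ranges()] object.
#' @param seed Integer master seed.
#' @param keep_images If `FALSE`, subject image arrays are dropped (labels and
#'   masks kept), which bounds memory for large cohorts.
#' @param label_cfg A [label_config()].
#' @return A list with `subjects` (list of `synthetic_subject`) and `table`
#'   (one row per subject: subject_id, stroke, impairment, poor_outcome, seed).
#' @export
generate_cohort <- function(n_subjects, prevalence = 0.5,
                            acq = acquisition_spec(),
                            ranges = lesion_ranges(), seed = 1L,
                            keep_images = TRUE, label_cfg = label_config()) {
  plan <- cohort_plan(n_subjects, prevalence, acq, ranges, seed, label_cfg)
  subjects <- lapply(plan, function(p) {
    s <- generate_subject(acq, p$lesion, seed = p$seed, label_cfg = label_cfg)
    if (!keep_images) s$volume4d <- NULL
    s
  })
  names(subjects) <- vapply(plan, `[[`, "", "id")
  list(subjects = subjects, table = plan_table(plan))
}

#' Write a synthetic subject as NIfTI files
#'
#' Writes the 4D image plus 3D brain and lesion masks with the subject's voxel
#' spacing in the headers.
#'
#' @param subject A `synthetic_subject`.
#' @param prefix Output path prefix; files `<prefix>.nii.gz`,
#'   `<prefix>_brainmask.nii.gz`, `<prefix>_lesionmask.nii.gz` are created.
#' @return Invisibly, the three file paths.
#' @export
write_subject <- function(subject, prefix) {
  sp <- subject$spacing
  img <- RNifti::asNifti(subject$volume4d)
  RNifti::pixdim(img) <- c(sp, 1)
  bm <- RNifti::asNifti(subject$brain_mask * 1L)
  RNifti::pixdim(bm) <- sp
  lm <- RNifti::asNifti(subject$lesion_mask * 1L)
  RNifti::pixdim(lm) <- sp
  paths <- paste0(prefix, c(".nii.gz", "_brainmask.nii.gz",
                            "_lesionmask.nii.gz"))
  RNifti::writeNifti(img, paths[1])
  RNifti::writeNifti(bm, paths[2])
  RNifti::writeNifti(lm, paths[3])
  invisible(paths)
}

#' Read a subject written by [write_subject()]
#'
#' @param prefix Path prefix used at write time.
#' @return A list with `volume4d`, `brain_mask`, `lesion_mask`, `spacing`.
#' @export
read_subject <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  sp <- RNifti::pixdim(img)[1:3]
  list(volume4d = unclass(img)[, , , , drop = FALSE],
       brain_mask = unclass(RNifti::readNifti(
         paste0(prefix, "_brainmask.nii.gz"))) > 0,
       lesion_mask = unclass(RNifti::readNifti(
         paste0(prefix, "_lesionmask.nii.gz"))) > 0,
       spacing = sp)
}
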