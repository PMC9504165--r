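#' Triple moving-average temporal smoothing
#'
#' Smooths each voxel's time course independently with a centred window-3
#' moving average applied `passes` successive times (default three — the
#' "triple" moving average), using replicate-edge padding so the number of
#' timepoints is preserved. Each pass is a contraction: the per-voxel temporal
#' variance never increases.
#'
#' @param volume4d 4D array (S x H x W x N) with N >= 3.
#' @param passes Number of successive passes (default 3).
#' @return The smoothed 4D array, same shape.
#' @export
temporal_smooth <- function(volume4d, passes = 3) {
  d <- dim(volume4d)
  stop_if_not(length(d) == 4, "volume4d must be a 4D array")
  n <- d[4]
  stop_if_not(n >= 3, "temporal smoothing needs at least 3 timepoints")
  # one window-3 replicate-edge pass per iteration, along the time axis
  x <- volume4d
  dim(x) <- c(prod(d[1:3]), n, 1L)
  for (p in seq_len(passes))
    x <- conv_axis(x, c(1, 1, 1) / 3, axis = 1, mode = "replicate")
  array(x, dim = d)
}

#' Reference volume from the bolus-free tails
#'
#' Voxel-wise arithmetic mean of exactly twenty volumes: the first ten and the
#' last ten timepoints, which bracket the bolus passage.
#'
#' @param volume4d 4D array with at least 21 timepoints (so the two blocks of
#'   ten do not overlap).
#' @return A 3D array with the input's spatial shape.
#' @export
reference_volume <- function(volume4d) {
  d <- dim(volume4d)
  stop_if_not(length(d) == 4, "volume4d must be a 4D array")
  n <- d[4]
  if (n < 21)
    stop("reference volume requires >= 21 timepoints: the mean is taken over ",
         "the first ten and the last ten 3D images, which must not overlap",
         call. = FALSE)
  sel <- c(1:10, (n - 9):n)
  out <- array(0, d[1:3])
  for (tt in sel) out <- out + volume4d[, , , tt]
  out / 20
}

#' Restrict a 4D series to the brain mask
#'
#' Marks non-brain voxels as `NA` at every timepoint so that downstream
#' statistics see only brain tissue. Feature extraction itself takes the mask
#' directly; this helper is the explicit masking contract.
#'
#' @param volume4d 4D array.
#' @param mask Logical (or 0/1) 3D array matching the spatial shape.
#' @return The 4D array with non-brain voxels set to `NA`, with the mask
#'   attached as attribute `mask`.
#' @export
apply_brain_mask <- function(volume4d, mask) {
  d <- dim(volume4d)
  stop_if_not(length(d) == 4, "volume4d must be a 4D array")
  mask <- array(mask > 0, dim = dim(mask))
  stop_if_not(identical(dim(mask), d[1:3]),
              "mask spatial shape must match the image")
  if (!any(mask)) stop("brain mask is empty", call. = FALSE)
  out <- volume4d
  out[array(!mask, dim = d)] <- NA_real_
  attr(out, "mask") <- mask
  out
}

#' Preprocess one subject
#'
#' Applies temporal smoothing, computes the reference volume from the smoothed
#' series, and records provenance.
#'
#' @param subject A `synthetic_subject` or any list with `volume4d` and
#'   `brain_mask`.
#' @param passes Smoothing passes (default 3).
#' @return A list with `volume4d` (smoothed), `reference`, `mask`,
#'   `provenance`.
#' @export
preprocess_subject <- function(subject, passes = 3) {
  sm <- temporal_smooth(subject$volume4d, passes = passes)
  list(volume4d = sm, reference = reference_volume(sm),
       mask = subject$brain_mask,
       spacing = subject$spacing,
       provenance = list(smooth_passes = passes, reference_volumes = 20L))
}
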