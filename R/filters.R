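# One-level coiflet-1 analysis filters (orthogonal; the high-pass is the
# quadrature mirror of the low-pass and sums to zero, so detail sub-bands of a
# constant image vanish).
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
              0.3848648468648578, 0.8525720202116004,
              0.3378976624574818, -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818,
              -0.8525720202116004, 0.3848648468648578,
              0.07273261951252645, -0.015655728135791993)

gaussian_kernel_1d <- function(sigma, spacing) {
  r <- max(1L, as.integer(ceiling(3 * sigma / spacing)))
  x <- (-r:r) * spacing
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Convolve a 3D array along one axis (0-based axis index in C++; R-facing
# axis is 1..3). mode "replicate" or "periodic".
conv_axis <- function(vol, kernel, axis, mode = c("replicate", "periodic"),
                      origin = NULL) {
  mode <- match.arg(mode)
  if (is.null(origin)) origin <- (length(kernel) - 1L) %/% 2L
  d <- dim(vol)
  out <- cpp_conv_axis(as.numeric(vol), as.integer(d), as.numeric(kernel),
                       as.integer(axis), as.integer(mode == "periodic"),
                       as.integer(origin))
  array(out, dim = d)
}

gaussian_smooth3d <- function(vol, spacing, sigma) {
  for (ax in 0:2)
    vol <- conv_axis(vol, gaussian_kernel_1d(sigma, spacing[ax + 1]), ax)
  vol
}

laplacian3d <- function(vol, spacing) {
  out <- array(0, dim(vol))
  for (ax in 0:2)
    out <- out + conv_axis(vol, c(1, -2, 1) / spacing[ax + 1]^2, ax)
  out
}

# Scale-normalised Laplacian of Gaussian: sigma^2 * Laplacian(Gaussian(vol)).
log_filter <- function(vol, spacing, sigma) {
  sigma^2 * laplacian3d(gaussian_smooth3d(vol, spacing, sigma), spacing)
}

# One-level undecimated separable 3D wavelet decomposition into 8 sub-bands
# (periodic padding), named by the filter applied along each axis
# (L = low-pass, H = high-pass; axis order slice, row, column).
wavelet_bank <- function(vol, lo = COIF1_LO, hi = COIF1_HI) {
  bands <- list(L = conv_axis(vol, lo, 0, "periodic"),
                H = conv_axis(vol, hi, 0, "periodic"))
  for (ax in 1:2) {
    nxt <- list()
    for (nm in names(bands)) {
      nxt[[paste0(nm, "L")]] <- conv_axis(bands[[nm]], lo, ax, "periodic")
      nxt[[paste0(nm, "H")]] <- conv_axis(bands[[nm]], hi, ax, "periodic")
    }
    bands <- nxt
  }
  order <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bands[order]
}

# Range-preserving intensity remaps (standard radiomics derived images). All
# scale factors come from the masked intensities; a constant-zero region makes
# the factors undefined, in which case the image is returned unchanged with a
# warning.
remap_image <- function(vol, mask, type) {
  m <- max(abs(vol[mask]))
  if (m == 0) {
    warning("constant-zero image: '", type, "' remap returned unchanged")
    return(vol)
  }
  switch(type,
    square = (vol / sqrt(m))^2,
    squareroot = sqrt(abs(vol) / m) * sign(vol),
    logarithm = {
      z <- sign(vol) * log(abs(vol) + 1)
      mz <- max(abs(z[mask]))
      if (mz == 0) vol else z * (m / mz)
    },
    exponential = exp(vol * (log(m) / m)),
    stop("unknown remap type: ", type))
}

log_sigma_name <- function(sigma)
  sprintf("log-sigma-%s-mm-3D", gsub("\\.", "-", sprintf("%.1f", sigma)))

#' Names of the image types in the filter bank
#'
#' @param log_sigmas LoG scales in mm.
#' @return Character vector of 18 image-type names for the default scales.
#' @export
image_type_names <- function(log_sigmas = 1:5) {
  c("original",
    vapply(log_sigmas, log_sigma_name, ""),
    paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                         "HLL", "HLH", "HHL", "HHH")),
    "square", "squareroot", "logarithm", "exponential")
}

#' Compute the image-type filter bank for one 3D volume
#'
#' Derived images on which every feature family is recomputed: the original
#' image; Laplacian-of-Gaussian responses at physical scales `log_sigmas` mm
#' (sigma converted to voxels through `spacing`); the 8 sub-bands of a
#' one-level undecimated coiflet-1 wavelet decomposition; and the four
#' standard intensity remaps (square, square root, logarithm, exponential).
#'
#' @param volume3d 3D array.
#' @param spacing Voxel size in mm (length 3).
#' @param mask Logical 3D array (non-empty).
#' @param image_types Subset of [image_type_names()] to compute (default all).
#' @param log_sigmas LoG scales in mm.
#' @return Named list of 3D arrays, each with the input's spatial shape.
#' @export
filter_bank <- function(volume3d, spacing, mask,
                        image_types = image_type_names(log_sigmas),
                        log_sigmas = 1:5) {
  stop_if_not(any(mask), "mask must be non-empty")
  out <- list()
  wl <- NULL
  for (ty in image_types) {
    if (ty == "original") {
      out[[ty]] <- volume3d
    } else if (grepl("^log-sigma-", ty)) {
      sig <- as.numeric(gsub("-", ".", sub("log-sigma-(.*)-mm-3D", "\\1", ty)))
      out[[ty]] <- log_filter(volume3d, spacing, sig)
    } else if (grepl("^wavelet-", ty)) {
      if (is.null(wl)) wl <- wavelet_bank(volume3d)
      out[[ty]] <- wl[[sub("wavelet-", "", ty)]]
    } else {
      out[[ty]] <- remap_image(volume3d, mask, ty)
    }
  }
  out
}

#' Discretize intensities into gray levels
#'
#' Fixed-bin-width discretization anchored at the masked minimum:
#' `level(x) = floor((x - min_masked) / bin_width) + 1`. Voxels outside the
#' mask get level 0.
#'
#' @param volume3d 3D array.
#' @param mask Logical 3D array (non-empty).
#' @param bin_width Positive bin width in intensity units.
#' @return Integer array of gray levels, with attribute `ng` (number of
#'   levels).
#' @export
discretize <- function(volume3d, mask, bin_width = 25) {
  stop_if_not(bin_width > 0, "bin_width must be positive")
  stop_if_not(any(mask), "mask must be non-empty")
  lev <- array(0L, dim(volume3d))
  xv <- volume3d[mask]
  lev[mask] <- as.integer(floor((xv - min(xv)) / bin_width)) + 1L
  attr(lev, "ng") <- max(lev)
  lev
}
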