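#' First-order intensity statistics
#'
#' The 18 standard first-order radiomics features of the masked intensities.
#' Entropy and Uniformity are computed on a fixed-bin-width histogram
#' (`bin_width`); TotalEnergy scales Energy by the voxel volume. Skewness and
#' kurtosis of a zero-variance region are defined as 0 (degenerate-moment
#' convention); kurtosis is not excess-corrected.
#'
#' @param x Numeric vector of masked intensities (length >= 1).
#' @param bin_width Bin width for the histogram-based features.
#' @param voxel_volume Physical voxel volume in mm^3.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(x, bin_width = 25, voxel_volume = 1) {
  stop_if_not(length(x) >= 1, "first-order features need at least one voxel")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)  # population variance
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  p <- tabulate(floor((x - min(x)) / bin_width) + 1L)
  p <- p[p > 0] / n
  robust <- x[x >= q[1] & x <= q[5]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}

#' @rdname first_order_features
#' @format NULL
#' @export
FIRSTORDER_NAMES <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                      "10Percentile", "90Percentile", "Maximum", "Mean",
                      "Median", "InterquartileRange", "Range",
                      "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                      "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                      "Uniformity")
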