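# Texture feature families on discretized gray-level volumes.
#
# Matrices are accumulated in C++ (13 unique 3D directions at Chebyshev
# distance 1 for GLCM/GLRLM; 26-connectivity for GLSZM zones and
# GLDM/NGTDM neighbourhoods); the feature arithmetic lives here.
#
# Degenerate conventions (applied consistently and logged by callers):
#   - correlation-type GLCM features with zero marginal variance -> 1
#   - information-measure features with zero entropy denominator -> 0
#   - NGTDM coarseness with zero denominator -> capped at 1e6
#   - a single-voxel mask yields empty pair/run sets; features on an all-zero
#     matrix are returned as 0 with a warning.

#' Feature rosters of the texture families
#'
#' The standard per-family feature names (24 GLCM, 16 GLRLM, 16 GLSZM,
#' 14 GLDM, 5 NGTDM), which together with the 18 first-order features give 93
#' features per image type.
#'
#' @name feature_rosters
#' @aliases GLCM_NAMES GLRLM_NAMES GLSZM_NAMES GLDM_NAMES NGTDM_NAMES
#' @export GLCM_NAMES GLRLM_NAMES GLSZM_NAMES GLDM_NAMES NGTDM_NAMES
NULL

GLCM_NAMES <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
                "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
                "JointAverage", "JointEnergy", "JointEntropy", "MCC",
                "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")

GLRLM_NAMES <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "GrayLevelVariance", "HighGrayLevelRunEmphasis",
                 "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
                 "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                 "RunEntropy", "RunLengthNonUniformity",
                 "RunLengthNonUniformityNormalized", "RunPercentage",
                 "RunVariance", "ShortRunEmphasis",
                 "ShortRunHighGrayLevelEmphasis",
                 "ShortRunLowGrayLevelEmphasis")

GLSZM_NAMES <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
                 "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
                 "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
                 "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                 "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
                 "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
                 "ZonePercentage", "ZoneVariance")

GLDM_NAMES <- c("DependenceEntropy", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "DependenceVariance",
                "GrayLevelNonUniformity", "GrayLevelVariance",
                "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
                "LargeDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
                "SmallDependenceEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis")

NGTDM_NAMES <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                 "Strength")

as_level_volume <- function(gray, mask = NULL) {
  lev <- gray
  if (!is.null(mask)) {
    lev <- array(as.integer(lev), dim = dim(lev))
    lev[!(mask > 0)] <- 0L
  }
  storage.mode(lev) <- "integer"
  lev
}

xlog2x <- function(M) {
  M[M > 0] <- M[M > 0] * log2(M[M > 0])
  M
}

#' Gray-level co-occurrence features
#'
#' Co-occurrence counts are accumulated over the 13 unique 3D direction
#' vectors at distance 1, symmetrized and normalised per direction; the 24
#' features are computed per direction and averaged over directions that
#' contain at least one pair.
#'
#' @param gray Integer gray-level volume (0 outside the mask), e.g. from
#'   [discretize()].
#' @param mask Optional logical array restricting the volume further.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(gray, mask = NULL) {
  lev <- as_level_volume(gray, mask)
  ng <- max(lev)
  if (ng == 0) stop("empty mask", call. = FALSE)
  arr <- cpp_glcm(lev, dim(lev), ng)
  Pm <- matrix(arr, ng * ng, 13)
  tot <- colSums(Pm)
  keep <- tot > 0
  if (!any(keep)) {
    warning("single masked voxel: no co-occurring pairs; GLCM features set to 0")
    return(setNames(numeric(length(GLCM_NAMES)), GLCM_NAMES))
  }
  Pm <- sweep(Pm[, keep, drop = FALSE], 2, tot[keep], "/")
  nd <- sum(keep)
  g <- seq_len(ng)
  iv <- rep(g, times = ng); jv <- rep(g, each = ng)
  # per-direction marginals (gray x nd) and diagonal/cross-diagonal marginals
  px <- rowsum(Pm, iv); py <- rowsum(Pm, jv)
  pxmy <- rowsum(Pm, abs(iv - jv))            # rows: |i-j| = 0..ng-1
  pxpy <- rowsum(Pm, iv + jv)                 # rows: i+j = 2..2ng
  mux <- colSums(px * g); muy <- colSums(py * g)
  sigx2 <- colSums((outer(g, mux, "-"))^2 * px)
  sigy2 <- colSums((outer(g, muy, "-"))^2 * py)
  HX <- -colSums(xlog2x(px)); HY <- -colSums(xlog2x(py))
  HXY <- -colSums(xlog2x(Pm))
  # HXY1 and HXY2 collapse to HX + HY for true marginals
  kd <- 0:(ng - 1)
  ks <- 2:(2 * ng)
  ac <- colSums(Pm * (iv * jv))
  contrast <- colSums(Pm * (iv - jv)^2)
  je <- colSums(Pm^2)
  maxp <- apply(Pm, 2, max)
  da <- colSums(pxmy * kd)
  dv <- colSums((outer(kd, da, "-"))^2 * pxmy)
  de <- -colSums(xlog2x(pxmy))
  id <- colSums(pxmy / (1 + kd))
  idm <- colSums(pxmy / (1 + kd^2))
  idmn <- colSums(pxmy / (1 + kd^2 / ng^2))
  idn <- colSums(pxmy / (1 + kd / ng))
  invv <- if (ng > 1) colSums(pxmy[-1, , drop = FALSE] / kd[-1]^2)
  else rep(0, nd)
  sa <- colSums(pxpy * ks)
  se <- -colSums(xlog2x(pxpy))
  cdev <- outer(ks, mux + muy, "-")
  ct <- colSums(cdev^2 * pxpy)
  cs <- colSums(cdev^3 * pxpy)
  cp <- colSums(cdev^4 * pxpy)
  corr <- ifelse(sigx2 > 0 & sigy2 > 0,
                 (ac - mux * muy) / sqrt(pmax(sigx2 * sigy2, 1e-300)), 1)
  mi <- HX + HY - HXY
  imc1 <- ifelse(pmax(HX, HY) > 0, -mi / pmax(HX, HY, 1e-300), 0)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * mi)))
  # MCC = sqrt of the 2nd eigenvalue of Q = Dx^-1 P Dy^-1 P'. The symmetrized
  # GLCM has px = py, so Q is similar to S^2 with S = D^-1/2 P D^-1/2
  # symmetric; the 2nd largest |eigenvalue| of S equals the MCC and avoids
  # the sqrt-at-zero noise amplification of the direct form.
  mcc <- numeric(nd)
  for (d in seq_len(nd)) {
    if (ng == 1) { mcc[d] <- 1; next }
    P <- matrix(Pm[, d], ng, ng)
    ds <- 1 / sqrt(pmax(px[, d], .Machine$double.xmin))
    S <- P * outer(ds, ds)
    ev <- sort(abs(eigen(S, symmetric = TRUE,
                         only.values = TRUE)$values), decreasing = TRUE)
    mcc[d] <- ev[2]
  }
  out <- rbind(Autocorrelation = ac, ClusterProminence = cp,
               ClusterShade = cs, ClusterTendency = ct, Contrast = contrast,
               Correlation = corr, DifferenceAverage = da,
               DifferenceEntropy = de, DifferenceVariance = dv, Id = id,
               Idm = idm, Idmn = idmn, Idn = idn, Imc1 = imc1, Imc2 = imc2,
               InverseVariance = invv, JointAverage = mux, JointEnergy = je,
               JointEntropy = HXY, MCC = mcc, MaximumProbability = maxp,
               SumAverage = sa, SumEntropy = se, SumSquares = sigx2)
  rowMeans(out)[GLCM_NAMES]
}

# Shared arithmetic for run-length-shaped matrices P (gray level x size).
# Returns the 16 generic statistics; family wrappers rename / subset.
pmat_features <- function(P, n_voxels) {
  ns <- sum(P)
  if (ns == 0) return(setNames(numeric(16),
    c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rv", "re",
      "lgl", "hgl", "srlgl", "srhgl", "lrhgl", "lrlgl")))
  g <- seq_len(nrow(P)); s <- seq_len(ncol(P))
  pg <- rowSums(P); ps <- colSums(P)
  p <- P / ns
  mug <- sum(g * rowSums(p)); mus <- sum(s * colSums(p))
  pp <- p[p > 0]
  c(sre = sum(sweep(P, 2, s^2, "/")) / ns,
    lre = sum(sweep(P, 2, s^2, "*")) / ns,
    gln = sum(pg^2) / ns,
    glnn = sum(pg^2) / ns^2,
    rln = sum(ps^2) / ns,
    rlnn = sum(ps^2) / ns^2,
    rp = ns / n_voxels,
    glv = sum(sweep(p, 1, (g - mug)^2, "*")),
    rv = sum(sweep(p, 2, (s - mus)^2, "*")),
    re = -sum(pp * log2(pp)),
    lgl = sum(sweep(P, 1, g^2, "/")) / ns,
    hgl = sum(sweep(P, 1, g^2, "*")) / ns,
    srlgl = sum(P / outer(g^2, s^2)) / ns,
    srhgl = sum(P * outer(g^2, 1 / s^2)) / ns,
    lrhgl = sum(P * outer(g^2, s^2)) / ns,
    lrlgl = sum(P * outer(1 / g^2, s^2)) / ns)
}

#' Gray-level run-length features
#'
#' Runs of equal gray level are counted along each of the 13 unique 3D
#' directions; the 16 features are computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(gray, mask = NULL) {
  lev <- as_level_volume(gray, mask)
  ng <- max(lev)
  if (ng == 0) stop("empty mask", call. = FALSE)
  np <- sum(lev > 0)
  arr <- cpp_glrlm(lev, dim(lev), ng)
  ml <- dim(arr)[2]
  Pm <- matrix(arr, ng * ml, 13)
  ns <- colSums(Pm)
  g <- seq_len(ng); s <- seq_len(ml)
  giv <- rep(g, times = ml); sjv <- rep(s, each = ng)
  pg <- rowsum(Pm, giv); ps <- rowsum(Pm, sjv)
  wsum <- function(w) colSums(Pm * w) / ns
  mug <- colSums(pg * g) / ns; mus <- colSums(ps * s) / ns
  Pn <- sweep(Pm, 2, ns, "/")
  f13 <- rbind(
    sre = wsum(1 / sjv^2), lre = wsum(sjv^2),
    gln = colSums(pg^2) / ns, glnn = colSums(pg^2) / ns^2,
    rln = colSums(ps^2) / ns, rlnn = colSums(ps^2) / ns^2,
    rp = ns / np,
    glv = colSums((outer(g, mug, "-"))^2 * pg) / ns,
    rv = colSums((outer(s, mus, "-"))^2 * ps) / ns,
    re = -colSums(xlog2x(Pn)),
    lgl = wsum(1 / giv^2), hgl = wsum(giv^2),
    srlgl = wsum(1 / (giv^2 * sjv^2)), srhgl = wsum(giv^2 / sjv^2),
    lrhgl = wsum(giv^2 * sjv^2), lrlgl = wsum(sjv^2 / giv^2))
  f <- rowMeans(f13)
  setNames(f[c("gln", "glnn", "glv", "hgl", "lre", "lrhgl", "lrlgl", "lgl",
               "re", "rln", "rlnn", "rp", "rv", "sre", "srhgl", "srlgl")],
           GLRLM_NAMES)
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level within the mask; the
#' 16 features are computed on the single zone matrix.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(gray, mask = NULL) {
  lev <- as_level_volume(gray, mask)
  ng <- max(lev)
  if (ng == 0) stop("empty mask", call. = FALSE)
  np <- sum(lev > 0)
  z <- cpp_glszm_zones(lev, dim(lev))
  # sparse zone-list arithmetic (a single zone can span thousands of voxels,
  # so the dense gray x size matrix is avoided)
  gi <- z[, 1]; si <- z[, 2]
  ns <- length(gi)
  pg <- tabulate(gi, ng)
  cs <- tabulate(si, max(si))       # zone counts per distinct size
  mug <- mean(gi); mus <- mean(si)
  key <- (gi - 1) * max(si) + si
  ck <- tabulate(key, ng * max(si))
  pk <- ck[ck > 0] / ns
  f <- c(gln = sum(pg^2) / ns, glnn = sum(pg^2) / ns^2,
         glv = mean((gi - mug)^2), hgl = mean(gi^2),
         lre = mean(si^2), lrhgl = mean(gi^2 * si^2),
         lrlgl = mean(si^2 / gi^2), lgl = mean(1 / gi^2),
         rln = sum(cs^2) / ns, rlnn = sum(cs^2) / ns^2,
         sre = mean(1 / si^2), srhgl = mean(gi^2 / si^2),
         srlgl = mean(1 / (gi^2 * si^2)),
         re = -sum(pk * log2(pk)), rp = ns / np,
         rv = mean((si - mus)^2))
  setNames(f, GLSZM_NAMES)
}

#' Gray-level dependence features
#'
#' The dependence of a masked voxel is the number of its 26 masked neighbours
#' whose gray level differs by at most `alpha`. The matrix column index is
#' dependence + 1 (so the size weight of an isolated voxel is 1).
#'
#' @inheritParams glcm_features
#' @param alpha Dependence tolerance (default 0: equal levels only).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(gray, mask = NULL, alpha = 0) {
  lev <- as_level_volume(gray, mask)
  ng <- max(lev)
  if (ng == 0) stop("empty mask", call. = FALSE)
  np <- sum(lev > 0)
  P <- cpp_gldm(lev, dim(lev), ng, as.integer(alpha))
  f <- pmat_features(P, np)
  setNames(f[c("re", "rln", "rlnn", "rv", "gln", "glv", "hgl", "lre", "lrhgl",
               "lrlgl", "lgl", "sre", "srhgl", "srlgl")],
           GLDM_NAMES)
}

#' Neighbouring gray-tone difference features
#'
#' For each gray level i present in the mask, `s_i` accumulates the absolute
#' difference between i and the mean level of each voxel's valid
#' 26-neighbourhood. Coarseness with a zero denominator is capped at 1e6;
#' Contrast of a single-level region is 0.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(gray, mask = NULL) {
  lev <- as_level_volume(gray, mask)
  ng <- max(lev)
  if (ng == 0) stop("empty mask", call. = FALSE)
  M <- cpp_ngtdm(lev, dim(lev), ng)
  nvec <- M[, 1]; svec <- M[, 2]
  nvp <- sum(nvec)
  pres <- nvec > 0
  gi <- which(pres)
  pi <- nvec[pres] / nvp
  si <- svec[pres]
  ngp <- length(gi)
  psum <- sum(pi * si)
  coarse <- if (psum > 0) min(1 / psum, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(pi, pi) * outer(gi, gi, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(svec) / nvp)
  } else 0
  busy_den <- sum(abs(outer(gi * pi, gi * pi, "-")))
  busy <- if (busy_den > 0) psum / busy_den else 0
  dgi <- abs(outer(gi, gi, "-"))
  cplx <- sum(dgi * outer(pi * si, pi * si, "+") /
                outer(pi, pi, "+")) / nvp
  str_num <- sum(outer(pi, pi, "+") * outer(gi, gi, function(a, b) (a - b)^2))
  strength <- if (sum(svec) > 0) str_num / sum(svec) else 0
  c(Busyness = busy, Coarseness = coarse, Complexity = cplx,
    Contrast = contrast, Strength = strength)
}
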