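# Independent brute-force oracles for the texture families, written as plain
# enumerations over voxels/pairs/runs/zones with explicit loops. They share
# only the documented conventions with the package (13-direction set,
# dependence column = dependence + 1, degenerate-value conventions).

ORACLE_DIRS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

ALL_OFFSETS26 <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
ALL_OFFSETS26 <- ALL_OFFSETS26[rowSums(abs(ALL_OFFSETS26)) > 0, ]

lev_at <- function(lev, p) {
  d <- dim(lev)
  if (any(p < 1) || any(p > d)) return(0L)
  lev[p[1], p[2], p[3]]
}

random_level_grid <- function(seed, max_dim = c(4, 4, 3), max_level = 4,
                              mask_frac = 0.85) {
  set.seed(seed)
  d <- c(sample(2:max_dim[1], 1), sample(2:max_dim[2], 1),
         sample(1:max_dim[3], 1))
  lev <- array(sample.int(max_level, prod(d), replace = TRUE), dim = d)
  drop_n <- rbinom(1, prod(d) - 1, 1 - mask_frac)
  if (drop_n > 0) lev[sample(prod(d), drop_n)] <- 0L
  if (all(lev == 0)) lev[1] <- 1L
  storage.mode(lev) <- "integer"
  lev
}

# ---- GLCM ------------------------------------------------------------------

oracle_glcm_matrix <- function(lev, dir) {
  ng <- max(lev)
  P <- matrix(0, ng, ng)
  d <- dim(lev)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (a == 0) next
    b <- lev_at(lev, c(i, j, k) + dir)
    if (b == 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracle_glcm_features_one <- function(P) {
  ng <- nrow(P)
  p <- P / sum(P)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:ng) { sx2 <- sx2 + (i - mux)^2 * px[i]
                    sy2 <- sy2 + (i - muy)^2 * py[i] }
  pxmy <- numeric(ng); pxpy <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pxmy[abs(i - j) + 1] <- pxmy[abs(i - j) + 1] + p[i, j]
    pxpy[i + j] <- pxpy[i + j] + p[i, j]
  }
  H <- function(v) { v <- v[v > 0]; if (!length(v)) 0 else -sum(v * log2(v)) }
  ac <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; jav <- 0; je <- 0; ss <- 0
  ipj <- 0
  for (i in 1:ng) for (j in 1:ng) {
    ac <- ac + i * j * p[i, j]
    cp <- cp + (i + j - mux - muy)^4 * p[i, j]
    cs <- cs + (i + j - mux - muy)^3 * p[i, j]
    ct <- ct + (i + j - mux - muy)^2 * p[i, j]
    con <- con + (i - j)^2 * p[i, j]
    jav <- jav + i * p[i, j]
    je <- je + p[i, j]^2
    ss <- ss + (i - mux)^2 * p[i, j]
    ipj <- ipj + i * j * p[i, j]
  }
  corr <- if (sx2 > 0 && sy2 > 0) (ipj - mux * muy) / sqrt(sx2 * sy2) else 1
  kd <- 0:(ng - 1)
  da <- sum(kd * pxmy)
  dv <- sum((kd - da)^2 * pxmy)
  id <- sum(pxmy / (1 + kd)); idm <- sum(pxmy / (1 + kd^2))
  idmn <- sum(pxmy / (1 + kd^2 / ng^2)); idn <- sum(pxmy / (1 + kd / ng))
  iv <- if (ng > 1) sum(pxmy[-1] / (kd[-1])^2) else 0
  HX <- H(px); HY <- H(py); HXY <- H(as.numeric(p))
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) HXY1 <- HXY1 - p[i, j] * log2(q)
      HXY2 <- HXY2 - q * log2(q)
    }
  }
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  # second-largest |eigenvalue| of the symmetric D^-1/2 P D^-1/2 (the stable
  # equivalent of sqrt(lambda_2) of the marginal-scaled product matrix)
  mcc <- if (ng == 1) 1 else {
    S <- matrix(0, ng, ng)
    for (i in 1:ng) for (j in 1:ng)
      if (px[i] > 0 && py[j] > 0)
        S[i, j] <- p[i, j] / sqrt(px[i] * py[j])
    ev <- sort(abs(eigen(S, symmetric = TRUE)$values), decreasing = TRUE)
    ev[2]
  }
  c(Autocorrelation = ac, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = con, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = H(pxmy),
    DifferenceVariance = dv, Id = id, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = imc1, Imc2 = imc2, InverseVariance = iv, JointAverage = jav,
    JointEnergy = je, JointEntropy = HXY, MCC = mcc,
    MaximumProbability = max(p), SumAverage = sum((2:(2 * ng)) * pxpy[-1]),
    SumEntropy = H(pxpy), SumSquares = ss)
}

oracle_glcm_features <- function(lev) {
  acc <- NULL; nd <- 0
  for (r in seq_len(nrow(ORACLE_DIRS))) {
    P <- oracle_glcm_matrix(lev, ORACLE_DIRS[r, ])
    if (sum(P) == 0) next
    f <- oracle_glcm_features_one(P)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) return(setNames(numeric(24), names(oracle_glcm_features_one(matrix(1)))))
  acc / nd
}

# ---- generic gray-level x size feature formulas (loops) --------------------

oracle_pmat_features <- function(P, np) {
  ns <- sum(P)
  ng <- nrow(P); ms <- ncol(P)
  sre <- lre <- lgl <- hgl <- srlgl <- srhgl <- lrhgl <- lrlgl <- 0
  for (i in 1:ng) for (j in 1:ms) {
    if (P[i, j] == 0) next
    sre <- sre + P[i, j] / j^2; lre <- lre + P[i, j] * j^2
    lgl <- lgl + P[i, j] / i^2; hgl <- hgl + P[i, j] * i^2
    srlgl <- srlgl + P[i, j] / (i^2 * j^2)
    srhgl <- srhgl + P[i, j] * i^2 / j^2
    lrhgl <- lrhgl + P[i, j] * i^2 * j^2
    lrlgl <- lrlgl + P[i, j] * j^2 / i^2
  }
  pg <- rowSums(P); ps <- colSums(P)
  mug <- sum((1:ng) * pg) / ns; mus <- sum((1:ms) * ps) / ns
  glv <- sum(((1:ng) - mug)^2 * pg) / ns
  rv <- sum(((1:ms) - mus)^2 * ps) / ns
  pp <- P[P > 0] / ns
  c(sre = sre / ns, lre = lre / ns, gln = sum(pg^2) / ns,
    glnn = sum(pg^2) / ns^2, rln = sum(ps^2) / ns, rlnn = sum(ps^2) / ns^2,
    rp = ns / np, glv = glv, rv = rv, re = -sum(pp * log2(pp)),
    lgl = lgl / ns, hgl = hgl / ns, srlgl = srlgl / ns, srhgl = srhgl / ns,
    lrhgl = lrhgl / ns, lrlgl = lrlgl / ns)
}

# ---- GLRLM -----------------------------------------------------------------

# run-length counts via rle() over every maximal grid line in a direction
oracle_glrlm_matrix <- function(lev, dir) {
  d <- dim(lev)
  ng <- max(lev)
  maxlen <- max(d)
  P <- matrix(0, ng, maxlen)
  starts <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    prev <- c(i, j, k) - dir
    inside <- all(prev >= 1) && all(prev <= d)
    if (!inside) starts[[length(starts) + 1]] <- c(i, j, k)
  }
  for (s in starts) {
    seqv <- integer(0)
    p <- s
    while (all(p >= 1) && all(p <= d)) {
      seqv <- c(seqv, lev[p[1], p[2], p[3]])
      p <- p + dir
    }
    r <- rle(seqv)
    for (q in seq_along(r$values))
      if (r$values[q] > 0)
        P[r$values[q], r$lengths[q]] <- P[r$values[q], r$lengths[q]] + 1
  }
  P
}

oracle_glrlm_features <- function(lev) {
  np <- sum(lev > 0)
  acc <- NULL
  for (r in seq_len(nrow(ORACLE_DIRS))) {
    f <- oracle_pmat_features(oracle_glrlm_matrix(lev, ORACLE_DIRS[r, ]), np)
    acc <- if (is.null(acc)) f else acc + f
  }
  f <- acc / 13
  setNames(f[c("gln", "glnn", "glv", "hgl", "lre", "lrhgl", "lrlgl", "lgl",
               "re", "rln", "rlnn", "rp", "rv", "sre", "srhgl", "srlgl")],
           dynradiomics::GLRLM_NAMES)
}

# ---- GLSZM -----------------------------------------------------------------

# zones by iterative set expansion over the 26 offsets
oracle_zones <- function(lev) {
  d <- dim(lev)
  coords <- which(lev > 0, arr.ind = TRUE)
  remaining <- apply(coords, 1, paste, collapse = ",")
  key <- function(p) paste(p, collapse = ",")
  zones <- list()
  while (length(remaining) > 0) {
    seed_p <- as.integer(strsplit(remaining[1], ",")[[1]])
    zl <- lev[seed_p[1], seed_p[2], seed_p[3]]
    zone <- remaining[1]
    repeat {
      grew <- FALSE
      for (kk in zone) {
        p <- as.integer(strsplit(kk, ",")[[1]])
        for (r in seq_len(nrow(ALL_OFFSETS26))) {
          q <- p + as.integer(ALL_OFFSETS26[r, ])
          if (any(q < 1) || any(q > d)) next
          if (lev[q[1], q[2], q[3]] == zl && !(key(q) %in% zone)) {
            zone <- c(zone, key(q)); grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    zones[[length(zones) + 1]] <- list(level = zl, size = length(zone))
    remaining <- setdiff(remaining, zone)
  }
  zones
}

oracle_glszm_features <- function(lev) {
  np <- sum(lev > 0)
  z <- oracle_zones(lev)
  ng <- max(lev)
  ms <- max(vapply(z, `[[`, 0, "size"))
  P <- matrix(0, ng, ms)
  for (zz in z) P[zz$level, zz$size] <- P[zz$level, zz$size] + 1
  f <- oracle_pmat_features(P, np)
  setNames(f[c("gln", "glnn", "glv", "hgl", "lre", "lrhgl", "lrlgl", "lgl",
               "rln", "rlnn", "sre", "srhgl", "srlgl", "re", "rp", "rv")],
           dynradiomics::GLSZM_NAMES)
}

# ---- GLDM ------------------------------------------------------------------

oracle_gldm_features <- function(lev, alpha = 0) {
  d <- dim(lev)
  ng <- max(lev)
  np <- sum(lev > 0)
  P <- matrix(0, ng, 27)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (a == 0) next
    dep <- 0
    for (r in seq_len(nrow(ALL_OFFSETS26))) {
      b <- lev_at(lev, c(i, j, k) + as.integer(ALL_OFFSETS26[r, ]))
      if (b > 0 && abs(b - a) <= alpha) dep <- dep + 1
    }
    P[a, dep + 1] <- P[a, dep + 1] + 1
  }
  f <- oracle_pmat_features(P, np)
  setNames(f[c("re", "rln", "rlnn", "rv", "gln", "glv", "hgl", "lre", "lrhgl",
               "lrlgl", "lgl", "sre", "srhgl", "srlgl")],
           dynradiomics::GLDM_NAMES)
}

# ---- NGTDM -----------------------------------------------------------------

oracle_ngtdm_features <- function(lev) {
  d <- dim(lev)
  ng <- max(lev)
  nvec <- numeric(ng); svec <- numeric(ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (a == 0) next
    vals <- c()
    for (r in seq_len(nrow(ALL_OFFSETS26))) {
      b <- lev_at(lev, c(i, j, k) + as.integer(ALL_OFFSETS26[r, ]))
      if (b > 0) vals <- c(vals, b)
    }
    nvec[a] <- nvec[a] + 1
    if (length(vals) > 0) svec[a] <- svec[a] + abs(a - mean(vals))
  }
  nvp <- sum(nvec)
  gi <- which(nvec > 0)
  pi <- nvec[gi] / nvp; si <- svec[gi]
  ngp <- length(gi)
  psum <- sum(pi * si)
  coarse <- if (psum > 0) min(1 / psum, 1e6) else 1e6
  contrast <- 0
  if (ngp > 1) {
    s1 <- 0
    for (a in seq_along(gi)) for (b in seq_along(gi))
      s1 <- s1 + pi[a] * pi[b] * (gi[a] - gi[b])^2
    contrast <- s1 / (ngp * (ngp - 1)) * sum(svec) / nvp
  }
  bden <- 0; cplx <- 0; snum <- 0
  for (a in seq_along(gi)) for (b in seq_along(gi)) {
    bden <- bden + abs(gi[a] * pi[a] - gi[b] * pi[b])
    cplx <- cplx + abs(gi[a] - gi[b]) * (pi[a] * si[a] + pi[b] * si[b]) /
      (pi[a] + pi[b])
    snum <- snum + (pi[a] + pi[b]) * (gi[a] - gi[b])^2
  }
  c(Busyness = if (bden > 0) psum / bden else 0,
    Coarseness = coarse,
    Complexity = cplx / nvp,
    Contrast = contrast,
    Strength = if (sum(svec) > 0) snum / sum(svec) else 0)
}
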