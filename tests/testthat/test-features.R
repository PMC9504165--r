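test_that("first-order features match hand computations", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(f[["Mean"]], 2.5)
  expect_equal(f[["Median"]], 2.5)
  expect_equal(f[["Variance"]], 1.25)  # population convention
  expect_equal(f[["Energy"]], 1 + 4 + 9 + 16)
  expect_equal(f[["Range"]], 3)
  expect_equal(f[["RootMeanSquared"]], sqrt(30 / 4))
  const <- first_order_features(rep(3, 10), voxel_volume = 2)
  expect_equal(const[["Variance"]], 0)
  expect_equal(const[["Range"]], 0)
  expect_equal(const[["Energy"]], 90)
  expect_equal(const[["TotalEnergy"]], 180)
  expect_equal(const[["Skewness"]], 0)  # degenerate-moment convention
  expect_equal(const[["Kurtosis"]], 0)
  expect_equal(const[["Entropy"]], 0)
  expect_equal(const[["Uniformity"]], 1)
  expect_length(f, 18)
  expect_identical(names(f), FIRSTORDER_NAMES)
  expect_error(first_order_features(numeric(0)), "voxel")
})

test_that("GLCM hand examples: constant cube and 2x2 grid directions", {
  cube <- array(1L, dim = c(3, 3, 3))
  f <- glcm_features(cube)
  expect_equal(f[["JointEntropy"]], 0)
  expect_equal(f[["Id"]], 1)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Correlation"]], 1)  # degenerate convention
  expect_equal(f[["MCC"]], 1)
  # 2x2x1 grid [[1,1],[2,2]]: along-row pairs stay within a level
  # (contrast 0), across-row pairs always differ by 1 (contrast 1)
  g <- array(c(1L, 2L, 1L, 2L), dim = c(2, 2, 1))
  arr <- dynradiomics:::cpp_glcm(g, dim(g), 2L)
  d_along <- arr[, , 2]   # direction (0,1,0): same level
  d_across <- arr[, , 1]  # direction (1,0,0): level changes
  expect_equal(d_along, matrix(c(2, 0, 0, 2), 2))
  expect_equal(d_across, matrix(c(0, 2, 2, 0), 2))
  pal <- d_along / sum(d_along)
  pac <- d_across / sum(d_across)
  expect_equal(sum((row(pal) - col(pal))^2 * pal), 0)
  expect_equal(sum((row(pac) - col(pac))^2 * pac), 1)
})

test_that("GLRLM hand examples: single run and alternating line", {
  line <- array(1L, dim = c(1, 1, 4))
  f <- glrlm_features(line)
  # the (0,0,1) direction sees one run of length 4 (LRE 16); the other 12
  # directions see four runs of length 1 (LRE 1)
  expect_equal(f[["LongRunEmphasis"]], (16 + 12) / 13)
  alt <- array(c(1L, 2L, 1L, 2L), dim = c(1, 1, 4))
  fa <- glrlm_features(alt)
  expect_equal(fa[["ShortRunEmphasis"]], 1)  # every run has length 1
  expect_equal(fa[["RunPercentage"]], 1)
})

test_that("GLSZM and GLDM hand examples: connectivity and dependence", {
  cube <- array(2L, dim = c(3, 3, 3))
  f <- glszm_features(cube)
  expect_equal(f[["LargeAreaEmphasis"]], 27^2)  # one zone of 27 voxels
  expect_equal(f[["ZonePercentage"]], 1 / 27)
  # two diagonal-touching voxels form one zone under 26-connectivity
  g <- array(0L, dim = c(3, 3, 1))
  g[1, 1, 1] <- 1L; g[2, 2, 1] <- 1L
  z <- dynradiomics:::cpp_glszm_zones(g, dim(g))
  expect_equal(nrow(z), 1)
  expect_equal(z[1, 2], 2)
  # constant cube: centre voxel depends on all 26 neighbours
  P <- dynradiomics:::cpp_gldm(cube, dim(cube), 2L, 0L)
  expect_equal(P[2, 27], 1)  # dependence 26 (column = dep + 1)
  # isolated masked voxel has dependence 0
  iso <- array(0L, dim = c(3, 3, 1)); iso[2, 2, 1] <- 1L
  Pi <- dynradiomics:::cpp_gldm(iso, dim(iso), 1L, 0L)
  expect_equal(Pi[1, 1], 1)
})

test_that("NGTDM degenerate conventions hold", {
  cube <- array(3L, dim = c(3, 3, 3))
  f <- ngtdm_features(cube)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Coarseness"]], 1e6)  # zero-denominator sentinel
  expect_equal(f[["Busyness"]], 0)
  expect_equal(f[["Strength"]], 0)
})

test_that("all five texture families match their enumeration oracles", {
  for (s in 1:30) {
    lev <- random_level_grid(s)
    expect_equal(suppressWarnings(glcm_features(lev)),
                 oracle_glcm_features(lev), tolerance = 1e-12)
    expect_equal(glrlm_features(lev), oracle_glrlm_features(lev),
                 tolerance = 1e-12)
    expect_equal(glszm_features(lev), oracle_glszm_features(lev),
                 tolerance = 1e-12)
    expect_equal(gldm_features(lev), oracle_gldm_features(lev),
                 tolerance = 1e-12)
    expect_equal(ngtdm_features(lev), oracle_ngtdm_features(lev),
                 tolerance = 1e-12)
  }
})

test_that("texture features on the original type are intensity-shift invariant", {
  set.seed(9)
  vol <- array(rnorm(6 * 6 * 4, 100, 20), dim = c(6, 6, 4))
  mask <- array(runif(length(vol)) > 0.2, dim = dim(vol))
  mask[1] <- TRUE
  g1 <- discretize(vol, mask, 25)
  g2 <- discretize(vol + 500, mask, 25)  # min-anchored binning
  expect_identical(g1, g2)
  expect_equal(suppressWarnings(glcm_features(g1)),
               suppressWarnings(glcm_features(g2)))
})
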