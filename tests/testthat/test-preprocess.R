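tc_array <- function(x) array(rep(x, each = 1), dim = c(1, 1, 1, length(x)))

test_that("one smoothing pass matches the hand convolution with replicate edges", {
  v <- tc_array(c(0, 0, 1, 0, 0))
  sm <- temporal_smooth(v, passes = 1)
  expect_equal(as.numeric(sm), c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  const <- tc_array(rep(4.2, 7))
  expect_equal(temporal_smooth(const), const)
  expect_error(temporal_smooth(tc_array(c(1, 2))), "3 timepoints")
})

test_that("three passes equal one convolution with the composed kernel on interior points", {
  set.seed(1)
  x <- rnorm(60)
  v <- tc_array(x)
  sm3 <- as.numeric(temporal_smooth(v, passes = 3))
  k <- c(1, 1, 1) / 3
  composed <- convolve(convolve(k, rev(k), type = "open"), rev(k),
                       type = "open")  # length 7
  interior <- 4:(60 - 3)
  manual <- vapply(interior, function(i) sum(composed * x[(i - 3):(i + 3)]), 0)
  expect_equal(sm3[interior], manual, tolerance = 1e-12)
})

test_that("smoothing is a per-voxel temporal contraction", {
  set.seed(2)
  v <- array(rnorm(4 * 5 * 6 * 30), dim = c(4, 5, 6, 30))
  cur <- v
  for (p in 1:3) {
    nxt <- temporal_smooth(cur, passes = 1)
    v_cur <- apply(cur, 1:3, var)
    v_nxt <- apply(nxt, 1:3, var)
    expect_true(all(v_nxt <= v_cur + 1e-12))
    cur <- nxt
  }
})

test_that("the reference volume averages exactly the first and last ten images", {
  d <- c(3, 4, 5)
  v <- array(0, dim = c(d, 50))
  for (tt in 1:50) v[, , , tt] <- tt - 1  # volume t filled with value t
  ref <- reference_volume(v)
  expect_equal(dim(ref), d)
  expect_true(all(abs(ref - 24.5) < 1e-12))  # (sum 0..9 + sum 40..49)/20
  allsame <- array(rep(array(rnorm(prod(d)), d), 50), dim = c(d, 50))
  expect_equal(reference_volume(allsame), allsame[, , , 1])
  # permutation invariance within the two blocks
  vp <- v[, , , c(sample(1:10), 11:40, sample(41:50))]
  expect_equal(reference_volume(vp), ref)
  expect_error(reference_volume(v[, , , 1:20]), "21 timepoints")
})

test_that("brain masking keeps exactly the masked voxels", {
  set.seed(3)
  v <- array(rnorm(4 * 4 * 2 * 25), dim = c(4, 4, 2, 25))
  all1 <- array(TRUE, dim = c(4, 4, 2))
  expect_equal(sum(!is.na(apply_brain_mask(v, all1))), length(v))
  chk <- array((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2 == 0,
               dim = c(4, 4, 2))
  mv <- apply_brain_mask(v, chk)
  for (tt in c(1, 25)) {
    expect_equal(sum(!is.na(mv[, , , tt])), sum(chk))
    expect_equal(mean(mv[, , , tt], na.rm = TRUE), mean(v[, , , tt][chk]))
  }
  expect_error(apply_brain_mask(v, array(FALSE, c(4, 4, 2))), "empty")
  expect_error(apply_brain_mask(v, array(TRUE, c(4, 4, 3))), "shape")
})

test_that("masking and smoothing commute", {
  set.seed(4)
  v <- array(rnorm(4 * 4 * 2 * 25), dim = c(4, 4, 2, 25))
  m <- array(sample(c(TRUE, FALSE), 32, TRUE), dim = c(4, 4, 2))
  m[1] <- TRUE
  a <- temporal_smooth(apply_brain_mask(v, m))
  b <- apply_brain_mask(temporal_smooth(v), m)
  expect_equal(as.numeric(a), as.numeric(b))
})
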