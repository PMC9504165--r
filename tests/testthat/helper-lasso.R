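# Plain cyclic coordinate-descent lasso at a fixed penalty, in glmnet's
# parametrisation: minimise (1/2n) * RSS + lambda * sum |beta|, with an
# unpenalised intercept. Independent check of the selection path.
cd_lasso <- function(x, y, lambda, max_iter = 2000, tol = 1e-10) {
  n <- nrow(x); p <- ncol(x)
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2, xm); yc <- y - ym
  b <- numeric(p)
  xs2 <- colSums(xc^2) / n
  r <- yc
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xs2[j] == 0) next
      rho <- sum(xc[, j] * r) / n + xs2[j] * b[j]
      bn <- sign(rho) * max(0, abs(rho) - lambda) / xs2[j]
      if (bn != b[j]) {
        r <- r - xc[, j] * (bn - b[j])
        delta <- max(delta, abs(bn - b[j]))
        b[j] <- bn
      }
    }
    if (delta < tol) break
  }
  list(beta = setNames(b, colnames(x)), intercept = ym - sum(xm * b))
}
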