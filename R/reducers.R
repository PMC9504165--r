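# Five unsupervised dimensionality reducers, each mapping a (subjects x
# features) matrix to a (subjects x n_components) embedding. PCA and classical
# MDS come from base R; FastICA, exact t-SNE and the UMAP-style embedding are
# implemented here (no installed R package provides them with 10 output
# dimensions), with seeds fixed for reproducibility.

pad_components <- function(scores, k, prefix) {
  if (ncol(scores) < k) {
    warning(prefix, ": data rank below ", k, "; padding with zero components")
    scores <- cbind(scores, matrix(0, nrow(scores), k - ncol(scores)))
  }
  scores <- scores[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0(prefix, seq_len(k) - 1)
  scores
}

reduce_pca <- function(x, k) {
  pad_components(prcomp(x, center = TRUE)$x, k, "PCA")
}

# FastICA with logcosh contrast and symmetric decorrelation, on a PCA-whitened
# basis of k components.
reduce_ica <- function(x, k, seed, max_iter = 200, tol = 1e-6) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  n <- nrow(xc)
  sv <- svd(xc, nu = k, nv = 0)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  kk <- min(k, r, n - 1)
  Z <- sv$u[, seq_len(kk), drop = FALSE] * sqrt(n)  # whitened: cov(Z) = I
  W <- with_seed(seed, matrix(rnorm(kk * kk), kk, kk))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), kk) %*%
      t(e$vectors)
    solve_sqrt %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    U <- Z %*% t(W)
    G <- tanh(U)
    Gp <- colMeans(1 - G^2)
    W1 <- t(G) %*% Z / n - diag(Gp, kk) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  pad_components(Z %*% t(W), k, "ICA")
}

# Exact t-SNE (non-tree gradient) with PCA initialisation, suitable for
# 10 output dimensions on cohort-sized inputs.
reduce_tsne <- function(x, k, seed, perplexity = NULL, n_iter = 300,
                        exaggeration = 12, lr = 200) {
  n <- nrow(x)
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  xp <- prcomp(x, center = TRUE)$x
  xp <- xp[, seq_len(min(ncol(xp), 30)), drop = FALSE]
  D2 <- as.matrix(dist(xp))^2
  P <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0 } else {
        pj <- w / sw
        H <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / max(sum(w), .Machine$double.xmin)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- pad_components(xp, k, "T")  # PCA init, scaled down
  Y <- Y / max(sd(as.numeric(Y)), 1e-12) * 1e-4
  Y <- Y + with_seed(seed, matrix(rnorm(n * k, sd = 1e-6), n, k))
  upd <- matrix(0, n, k)
  for (it in seq_len(n_iter)) {
    Pit <- if (it <= 100) P * exaggeration else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 100) 0.5 else 0.8
    upd <- mom * upd - lr * grad
    Y <- Y + upd
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- paste0("TSNE", seq_len(k) - 1)
  Y
}

# Fit the (a, b) low-dimensional similarity curve 1/(1 + a d^(2b)) to the
# target membership exp(-(d - min_dist)) beyond min_dist (1 inside).
umap_ab <- function(min_dist = 0.3, spread = 1) {
  d <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(d <= min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(p) sum((1 / (1 + p[1] * d^(2 * p[2])) - target)^2)
  stats::optim(c(1.5, 1), obj, method = "L-BFGS-B",
               lower = c(1e-3, 1e-3))$par
}

# Compact UMAP-style embedding: smooth-kNN fuzzy graph (probabilistic union),
# PCA initialisation, full-gradient cross-entropy descent. Suitable for
# cohort-sized inputs where negative sampling is unnecessary.
reduce_umap <- function(x, k, seed, n_neighbors = 5, min_dist = 0.3,
                        n_epochs = 200) {
  n <- nrow(x)
  n_neighbors <- min(n_neighbors, n - 1)
  D <- as.matrix(dist(x))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- setdiff(order(D[i, ]), i)[seq_len(n_neighbors)]
    dnb <- D[i, nb]
    rho <- min(dnb)
    target <- log2(n_neighbors)
    lo <- 1e-6; hi <- 1e3
    for (it in 1:50) {
      sig <- (lo + hi) / 2
      s <- sum(exp(-pmax(dnb - rho, 0) / sig))
      if (abs(s - target) < 1e-5) break
      if (s > target) hi <- sig else lo <- sig
    }
    W[i, nb] <- exp(-pmax(dnb - rho, 0) / sig)
  }
  G <- W + t(W) - W * t(W)  # fuzzy set union
  ab <- umap_ab(min_dist)
  a <- ab[1]; b <- ab[2]
  Y <- pad_components(prcomp(x, center = TRUE)$x, k, "U")
  Y <- Y / max(sd(as.numeric(Y)), 1e-12)
  Y <- Y + with_seed(seed, matrix(rnorm(n * k, sd = 1e-4), n, k))
  eps <- 1e-3
  for (it in seq_len(n_epochs)) {
    alpha <- 1 - (it - 1) / n_epochs
    D2 <- as.matrix(dist(Y))^2
    ad2b <- a * D2^b
    denom <- 1 + ad2b
    # attractive: w * 2ab d^(2b-2) / (1 + a d^2b); repulsive: (1-w) * 2b /
    # ((eps + d^2) (1 + a d^2b))
    att <- G * 2 * a * b * D2^(pmax(b - 1, 0)) / denom
    rep_ <- (1 - G) * 2 * b / ((eps + D2) * denom)
    diag(att) <- 0; diag(rep_) <- 0
    Fc <- att - rep_
    grad <- (diag(rowSums(Fc)) - Fc) %*% Y
    gn <- sqrt(sum(grad^2)) / n
    if (gn > 10) grad <- grad * (10 / gn)
    Y <- Y - alpha * 0.5 * grad
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- paste0("UMAP", seq_len(k) - 1)
  Y
}

# Isomap: k-NN graph geodesics + classical MDS. Disconnected neighbourhood
# graphs are bridged by the shortest inter-component link so the geodesic
# matrix stays finite.
reduce_isomap <- function(x, k, n_neighbors = 5) {
  n <- nrow(x)
  n_neighbors <- min(n_neighbors, n - 1)
  D <- as.matrix(dist(x))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- setdiff(order(D[i, ]), i)[seq_len(n_neighbors)]
    A[i, nb] <- D[i, nb]
  }
  A <- pmax(A, t(A))  # symmetrize
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  while (comp$no > 1) {
    c1 <- which(comp$membership == 1)
    c2 <- which(comp$membership != 1)
    sub <- D[c1, c2, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- c1[ij[1]]; j <- c2[ij[2]]
    A[i, j] <- A[j, i] <- D[i, j]
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    comp <- igraph::components(g)
  }
  GD <- igraph::distances(g)
  emb <- suppressWarnings(cmdscale(GD, k = min(k, n - 1)))
  pad_components(emb, k, "ISOMAP")
}

#' Unsupervised dimensionality reduction to named components
#'
#' Reduces the significant-feature matrix to `n_components` columns named
#' `<METHOD>0 .. <METHOD>9` by one of five methods: PCA, FastICA, exact t-SNE,
#' a UMAP-style fuzzy-graph embedding (neighbours 5, min_dist 0.3), or Isomap
#' (neighbours 5). Seeded methods are reproducible for a fixed seed.
#'
#' @param x Numeric matrix (subjects x features), more subjects than
#'   `n_components`.
#' @param method One of `"PCA"`, `"ICA"`, `"TSNE"`, `"UMAP"`, `"ISOMAP"`.
#' @param n_components Embedding dimension (default 10).
#' @param seed Random seed for the seeded methods (default 12).
#' @return Subjects x `n_components` matrix with named columns.
#' @export
reduce_dimensions <- function(x, method = c("PCA", "ICA", "TSNE", "UMAP",
                                            "ISOMAP"),
                              n_components = 10, seed = 12L) {
  method <- match.arg(method)
  stop_if_not(nrow(x) > n_components,
              "need more subjects than components")
  out <- switch(method,
                PCA = reduce_pca(x, n_components),
                ICA = reduce_ica(x, n_components, seed),
                TSNE = reduce_tsne(x, n_components, seed),
                UMAP = reduce_umap(x, n_components, seed),
                ISOMAP = reduce_isomap(x, n_components))
  rownames(out) <- rownames(x)
  out
}

#' Run all five reducers
#'
#' @inheritParams reduce_dimensions
#' @param methods Reducers to run.
#' @return Named list of embeddings.
#' @export
reduce_all <- function(x, n_components = 10, seed = 12L,
                       methods = c("PCA", "ICA", "TSNE", "UMAP", "ISOMAP")) {
  setNames(lapply(methods, function(m)
    reduce_dimensions(x, m, n_components, seed)), methods)
}
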