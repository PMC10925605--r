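# Shared fixtures and independent oracles, built in code at test time.

# random connected weighted graph (dense positive off-diagonal weights)
random_connectome <- function(n, seed = 1) {
  set.seed(seed)
  raw <- matrix(runif(n * n, 0.2, 1), n)
  diag(raw) <- 0
  symmetrize_connectome(raw)
}

random_ts <- function(T_, n, seed = 1, tr = 1.25) {
  set.seed(seed)
  parcellated_ts(matrix(rnorm(T_ * n), T_, n), tr = tr)
}

# Independent diffusion-map oracle, coded directly from the definition:
# alpha-normalise, row-normalise to a Markov matrix, dense non-symmetric
# eigendecomposition, drop the stationary component, scale lambda/(1-lambda).
# Deliberately avoids the symmetric-conjugate route the package uses.
dme_oracle <- function(w, alpha = 0.5, m = 5) {
  d <- rowSums(w)
  wa <- w / outer(d^alpha, d^alpha)
  da <- rowSums(wa)
  p <- wa / da
  es <- eigen(p)                     # non-symmetric solver
  ord <- order(Re(es$values), decreasing = TRUE)
  vals <- Re(es$values)[ord]
  vecs <- Re(es$vectors)[, ord, drop = FALSE]
  # unit norm under the stationary-weighted inner product (the embedding's
  # normalisation convention), then trivial right-eigenvector -> constant 1
  vecs <- sweep(vecs, 2, sqrt(colSums(da * vecs^2)), `/`)
  vecs <- vecs / vecs[, 1]
  idx <- 1 + seq_len(m)
  g <- sweep(vecs[, idx, drop = FALSE], 2, vals[idx] / (1 - vals[idx]), `*`)
  list(gradients = g, eigenvalues = vals[idx])
}

# FC with a prescribed eigensystem (columns of u orthonormal)
fc_from_modes <- function(u, lambda) {
  m <- u %*% diag(lambda) %*% t(u)
  (m + t(m)) / 2
}

# 4-node scaled Hadamard eigenbasis used in hierarchy tests
hadamard4 <- function() {
  u <- cbind(c(1, 1, 1, 1), c(1, 1, -1, -1), c(1, -1, 1, -1),
             c(1, -1, -1, 1)) / 2
  list(u = u, lambda = c(2, 1, 0.5, 0.25))
}

# equicorrelated correlation matrix
equicorr <- function(n, r) {
  m <- matrix(r, n, n)
  diag(m) <- 1
  m
}
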