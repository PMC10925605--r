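test_that("FC is textbook Pearson correlation with validated input", {
  set.seed(1)
  x <- matrix(rnorm(100 * 8), 100, 8)
  x[, 2] <- x[, 1]                        # identical pair
  x[, 3] <- -x[, 1]                       # negated pair
  fc <- compute_fc(parcellated_ts(x, 1.25))
  expect_equal(fc$matrix[1, 2], 1)
  expect_equal(fc$matrix[1, 3], -1)
  # entrywise formula oracle
  for (i in c(1, 4)) for (j in c(5, 8)) {
    num <- sum((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j])))
    den <- sqrt(sum((x[, i] - mean(x[, i]))^2) * sum((x[, j] - mean(x[, j]))^2))
    expect_lt(abs(fc$matrix[i, j] - num / den), 1e-12)
  }
  expect_equal(unname(diag(fc$matrix)), rep(1, 8))
  x[, 4] <- 2
  expect_error(compute_fc(parcellated_ts(x, 1.25)), "R4")
})

test_that("affinity matrix is a valid symmetric kernel", {
  set.seed(2)
  x <- matrix(rnorm(200 * 8), 200, 8)
  fc <- compute_fc(parcellated_ts(x, 1))
  aff <- build_affinity(fc, density = 0.4)
  expect_true(all(aff >= 0 & aff <= 1))
  expect_equal(unname(diag(aff)), rep(1, 8))
  expect_lt(max(abs(aff - t(aff))), 1e-12)
  # regions from the same correlated cluster are more affine than
  # cross-cluster pairs
  shared <- rnorm(200)
  x2 <- cbind(shared + matrix(rnorm(200 * 4, sd = 0.5), 200, 4),
              -shared + matrix(rnorm(200 * 4, sd = 0.5), 200, 4))
  aff2 <- build_affinity(compute_fc(parcellated_ts(x2, 1)), density = 0.4)
  within <- c(aff2[1, 3], aff2[2, 4], aff2[5, 7], aff2[6, 8])
  across <- c(aff2[1, 5], aff2[2, 6], aff2[3, 7], aff2[4, 8])
  expect_gt(min(within), max(across))
})

test_that("normalized-angle similarity maps cosine -1/0/1 to 0/0.5/1", {
  # exercised through the internal arithmetic on synthetic thresholded rows
  cosvals <- c(-1, 0, 1)
  expect_equal(1 - acos(cosvals) / pi, c(0, 0.5, 1))
})

test_that("row threshold keeps round(density * (N-1)) entries", {
  set.seed(3)
  ts <- random_ts(300, 82, seed = 3)
  fc <- compute_fc(ts)
  aff <- build_affinity(fc, density = 0.10)
  # reimplement the counting rule: k = round(0.1 * 81) = 8
  expect_equal(round(0.10 * 81), 8)
  # and the affinity built from 8-entry rows must differ from denser ones
  aff50 <- build_affinity(fc, density = 0.50)
  expect_false(isTRUE(all.equal(aff, aff50)))
  expect_error(build_affinity(fc, density = 0.001), "k < 1")
})

test_that("diffusion map embedding matches an independent dense oracle", {
  # block-structured affinity: the leading eigenvalues are well separated,
  # so both solvers' eigenvectors are well conditioned
  set.seed(4)
  blocks <- rep(1:3, times = c(4, 6, 10))
  strength <- c(0.95, 0.7, 0.45)[blocks]
  w <- ifelse(outer(blocks, blocks, `==`), outer(strength, strength, pmin),
              0.15) + matrix(runif(400, 0, 0.05), 20)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  emb <- diffusion_map_embedding(w, alpha = 0.5, n_components = 3)
  ora <- dme_oracle(w, alpha = 0.5, m = 3)
  expect_equal(emb$eigenvalues, ora$eigenvalues, tolerance = 1e-8)
  for (k in 1:3) {
    d <- min(max(abs(emb$gradients[, k] - ora$gradients[, k])),
             max(abs(emb$gradients[, k] + ora$gradients[, k])))
    expect_lt(d, 1e-8)
  }
})

test_that("principal gradient separates two weakly coupled blocks by sign", {
  w <- matrix(0.01, 10, 10)
  w[1:5, 1:5] <- 1
  w[6:10, 6:10] <- 1
  diag(w) <- 1
  emb <- diffusion_map_embedding(w, n_components = 3)
  g1 <- emb$gradients[, 1]
  expect_true(all(sign(g1[1:5]) == sign(g1[1])))
  expect_true(all(sign(g1[6:10]) == -sign(g1[1])))
})

test_that("embedding is equivariant to region permutation", {
  set.seed(5)
  w <- matrix(runif(144, 0.1, 1), 12)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  perm <- sample(12)
  emb1 <- diffusion_map_embedding(w, n_components = 4)
  emb2 <- diffusion_map_embedding(w[perm, perm], n_components = 4)
  for (k in 1:4) {
    d <- min(max(abs(emb2$gradients[, k] - emb1$gradients[perm, k])),
             max(abs(emb2$gradients[, k] + emb1$gradients[perm, k])))
    expect_lt(d, 1e-8)
  }
  # markers are invariant
  expect_equal(gradient_range(emb2, 1), gradient_range(emb1, 1),
               tolerance = 1e-10)
  expect_equal(gradient_dispersion(emb2), gradient_dispersion(emb1),
               tolerance = 1e-10)
})

test_that("disconnected affinity is rejected", {
  w <- diag(1, 6)
  w[1:3, 1:3] <- 1
  w[4:6, 4:6] <- 1
  expect_error(diffusion_map_embedding(w), "disconnected")
})

test_that("gradient range arithmetic, sign and scale behaviour", {
  emb <- structure(list(gradients = cbind(c(-0.2, 0.1, 0.3), c(0, 1, 2)),
                        eigenvalues = c(0.6, 0.3),
                        params = list()), class = "gradient_embedding")
  expect_equal(gradient_range(emb, 1), 0.5)
  flipped <- emb
  flipped$gradients[, 1] <- -flipped$gradients[, 1]
  expect_equal(gradient_range(flipped, 1), 0.5)
  scaled <- emb
  scaled$gradients <- emb$gradients * 0.5
  expect_equal(gradient_range(scaled, 1), 0.25)
  expect_error(gradient_range(emb, 5), "out of range")
})

test_that("gradient dispersion equals N * trace of coordinate covariance", {
  pt <- structure(list(gradients = cbind(c(-1, 1), c(0, 0), c(0, 0)),
                       eigenvalues = c(0.5, 0.3, 0.2), params = list()),
                  class = "gradient_embedding")
  expect_equal(gradient_dispersion(pt), 2)
  same <- pt
  same$gradients <- matrix(0.7, 2, 3)
  expect_equal(gradient_dispersion(same), 0)

  set.seed(6)
  g <- matrix(rnorm(30), 10, 3)
  emb <- structure(list(gradients = g, eigenvalues = c(0.5, 0.3, 0.2),
                        params = list()), class = "gradient_embedding")
  n <- nrow(g)
  oracle <- n * sum(diag(stats::cov(g) * (n - 1) / n))   # biased covariance
  expect_lt(abs(gradient_dispersion(emb) - oracle), 1e-12)
  # rotation invariance of the 3-space
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  rot <- emb
  rot$gradients <- g %*% q
  expect_equal(gradient_dispersion(rot), gradient_dispersion(emb),
               tolerance = 1e-10)
  expect_error(gradient_dispersion(emb, m = 4), "exceeds")
})

test_that("principal eigenvalue ratio arithmetic", {
  mk <- function(lam) structure(
    list(gradients = matrix(0, 3, length(lam)), eigenvalues = lam,
         params = list()), class = "gradient_embedding")
  expect_equal(principal_eigenvalue_ratio(mk(0.7)), 1)
  expect_equal(principal_eigenvalue_ratio(mk(rep(0.2, 4))), 0.25)
  expect_equal(principal_eigenvalue_ratio(mk(c(0.5, 0.3, 0.2))), 0.5)
  expect_error(principal_eigenvalue_ratio(mk(numeric(0))), "no eigenvalues")
})

test_that("Markov construction: rows of P sum to one, one unit eigenvalue", {
  set.seed(7)
  w <- matrix(runif(100, 0.1, 1), 10)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  d <- rowSums(w)
  wa <- w / outer(sqrt(d), sqrt(d))
  p <- wa / rowSums(wa)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-12)
  ev <- sort(Re(eigen(p, only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(ev[1], 1, tolerance = 1e-10)
  expect_lt(ev[2], 1 - 1e-8)
  expect_true(all(ev > -1))
})
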