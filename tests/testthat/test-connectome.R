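test_that("symmetrisation averages mirror entries and zeroes the diagonal", {
  sc <- symmetrize_connectome(matrix(c(0, 2, 4, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(sc$weights), matrix(c(0, 3, 3, 0), 2, 2))

  # already-symmetric input is a fixed point
  sym <- random_connectome(6, seed = 3)$weights
  expect_equal(symmetrize_connectome(sym)$weights, sym)

  # random directed matrix: elementwise mean oracle
  set.seed(4)
  raw <- matrix(runif(100, 0.1, 2), 10)
  sc <- symmetrize_connectome(raw)
  oracle <- (raw + t(raw)) / 2
  diag(oracle) <- 0
  expect_equal(unname(sc$weights), oracle, tolerance = 1e-15)
  expect_equal(max(abs(sc$weights - t(sc$weights))), 0)
})

test_that("disconnected or isolated inputs are rejected by name", {
  w <- diag(0, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  expect_error(symmetrize_connectome(w), "disconnected")
  w2 <- matrix(1, 3, 3)
  w2[, 3] <- w2[3, ] <- 0
  expect_error(symmetrize_connectome(w2), "R3")
})

test_that("normalised Laplacian matches closed-form spectra", {
  # single edge
  lap <- build_normalized_laplacian(
    symmetrize_connectome(matrix(c(0, 1, 1, 0), 2)))
  expect_equal(unname(lap), matrix(c(1, -1, -1, 1), 2))
  expect_equal(eigen(lap, symmetric = TRUE, only.values = TRUE)$values,
               c(2, 0))

  # complete graph K_n: eigenvalues 0 and n/(n-1)
  k3 <- symmetrize_connectome(matrix(1, 3, 3) - diag(3))
  ev <- sort(eigen(build_normalized_laplacian(k3), symmetric = TRUE,
                   only.values = TRUE)$values)
  expect_equal(ev, c(0, 1.5, 1.5))

  # unit-weight ring of 8: circulant closed form 1 - cos(2*pi*k/8)
  ring <- diag(0, 8)
  for (i in 1:8) {
    j <- i %% 8 + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  ev <- sort(eigen(build_normalized_laplacian(symmetrize_connectome(ring)),
                   symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, sort(1 - cos(2 * pi * (0:7) / 8)), tolerance = 1e-12)

  # structural invariants: unit diagonal, eigenvalues in [0, 2]
  lap <- build_normalized_laplacian(random_connectome(12, seed = 8))
  expect_equal(unname(diag(lap)), rep(1, 12))
  ev <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12 & ev < 2 + 1e-12))
})

test_that("harmonic basis is complete, orthonormal, and reconstructs", {
  sc <- random_connectome(20, seed = 21)
  lap <- build_normalized_laplacian(sc)
  basis <- compute_harmonic_basis(lap)
  n <- 20
  expect_length(basis$eigenvalues, n)
  expect_lt(abs(basis$eigenvalues[1]), 1e-10)
  expect_true(all(diff(basis$eigenvalues) >= -1e-12))
  phi <- basis$eigenvectors
  expect_lt(max(abs(crossprod(phi) - diag(n))), 1e-8)
  recon <- phi %*% diag(basis$eigenvalues) %*% t(phi)
  expect_lt(max(abs(recon - lap)), 1e-8)
  # uniform mode proportional to D^(1/2) 1
  d <- sqrt(rowSums(sc$weights))
  u <- d / sqrt(sum(d^2))
  expect_lt(min(max(abs(phi[, 1] - u)), max(abs(phi[, 1] + u))), 1e-8)
  # sign convention: largest-magnitude entry positive
  for (k in 1:n) expect_gt(phi[which.max(abs(phi[, k])), k], 0)
  expect_error(compute_harmonic_basis(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("two-node basis matches the closed form", {
  basis <- compute_harmonic_basis(build_normalized_laplacian(
    symmetrize_connectome(matrix(c(0, 1, 1, 0), 2))))
  expect_equal(basis$eigenvalues, c(0, 2))
  expect_equal(abs(unname(basis$eigenvectors)),
               matrix(1 / sqrt(2), 2, 2), tolerance = 1e-12)
})

test_that("timepoint decomposition projects, reconstructs, and is Parseval", {
  basis <- compute_harmonic_basis(build_normalized_laplacian(
    random_connectome(15, seed = 30)))
  # F_t = phi_5 at every timepoint -> coefficient 1 in mode 5 only
  x <- matrix(rep(basis$eigenvectors[, 5], 10), 10, 15, byrow = TRUE)
  spec <- decompose_timeseries(
    parcellated_ts(x, 1.25, region_labels = basis$region_labels), basis)
  expect_lt(max(abs(spec$coefficients[, 5] - 1)), 1e-10)
  expect_lt(max(abs(spec$coefficients[, -5])), 1e-10)

  # random signal: dot-product oracle, reconstruction, Parseval
  set.seed(31)
  x <- matrix(rnorm(20 * 15), 20, 15)
  ts <- parcellated_ts(x, 1.25, region_labels = basis$region_labels)
  spec <- decompose_timeseries(ts, basis)
  for (t_ in c(1, 7, 20)) {
    oracle <- vapply(1:15, function(k) sum(x[t_, ] * basis$eigenvectors[, k]),
                     numeric(1))
    expect_lt(max(abs(spec$coefficients[t_, ] - oracle)), 1e-10)
  }
  recon <- spec$coefficients %*% t(basis$eigenvectors)
  expect_lt(max(abs(recon - x)), 1e-8)
  parseval <- rowSums(spec$coefficients^2) / rowSums(x^2)
  expect_lt(max(abs(parseval - 1)), 1e-10)
})

test_that("power and energy follow their defining arithmetic", {
  basis <- compute_harmonic_basis(build_normalized_laplacian(
    random_connectome(6, seed = 40)))
  # omega = -2 on a mode with lambda = 3: power 2, energy 36
  fake <- structure(list(
    coefficients = matrix(-2, 1, 1), power = matrix(2, 1, 1),
    energy = matrix((-2)^2 * 3^2, 1, 1), eigenvalues = 3),
    class = "harmonic_spectrum")
  expect_equal(fake$energy[1, 1], 36)
  set.seed(41)
  x <- matrix(rnorm(12 * 6), 12, 6)
  spec <- decompose_timeseries(
    parcellated_ts(x, 1, region_labels = basis$region_labels), basis)
  expect_equal(spec$power, abs(spec$coefficients))
  expect_equal(spec$energy,
               sweep(spec$coefficients^2, 2, basis$eigenvalues^2, `*`))
  # energy of the uniform mode is exactly zero
  expect_true(all(spec$energy[, 1] == 0))
})

test_that("scan energy: closed forms, Monte-Carlo expectation, monotonicity", {
  basis <- compute_harmonic_basis(build_normalized_laplacian(
    random_connectome(10, seed = 50)))
  lam <- basis$eigenvalues

  # signal spanned by the uniform mode alone -> zero energy
  x <- matrix(rep(3 * basis$eigenvectors[, 1], 5), 5, 10, byrow = TRUE)
  spec <- decompose_timeseries(
    parcellated_ts(x, 1, region_labels = basis$region_labels), basis)
  expect_equal(scan_energy(spec), 0, tolerance = 1e-20)

  # unit coefficient on mode k every timepoint -> energy lambda_k^2
  x <- matrix(rep(basis$eigenvectors[, 4], 5), 5, 10, byrow = TRUE)
  spec <- decompose_timeseries(
    parcellated_ts(x, 1, region_labels = basis$region_labels), basis)
  expect_equal(scan_energy(spec), lam[4]^2, tolerance = 1e-10)

  # iid normal coefficients: E[scan energy] = sum sigma_k^2 lambda_k^2
  sigma <- seq(0.2, 2, length.out = 10)
  ts <- generate_timeseries(basis, sigma, T_ = 10000, seed = 51)
  spec <- decompose_timeseries(ts, basis)
  expected <- sum(sigma^2 * lam^2)
  expect_lt(abs(scan_energy(spec) - expected) / expected, 0.05)

  # moving mass from a low-lambda to a high-lambda mode at fixed power
  # cannot decrease energy
  lo <- structure(list(energy = matrix(1 * lam[2]^2, 1, 1)),
                  class = "harmonic_spectrum")
  hi <- structure(list(energy = matrix(1 * lam[9]^2, 1, 1)),
                  class = "harmonic_spectrum")
  expect_gte(scan_energy(hi), scan_energy(lo))
})

test_that("decomposition enforces label alignment", {
  basis <- compute_harmonic_basis(build_normalized_laplacian(
    random_connectome(5, seed = 60)))
  ts <- random_ts(10, 5, seed = 61)          # labels R1..R5 but order checked
  ts$region_labels <- rev(basis$region_labels)
  colnames(ts$data) <- ts$region_labels
  expect_error(decompose_timeseries(ts, basis), "labels")
  ts4 <- random_ts(10, 4, seed = 62)
  expect_error(decompose_timeseries(ts4, basis), "mismatch")
})

test_that("connectome TSV round-trips", {
  sc <- random_connectome(7, seed = 70)
  path <- tempfile(fileext = ".tsv")
  write_connectome(sc, path)
  back <- read_connectome(path)
  expect_equal(back$region_labels, sc$region_labels)
  expect_equal(back$weights, sc$weights, tolerance = 1e-7)
})
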