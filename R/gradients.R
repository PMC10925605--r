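#' Functional connectivity matrix
#'
#' Pearson correlation between every pair of regional time series of a run.
#'
#' @param ts A [parcellated_ts()] with at least 3 timepoints.
#' @return An object of class `functional_connectivity`: `matrix` (N x N,
#'   symmetric, unit diagonal) and `region_labels`.
#' @export
compute_fc <- function(ts) {
  stopifnot(inherits(ts, "parcellated_ts"))
  if (nrow(ts$data) < 3L) stop("need at least 3 timepoints to estimate FC")
  v <- apply(ts$data, 2L, stats::var)
  if (any(v < .Machine$double.eps))
    stop("zero-variance region(s): ",
         paste(ts$region_labels[v < .Machine$double.eps], collapse = ", "))
  m <- stats::cor(ts$data)
  structure(list(matrix = m, region_labels = ts$region_labels),
            class = "functional_connectivity")
}

#' Affinity matrix from row-thresholded Fisher-z FC
#'
#' Converts an FC matrix into the non-negative similarity graph used by
#' diffusion map embedding. Off-diagonal correlations are Fisher
#' z-transformed (the diagonal is set to 0 and |r| is clipped to `1 - 1e-7`
#' to keep the transform finite). Each row then retains only its
#' `k = round(density * (N - 1))` largest signed entries (ties broken by the
#' lower column index), all others set to zero. The affinity between regions
#' i and j is the similarity between their thresholded connectivity rows:
#' the normalised-angle kernel `1 - acos(cos_sim) / pi` (in `[0, 1]`), or
#' plain cosine similarity with negative values clipped at 0. Row-wise
#' thresholding is asymmetric, but the row-to-row similarity restores a
#' symmetric matrix with unit diagonal.
#'
#' @param fc A [compute_fc()] result.
#' @param density Fraction of off-diagonal entries retained per row
#'   (default 0.10).
#' @param kernel `"normalized_angle"` (default) or `"cosine"`.
#' @return Symmetric non-negative N x N affinity matrix, unit diagonal.
#' @export
build_affinity <- function(fc, density = 0.10,
                           kernel = c("normalized_angle", "cosine")) {
  stopifnot(inherits(fc, "functional_connectivity"))
  kernel <- match.arg(kernel)
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("density must lie in (0, 1]")
  r <- fc$matrix
  n <- nrow(r)
  k <- round(density * (n - 1))
  if (k < 1) stop("density ", density, " retains no entries per row (k < 1)")

  z <- r
  diag(z) <- 0
  z <- pmin(pmax(z, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(z)
  diag(z) <- 0

  thr <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- z[i, ]
    row[i] <- -Inf                             # never retain the diagonal
    top <- order(row, decreasing = TRUE)[seq_len(k)]  # stable: ties by index
    thr[i, top] <- z[i, top]
  }

  norms <- sqrt(rowSums(thr^2))
  if (any(norms == 0))
    stop("thresholded connectivity row(s) are all zero: ",
         paste(fc$region_labels[norms == 0], collapse = ", "))
  cosim <- tcrossprod(thr) / tcrossprod(norms)
  cosim <- pmin(pmax(cosim, -1), 1)
  aff <- switch(kernel,
                normalized_angle = 1 - acos(cosim) / pi,
                cosine = pmax(cosim, 0))
  diag(aff) <- 1
  dimnames(aff) <- list(fc$region_labels, fc$region_labels)
  (aff + t(aff)) / 2
}

#' Diffusion map embedding of an affinity matrix
#'
#' Embeds regions into a low-dimensional space in which proximity reflects
#' similarity of whole-brain connectivity profiles. The affinity `W` is
#' alpha-normalised, `W' = D^(-alpha) W D^(-alpha)` with `D` the diagonal of
#' row sums (`alpha = 0.5` balances local and global geometry), and turned
#' into the Markov transition matrix `P` by row normalisation. `P` is
#' diagonalised through its symmetric conjugate; the trivial eigenvalue-1
#' constant eigenvector is dropped and each remaining eigenvector (normalised
#' so the trivial one is the constant 1) is scaled by
#' `lambda / (1 - lambda)` when `diffusion_time = 0` (the multiscale
#' convention), or by `lambda^diffusion_time` otherwise. The sign convention
#' of [compute_harmonic_basis()] is applied.
#'
#' @param affinity Symmetric non-negative matrix from [build_affinity()].
#' @param alpha Anisotropic diffusion parameter in `[0, 1]` (default 0.5).
#' @param n_components Number of embedding components to retain (default 10).
#' @param diffusion_time Diffusion time `t >= 0`; 0 selects the multiscale
#'   `lambda / (1 - lambda)` scaling.
#' @return An object of class `gradient_embedding`: `gradients` (N x m,
#'   columns ordered by descending eigenvalue), `eigenvalues` (length m),
#'   `params`.
#' @export
diffusion_map_embedding <- function(affinity, alpha = 0.5, n_components = 10,
                                    diffusion_time = 0) {
  w <- as.matrix(affinity)
  n <- nrow(w)
  if (any(w < -1e-12)) stop("affinity must be non-negative")
  if (max(abs(w - t(w))) > 1e-10) stop("affinity must be symmetric")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")

  d <- rowSums(w)
  if (any(d <= 0)) stop("affinity has an all-zero row")
  wa <- w * tcrossprod(d^(-alpha))             # alpha-normalisation
  da <- rowSums(wa)
  s <- wa * tcrossprod(1 / sqrt(da))           # symmetric conjugate of P
  s <- (s + t(s)) / 2
  es <- eigen(s, symmetric = TRUE)             # eigenvalues descending

  if (sum(es$values > 1 - 1e-8) > 1L)
    stop("affinity graph is disconnected (eigenvalue 1 has multiplicity > 1)")

  # eigenvectors of P; normalise so the trivial eigenvector is constant 1
  psi <- es$vectors / sqrt(da)
  psi <- psi / psi[, 1L]

  m <- min(n_components, n - 1L)
  idx <- 1L + seq_len(m)                       # drop the trivial component
  lam <- es$values[idx]
  scale_k <- if (diffusion_time == 0) lam / (1 - lam) else lam^diffusion_time
  grads <- sweep(psi[, idx, drop = FALSE], 2L, scale_k, `*`)
  grads <- fix_eigenvector_signs(grads)
  labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  dimnames(grads) <- list(labels, paste0("gradient", seq_len(m)))
  structure(
    list(gradients = grads, eigenvalues = lam,
         params = list(alpha = alpha, n_components = m,
                       diffusion_time = diffusion_time)),
    class = "gradient_embedding"
  )
}

#' @export
print.gradient_embedding <- function(x, ...) {
  cat("Gradient embedding:", nrow(x$gradients), "regions x",
      ncol(x$gradients), "components; eigenvalues",
      paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Gradient range
#'
#' Difference between the maximum and minimum region coordinates along one
#' embedding component. The range of the principal gradient is interpreted as
#' the depth of the cortical processing hierarchy.
#'
#' @param emb A [diffusion_map_embedding()] result.
#' @param k Component index (1 = principal gradient).
#' @return Non-negative scalar, invariant to a global sign flip.
#' @export
gradient_range <- function(emb, k = 1L) {
  stopifnot(inherits(emb, "gradient_embedding"))
  if (k < 1L || k > ncol(emb$gradients))
    stop("component index k = ", k, " out of range (1..",
         ncol(emb$gradients), ")")
  g <- emb$gradients[, k]
  max(g) - min(g)
}

#' Gradient dispersion
#'
#' Sum of squared Euclidean distances of all regions to the centroid in the
#' space of the first `m` gradients (default 3). Invariant to rotation and
#' sign of that space.
#'
#' @param emb A [diffusion_map_embedding()] result.
#' @param m Number of leading components (default 3).
#' @return Non-negative scalar.
#' @export
gradient_dispersion <- function(emb, m = 3L) {
  stopifnot(inherits(emb, "gradient_embedding"))
  if (m > ncol(emb$gradients))
    stop("m = ", m, " exceeds available components (", ncol(emb$gradients), ")")
  g <- emb$gradients[, seq_len(m), drop = FALSE]
  centred <- sweep(g, 2L, colMeans(g))
  sum(centred^2)
}

#' Principal-eigenvalue ratio
#'
#' Ratio of the eigenvalue of the first gradient to the sum of the retained
#' embedding eigenvalues; the relative importance of the principal gradient.
#'
#' @param emb A [diffusion_map_embedding()] result.
#' @return Scalar in `(0, 1]`.
#' @export
principal_eigenvalue_ratio <- function(emb) {
  stopifnot(inherits(emb, "gradient_embedding"))
  lam <- emb$eigenvalues
  if (length(lam) == 0L) stop("embedding has no eigenvalues")
  lam[1L] / sum(lam)
}
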