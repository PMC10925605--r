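#' Structural connectome container and symmetrisation
#'
#' Builds a [`structural_connectome`] from a (possibly directed) non-negative
#' weight matrix by averaging entries above and below the diagonal,
#' `(C + t(C)) / 2`, forcing a zero diagonal, and checking that the resulting
#' undirected graph is connected with no isolated region. Symmetry guarantees
#' a real eigendecomposition of the graph Laplacian.
#'
#' @param raw Square non-negative numeric matrix of connection strengths.
#' @param region_labels Region names; defaults to row names or `"R1"..."RN"`.
#' @return An object of class `structural_connectome` with elements `weights`
#'   (symmetric, zero-diagonal) and `region_labels`.
#' @examples
#' sc <- symmetrize_connectome(matrix(c(0, 2, 4, 0), 2, 2, byrow = TRUE))
#' sc$weights
#' @export
symmetrize_connectome <- function(raw, region_labels = NULL) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("connectome matrix must be square")
  if (!all(is.finite(raw))) stop("connectome contains non-finite values")
  if (any(raw < 0)) stop("connectome contains negative weights")
  w <- (raw + t(raw)) / 2
  diag(w) <- 0
  if (is.null(region_labels)) {
    region_labels <- rownames(raw)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(w)))
  }
  region_labels <- as.character(region_labels)
  stopifnot(length(region_labels) == nrow(w))
  dimnames(w) <- list(region_labels, region_labels)

  deg <- rowSums(w)
  if (any(deg <= 0))
    stop("isolated region(s) with zero degree: ",
         paste(region_labels[deg <= 0], collapse = ", "))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    small <- which(comp$membership == which.min(comp$csize))
    stop("structural connectome is disconnected (", comp$no,
         " components); smallest component: ",
         paste(region_labels[small], collapse = ", "))
  }
  structure(list(weights = w, region_labels = region_labels),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat("Structural connectome:", nrow(x$weights), "regions,",
      sum(x$weights > 0) / 2, "undirected edges\n")
  invisible(x)
}

#' Symmetric normalised graph Laplacian
#'
#' Computes the symmetric normalised Laplacian of the structural connectome,
#' `D^(-1/2) (D - C) D^(-1/2)`, where `D` is the diagonal degree (strength)
#' matrix. Its eigenvalues lie in `[0, 2]`, with 0 attained by the uniform
#' mode `D^(1/2) 1` for a connected graph, and its diagonal entries equal 1.
#'
#' @param sc A [symmetrize_connectome()] result.
#' @return Symmetric N x N Laplacian matrix with region dimnames.
#' @export
build_normalized_laplacian <- function(sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  w <- sc$weights
  deg <- rowSums(w)
  if (any(deg <= 0)) stop("zero-degree region: cannot normalise Laplacian")
  dinv <- 1 / sqrt(deg)
  lap <- -w * tcrossprod(dinv)
  diag(lap) <- 1
  # exact symmetry for the eigensolver
  (lap + t(lap)) / 2
}

#' Harmonic basis: Laplacian eigenmodes of the structural connectome
#'
#' Full eigendecomposition of the symmetric normalised Laplacian. Each
#' eigenvector ("harmonic mode") is a whole-cortex spatial pattern; its
#' eigenvalue indexes spatial frequency, from the uniform zero-eigenvalue mode
#' to fine-grained high-frequency patterns. The number of modes equals the
#' number of regions. A deterministic sign convention is applied: each mode is
#' flipped so that its largest-magnitude entry is positive (ties resolved by
#' the lowest region index). Eigenvectors within a numerically degenerate
#' eigenvalue subspace are solver-dependent up to rotation; aggregate
#' power/energy quantities are unaffected but individual mode patterns are
#' then not unique.
#'
#' @param laplacian Symmetric Laplacian matrix from
#'   [build_normalized_laplacian()].
#' @return An object of class `harmonic_basis`: `eigenvectors` (N x N, column
#'   k = mode k), `eigenvalues` (ascending, first ~0), `region_labels`.
#' @export
compute_harmonic_basis <- function(laplacian) {
  laplacian <- as.matrix(laplacian)
  if (max(abs(laplacian - t(laplacian))) > 1e-10)
    stop("Laplacian must be symmetric")
  es <- eigen(laplacian, symmetric = TRUE)
  ord <- rev(seq_along(es$values))            # ascending eigenvalues
  vals <- es$values[ord]
  vals[abs(vals) < 1e-12] <- 0                # uniform mode: exactly zero
  vecs <- es$vectors[, ord, drop = FALSE]
  vecs <- fix_eigenvector_signs(vecs)
  labels <- rownames(laplacian)
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(laplacian)))
  rownames(vecs) <- labels
  colnames(vecs) <- paste0("mode", seq_along(vals))
  structure(list(eigenvectors = vecs, eigenvalues = vals,
                 region_labels = labels),
            class = "harmonic_basis")
}

#' @export
print.harmonic_basis <- function(x, ...) {
  cat("Harmonic basis:", length(x$eigenvalues), "modes, eigenvalues in [",
      signif(min(x$eigenvalues), 4), ",", signif(max(x$eigenvalues), 4), "]\n")
  invisible(x)
}

# Deterministic sign convention shared by all eigendecompositions in the
# package: flip each column so its largest-magnitude entry is positive,
# breaking magnitude ties by the lowest row index.
fix_eigenvector_signs <- function(v) {
  for (k in seq_len(ncol(v))) {
    i <- which.max(abs(v[, k]))               # which.max returns first max
    if (v[i, k] < 0) v[, k] <- -v[, k]
  }
  v
}

#' Harmonic decomposition of a BOLD run
#'
#' Projects each timepoint of a parcellated BOLD run onto the harmonic modes
#' of the structural connectome: `omega_k(t) = <F_t, phi_k>`. Because the
#' basis is orthonormal the decomposition is exact
#' (`F_t = sum_k omega_k(t) phi_k`) and satisfies Parseval's identity. The
#' power of mode k at time t is `|omega_k(t)|` and its energy is
#' `omega_k(t)^2 * lambda_k^2`, combining contribution magnitude with the
#' mode's intrinsic spatial frequency; the uniform mode (`lambda = 0`)
#' carries zero energy by construction.
#'
#' @param ts A [parcellated_ts()] whose region labels match the basis.
#' @param basis A [compute_harmonic_basis()] result.
#' @return An object of class `harmonic_spectrum`: `coefficients` (T x N
#'   matrix of omega), `power`, `energy` (same shape), `eigenvalues`.
#' @export
decompose_timeseries <- function(ts, basis) {
  stopifnot(inherits(ts, "parcellated_ts"), inherits(basis, "harmonic_basis"))
  if (ncol(ts$data) != length(basis$region_labels))
    stop("region count mismatch: run has ", ncol(ts$data), ", basis has ",
         length(basis$region_labels))
  if (!identical(ts$region_labels, basis$region_labels))
    stop("region labels of run and harmonic basis do not match")
  omega <- ts$data %*% basis$eigenvectors     # T x N, row t = Phi' F_t
  energy <- sweep(omega^2, 2L, basis$eigenvalues^2, `*`)
  structure(list(coefficients = omega, power = abs(omega), energy = energy,
                 eigenvalues = basis$eigenvalues),
            class = "harmonic_spectrum")
}

#' Scan-level harmonic energy
#'
#' Summarises a run's harmonic spectrum as a single scalar: the energy summed
#' over modes at each timepoint, averaged over timepoints. Higher values
#' indicate that activity loads more on high-spatial-frequency modes, i.e. is
#' weighted further from the structurally smoothest patterns. Zero exactly
#' when the signal is spanned by the uniform mode alone.
#'
#' @param spectrum A [decompose_timeseries()] result.
#' @return Non-negative scalar.
#' @export
scan_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  if (nrow(spectrum$energy) == 0L) stop("empty harmonic spectrum")
  mean(rowSums(spectrum$energy))
}

#' Per-mode time-averaged energy
#'
#' Mean energy of each harmonic mode over timepoints; the energy-versus-
#' spatial-frequency profile of a run.
#'
#' @param spectrum A [decompose_timeseries()] result.
#' @return Numeric vector of length N (modes, ascending eigenvalue).
#' @export
mode_energy_profile <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  colMeans(spectrum$energy)
}

#' Read / write a structural connectome matrix
#'
#' TSV square matrix with a region-label header row and a leading label
#' column.
#'
#' @param path TSV file path.
#' @return `read_connectome()` returns a [symmetrize_connectome()] result.
#' @export
read_connectome <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!identical(rownames(m), colnames(m)))
    stop("connectome row and column labels differ")
  symmetrize_connectome(m, region_labels = rownames(m))
}

#' @rdname read_connectome
#' @param sc A `structural_connectome`.
#' @export
write_connectome <- function(sc, path) {
  stopifnot(inherits(sc, "structural_connectome"))
  df <- data.frame(region = sc$region_labels,
                   signif(sc$weights, 8), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
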