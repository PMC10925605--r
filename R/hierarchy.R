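#' Eigenmodes of functional connectivity
#'
#' Full eigendecomposition `FC = U Lambda U'` of a symmetric FC matrix, with
#' eigenvalues sorted in descending order and the package-wide deterministic
#' sign convention applied to the eigenvectors. The trace identity
#' `sum(Lambda) = N` holds for a correlation matrix. A warning is emitted when
#' consecutive eigenvalues are numerically degenerate, since the associated
#' eigenvectors (and therefore the sign partition) are then solver-dependent.
#'
#' @param fc A [compute_fc()] result or symmetric numeric matrix.
#' @return List with `values` (descending), `vectors` (columns = eigenmodes),
#'   `region_labels`.
#' @export
fc_eigenmodes <- function(fc) {
  m <- if (inherits(fc, "functional_connectivity")) fc$matrix else as.matrix(fc)
  labels <- if (inherits(fc, "functional_connectivity")) fc$region_labels
            else rownames(m)
  if (max(abs(m - t(m))) > 1e-10) stop("FC matrix must be symmetric")
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (any(abs(diff(es$values)) < 1e-10))
    warning("numerically degenerate FC eigenvalues: nested sign partition ",
            "is solver-dependent within the degenerate subspace")
  vecs <- fix_eigenvector_signs(es$vectors)
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(m)))
  rownames(vecs) <- labels
  list(values = es$values, vectors = vecs, region_labels = labels)
}

#' Nested sign partition of FC eigenmodes
#'
#' Builds the hierarchy of nested modules implied by the sign structure of
#' successive FC eigenvectors. Level 1 is the single whole-cortex module
#' (the first eigenmode has a single sign over the cortex). At each level
#' `i >= 2`, every module from level `i - 1` is split into its
#' non-negative-sign and negative-sign subsets under eigenvector `i`
#' (exactly-zero entries count as non-negative); empty subsets are dropped,
#' so a module whose members share a sign passes through unsplit. Module
#' counts are therefore non-decreasing, and generic eigenvectors drive the
#' partition to all singletons.
#'
#' @param modes A [fc_eigenmodes()] result (or list with `vectors`).
#' @return An object of class `sign_hierarchy`: `n_modules` (M_i per level),
#'   `sizes` (list of module-size vectors), `membership` (N x N matrix,
#'   column i = region-to-module map at level i), `corrections` (p_i per
#'   level).
#' @export
nested_sign_partition <- function(modes) {
  u <- modes$vectors
  n <- nrow(u)
  membership <- matrix(NA_integer_, n, n)
  membership[, 1L] <- 1L
  for (i in 2L:n) {
    pos <- u[, i] >= 0
    # split each parent module by sign; renumber in parent-then-sign order
    key <- membership[, i - 1L] * 2L - as.integer(pos)
    membership[, i] <- match(key, sort(unique(key)))
  }
  sizes <- lapply(seq_len(n), function(i) as.integer(table(membership[, i])))
  n_modules <- vapply(sizes, length, integer(1))
  corrections <- vapply(sizes, size_correction_factor, numeric(1), N = n)
  structure(list(n_modules = n_modules, sizes = sizes,
                 membership = membership, corrections = corrections),
            class = "sign_hierarchy")
}

#' Modular-size correction factor
#'
#' Deviation of a partition's module sizes from homogeneity:
#' `p = sum_j |m_j - N / M| / N` for `M` modules of sizes `m_j` summing to
#' `N`. Zero for equal-sized modules; larger values penalise lopsided
#' partitions, which are less genuinely segregated than balanced ones.
#'
#' @param sizes Integer vector of module sizes.
#' @param N Total number of regions (`sum(sizes)`).
#' @return Scalar in `[0, 2)`.
#' @export
size_correction_factor <- function(sizes, N) {
  if (length(sizes) == 0L) stop("empty module-size vector")
  if (sum(sizes) != N) stop("module sizes must sum to N")
  sum(abs(sizes - N / length(sizes))) / N
}

#' Hierarchical decomposition of functional connectivity
#'
#' Convenience wrapper chaining [fc_eigenmodes()] and
#' [nested_sign_partition()] and attaching the integration and segregation
#' summaries.
#'
#' @param fc A [compute_fc()] result or symmetric FC matrix.
#' @return An object of class `hierarchy_decomposition` with `values`,
#'   `vectors`, `hierarchy` (a `sign_hierarchy`), `h_in`, `h_se`.
#' @export
hierarchy_decomposition <- function(fc) {
  modes <- fc_eigenmodes(fc)
  hier <- nested_sign_partition(modes)
  out <- structure(list(values = modes$values, vectors = modes$vectors,
                        region_labels = modes$region_labels,
                        hierarchy = hier),
                   class = "hierarchy_decomposition")
  out$h_in <- hierarchical_integration(out)
  out$h_se <- hierarchical_segregation(out)
  out
}

#' Hierarchical integration
#'
#' Contribution of the first FC eigenmode - the whole-cortex module - to
#' total covariance: `H_In = Lambda_1^2 * M_1 * (1 - p_1) / N^2`, which with
#' a single whole-cortex module (`M_1 = 1`, `p_1 = 0`) reduces to
#' `Lambda_1^2 / N^2`. Equals 1 for a perfectly integrated (all-ones
#' correlation) matrix and approaches `1 / N^2` as correlations vanish.
#'
#' @param decomp A [hierarchy_decomposition()] result.
#' @return Scalar in `[0, 1]` for correlation FC.
#' @export
hierarchical_integration <- function(decomp) {
  stopifnot(inherits(decomp, "hierarchy_decomposition"))
  n <- length(decomp$values)
  lam1 <- max(decomp$values[1L], 0)           # clamp numerical negatives
  h <- decomp$hierarchy
  lam1^2 * h$n_modules[1L] * (1 - h$corrections[1L]) / n^2
}

#' Hierarchical segregation
#'
#' Summed contributions of all non-global eigenmodes, each weighted by its
#' module count and corrected for heterogeneous module sizes:
#' `H_Se = sum_{i>=2} Lambda_i^2 * M_i * (1 - p_i) / N^2`. Zero when all
#' covariance is carried by the whole-cortex mode. Tiny negative eigenvalues
#' arising from numerical error are clamped to zero before squaring.
#'
#' @param decomp A [hierarchy_decomposition()] result.
#' @return Non-negative scalar.
#' @export
hierarchical_segregation <- function(decomp) {
  stopifnot(inherits(decomp, "hierarchy_decomposition"))
  n <- length(decomp$values)
  if (n < 2L) return(0)
  h <- decomp$hierarchy
  lam <- pmax(decomp$values, 0)
  idx <- 2L:n
  sum(lam[idx]^2 * h$n_modules[idx] * (1 - h$corrections[idx])) / n^2
}
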