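#' Min-max normalise marker columns within each dataset
#'
#' Before pooling runs acquired with different scanners/contrast agents, each
#' marker column is rescaled to `[0, 1]` separately within each dataset:
#' `x <- (x - min(x)) / max(x - min(x))`.
#'
#' @param table Data frame with one row per run.
#' @param markers Character vector of marker column names to rescale.
#' @param by Name of the grouping (dataset) column.
#' @return The table with rescaled marker columns.
#' @export
normalize_markers <- function(table,
                              markers = c("gradient_range",
                                          "hierarchical_integration",
                                          "harmonic_energy"),
                              by = "dataset") {
  stopifnot(is.data.frame(table), by %in% names(table),
            all(markers %in% names(table)))
  for (grp in unique(table[[by]])) {
    rows <- table[[by]] == grp
    for (m in markers) {
      x <- table[[m]][rows]
      if (any(!is.finite(x))) stop("non-finite values in marker `", m, "`")
      shifted <- x - min(x)
      top <- max(shifted)
      if (top <= 0)
        stop("marker `", m, "` is constant within dataset `", grp,
             "`; cannot min-max normalise")
      table[[m]][rows] <- shifted / top
    }
  }
  table
}

# R^2 (or adjusted R^2, or McFadden pseudo-R^2 for binary y) of y on a
# predictor subset. Empty subset = intercept-only model (fit 0).
subset_fit <- function(X, y, cols, fit_metric = "r2") {
  if (fit_metric == "mcfadden") {
    ll0 <- logLik_binary(y, rep(mean(y), length(y)))
    if (length(cols) == 0L) return(0)
    # perfect separation is legitimate on well-separated data; the fitted
    # probabilities saturate and McFadden's measure tends to 1
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X[, cols, drop = FALSE]), y,
                     family = stats::binomial()))
    return(1 - logLik_binary(y, fit$fitted.values) / ll0)
  }
  if (length(cols) == 0L) return(0)
  Xs <- cbind(1, X[, cols, drop = FALSE])
  fit <- stats::lm.fit(Xs, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  if (fit_metric == "adj_r2") {
    n <- length(y); p <- length(cols)
    r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  r2
}

logLik_binary <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Dominance analysis of a linear (or logistic) model
#'
#' Partitions the explained variance of a regression of `y` on `p`
#' predictors among the predictors, by fitting all `2^p - 1` non-empty
#' predictor subsets. The total dominance of predictor j is the average over
#' subset sizes `s = 0 ... p-1` of the mean incremental fit obtained by
#' adding j to size-s subsets that exclude it. With `fit_metric = "r2"`
#' (default) total dominances sum exactly to the full-model R-squared;
#' relative importance expresses each dominance as a percentage of that sum.
#' `fit_metric = "adj_r2"` averages adjusted-R-squared increments instead
#' (additivity then holds only approximately), and `fit_metric = "mcfadden"`
#' runs the classification variant: logistic regression on a binary `y`
#' scored by McFadden's pseudo-R-squared.
#'
#' @param X Numeric matrix or data frame of predictors (n x p).
#' @param y Numeric response of length n (binary for `"mcfadden"`).
#' @param fit_metric `"r2"`, `"adj_r2"`, or `"mcfadden"`.
#' @return An object of class `dominance_result`: `total_dominance` (named,
#'   sums to the full-model fit under `"r2"`), `relative_importance` (named
#'   percentages summing to 100), `r2_full`, `adj_r2_full` (linear metrics
#'   only), `n_models` (`2^p - 1`), `fit_metric`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- X %*% c(2, 1, 0.2) + rnorm(40)
#' dominance_analysis(X, y)
#' @export
dominance_analysis <- function(X, y, fit_metric = c("r2", "adj_r2",
                                                    "mcfadden")) {
  fit_metric <- match.arg(fit_metric)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= p) stop("need more observations than predictors (n > p)")
  if (qr(cbind(1, X))$rank < p + 1L)
    stop("rank-deficient design: predictors are collinear")
  if (fit_metric == "mcfadden" && !all(y %in% c(0, 1)))
    stop("fit_metric \"mcfadden\" requires a binary 0/1 response")

  # fit every non-empty subset once, keyed by bitmask
  n_sub <- as.integer(2^p - 1)
  fits <- numeric(n_sub)
  masks <- seq_len(n_sub)
  cols_of <- lapply(masks, function(m) which(bitwAnd(m, 2L^(seq_len(p) - 1L)) > 0L))
  for (m in masks) fits[m] <- subset_fit(X, y, cols_of[[m]], fit_metric)

  dominance <- numeric(p)
  for (j in seq_len(p)) {
    bit_j <- 2L^(j - 1L)
    # increments stratified by subset size s = 0..p-1
    incr_by_size <- vector("list", p)
    # s = 0: marginal fit of j alone
    incr_by_size[[1L]] <- fits[bit_j] - 0
    for (m in masks) {
      if (bitwAnd(m, bit_j) > 0L) next
      s <- length(cols_of[[m]])
      incr_by_size[[s + 1L]] <- c(incr_by_size[[s + 1L]],
                                  fits[m + bit_j] - fits[m])
    }
    dominance[j] <- mean(vapply(incr_by_size, mean, numeric(1)))
  }
  names(dominance) <- colnames(X)

  r2_full <- subset_fit(X, y, seq_len(p), if (fit_metric == "mcfadden")
    "mcfadden" else "r2")
  adj_full <- if (fit_metric == "mcfadden") NA_real_ else
    subset_fit(X, y, seq_len(p), "adj_r2")
  structure(
    list(total_dominance = dominance,
         relative_importance = 100 * dominance / sum(dominance),
         r2_full = r2_full, adj_r2_full = adj_full,
         n_models = n_sub, fit_metric = fit_metric),
    class = "dominance_result"
  )
}

#' @export
print.dominance_result <- function(x, ...) {
  cat("Dominance analysis (", x$n_models, " submodels, metric = ",
      x$fit_metric, ")\n", sep = "")
  cat("  full-model fit:", signif(x$r2_full, 4), "\n")
  for (j in seq_along(x$total_dominance))
    cat(sprintf("  %-26s dominance %.4f  importance %5.1f%%\n",
                names(x$total_dominance)[j], x$total_dominance[j],
                x$relative_importance[j]))
  invisible(x)
}

#' Permutation test of the full-model R-squared
#'
#' One-sided non-parametric test of the multiple-regression fit: the response
#' is randomly permuted `n_perm` times, the full-model R-squared recomputed
#' each time, and the p-value computed with the add-one correction
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param X Predictor matrix (n x p).
#' @param y Response vector.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param fit_metric `"r2"` (default) or `"adj_r2"`.
#' @return List with `p_value`, `observed`, `null` (length `n_perm`),
#'   `n_perm`, `seed`.
#' @export
permutation_test_r2 <- function(X, y, n_perm = 1000L, seed = NULL,
                                fit_metric = c("r2", "adj_r2")) {
  fit_metric <- match.arg(fit_metric)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cols <- seq_len(ncol(X))
  observed <- subset_fit(X, y, cols, fit_metric)
  null <- vapply(seq_len(n_perm), function(i)
    subset_fit(X, sample(y), cols, fit_metric), numeric(1))
  list(p_value = (1 + sum(null >= observed)) / (1 + n_perm),
       observed = observed, null = null, n_perm = as.integer(n_perm),
       seed = seed)
}

#' Dichotomise arousal scores
#'
#' Thresholds 0-11 arousal scores into binary labels: 1 iff
#' `score >= cutoff`. A cutoff of 9 separates wakefulness and high-amplitude
#' centro-median DBS from all other conditions; a cutoff of 3 additionally
#' counts light anaesthesia and low-amplitude centro-median DBS as aroused.
#'
#' @param scores Numeric vector of scores in 0-11.
#' @param cutoff Threshold in (0, 11].
#' @return Integer vector of 0/1 labels.
#' @export
dichotomize_arousal <- function(scores, cutoff = 9) {
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0 ||
      cutoff > 11)
    stop("cutoff must be a single value in (0, 11]")
  if (any(!is.finite(scores) | scores < 0 | scores > 11))
    stop("arousal scores must lie in [0, 11]")
  as.integer(scores >= cutoff)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (delegating to [stats::p.adjust()]), plus the rejection set at level `q`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level for the rejection set (default 0.05).
#' @return List with `adjusted` (BH-adjusted p-values) and `rejected`
#'   (logical).
#' @export
fdr_adjust <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}
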