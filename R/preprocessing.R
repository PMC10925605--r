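#' Global-signal regression
#'
#' Removes the global signal (the per-timepoint mean across regions) from every
#' regional time series by ordinary least squares: each region is regressed on
#' the global signal plus an intercept and replaced by its residual. After
#' regression every region is exactly uncorrelated with the global signal of
#' the input.
#'
#' @param ts A [parcellated_ts()].
#' @return A [parcellated_ts()] of the same shape, TR, labels and metadata.
#' @examples
#' ts <- parcellated_ts(matrix(rnorm(300), 100, 3), tr = 2.4)
#' clean <- regress_global_signal(ts)
#' g <- rowMeans(ts$data)
#' max(abs(crossprod(clean$data, g - mean(g))))  # ~ 0
#' @export
regress_global_signal <- function(ts) {
  stopifnot(inherits(ts, "parcellated_ts"))
  x <- ts$data
  if (nrow(x) < 3L) stop("need at least 3 timepoints for global-signal regression")
  g <- rowMeans(x)
  if (stats::var(g) < .Machine$double.eps)
    stop("degenerate input: global signal has zero variance")
  fit <- stats::lm.fit(cbind(1, g), x)
  out <- fit$residuals
  dimnames(out) <- dimnames(x)
  parcellated_ts(out, tr = ts$tr, region_labels = ts$region_labels,
                 meta = ts$meta)
}

#' Zero-phase FFT band-pass and notch filter
#'
#' Filters each regional series by masking bins of its discrete Fourier
#' transform: bins with frequency below `low_cut` (including DC) or above
#' `high_cut` are zeroed, as is the bin nearest `notch` plus `notch_width`
#' bins on each side. The mask is applied symmetrically to positive and
#' negative frequencies, so the inverse transform is real and the filter has
#' exactly zero phase shift. Brick-wall masking makes the filter idempotent.
#'
#' Defaults follow common macaque resting-state practice: pass band
#' 0.0025-0.05 Hz with a 0.03 Hz notch removing a known artefactual pure
#' frequency.
#'
#' @param ts A [parcellated_ts()].
#' @param low_cut High-pass cutoff in Hz (bins strictly below are removed).
#' @param high_cut Low-pass cutoff in Hz (bins strictly above are removed);
#'   must not exceed the Nyquist frequency `1 / (2 * tr)`.
#' @param notch Notch frequency in Hz, or `NULL` to disable. Must lie inside
#'   `(low_cut, high_cut)`.
#' @param notch_width Number of FFT bins zeroed on each side of the bin
#'   nearest `notch`.
#' @return A filtered [parcellated_ts()] of identical shape and metadata.
#' @examples
#' tr <- 1.25; t <- seq_len(400)
#' x <- cbind(sin(2 * pi * 0.01 * t * tr), sin(2 * pi * 0.03 * t * tr))
#' f <- temporal_filter(parcellated_ts(x, tr), notch = 0.03)
#' sd(f$data[, 2]) / sd(x[, 2])  # notch target suppressed
#' @export
temporal_filter <- function(ts, low_cut = 0.0025, high_cut = 0.05,
                            notch = 0.03, notch_width = 1L) {
  stopifnot(inherits(ts, "parcellated_ts"))
  tr <- ts$tr
  nyquist <- 1 / (2 * tr)
  if (!is.numeric(low_cut) || !is.numeric(high_cut) ||
      low_cut < 0 || low_cut >= high_cut)
    stop("need 0 <= low_cut < high_cut")
  if (high_cut > nyquist + 1e-12)
    stop("high_cut (", high_cut, " Hz) exceeds the Nyquist frequency (",
         signif(nyquist, 6), " Hz) for TR = ", tr, " s")
  if (!is.null(notch) && (notch <= low_cut || notch >= high_cut))
    stop("notch must lie strictly inside (low_cut, high_cut)")

  x <- ts$data
  T_ <- nrow(x)
  fund <- 1 / (T_ * tr)                       # frequency resolution
  if (low_cut > 0 && fund > low_cut)
    warning("series too short to resolve low_cut = ", low_cut,
            " Hz (fundamental ", signif(fund, 4),
            " Hz); only the DC bin is removed by the high-pass")

  # two-sided frequency of each DFT bin j = 0..T-1
  j <- seq_len(T_) - 1L
  freq <- pmin(j, T_ - j) * fund
  keep <- freq >= low_cut & freq <= high_cut
  if (low_cut > 0) keep[1L] <- FALSE          # DC always removed by high-pass
  if (!is.null(notch)) {
    pos <- which(j <= T_ / 2)
    centre <- pos[which.min(abs(freq[pos] - notch))]
    hit <- (centre - notch_width):(centre + notch_width)
    hit <- hit[hit >= 1L & hit <= T_]
    mirror <- T_ + 2L - hit                   # conjugate bins
    mirror <- mirror[mirror >= 1L & mirror <= T_]
    keep[c(hit, mirror)] <- FALSE
  }

  out <- apply(x, 2L, function(col) {
    spec <- stats::fft(col)
    spec[!keep] <- 0
    Re(stats::fft(spec, inverse = TRUE)) / T_
  })
  dimnames(out) <- dimnames(x)
  parcellated_ts(out, tr = tr, region_labels = ts$region_labels,
                 meta = ts$meta)
}
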