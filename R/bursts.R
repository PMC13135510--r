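# Beta-burst detection on the LFP channel: band-pass the z-scored series,
# take the amplitude envelope (modulus of the analytic signal), and call a
# burst wherever the envelope strictly exceeds the scan's 75th percentile
# for at least 100 ms.  Overlap with network states is quantified relative
# to each state's occurrence time.

#' Amplitude envelope of a band-limited signal
#'
#' Z-scores the series, applies a zero-phase Butterworth band-pass, and
#' returns the modulus of the analytic signal.  With two input channels
#' (e.g. one per hemisphere) the z-scored channels are averaged first.
#'
#' @param x Numeric vector, or a 2-row matrix of channels to average.
#' @param band Length-2 band in Hz, `(13, 30)` by default.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order.
#' @return Numeric envelope, same length as the input.
#' @export
amplitude_envelope <- function(x, band = c(13, 30), fs, order = 4) {
  if (is.matrix(x)) {
    zs <- apply(x, 1, function(r) {
      s <- stats::sd(r)
      if (s == 0) stop("zero-variance channel cannot be z-scored")
      (r - mean(r)) / s
    })
    x <- rowMeans(zs)
  } else {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("zero-variance series cannot be z-scored")
    x <- (x - mean(x)) / s
  }
  stopifnot(band[2] < fs / 2, band[1] > 0)
  coefs <- butter_design(order, band, fs, "pass")
  Mod(analytic_signal(filtfilt(coefs, x)))
}

#' Detect threshold-crossing bursts in an envelope
#'
#' A burst is a maximal run of samples where the envelope strictly exceeds
#' the `percentile`-th percentile of the (good-sample) envelope, lasting at
#' least `min_duration_s`.  Intervals are half-open `[start, end)` in
#' 1-based sample indices (`end` is the first sample after the burst).
#'
#' @param envelope Numeric envelope series.
#' @param fs Sampling rate in Hz.
#' @param percentile Threshold percentile (75 by default).
#' @param min_duration_s Minimum burst duration in seconds (0.1 by default).
#' @param good Optional logical mask; the threshold is computed over good
#'   samples only and bursts cannot include bad samples.
#' @return Object of class `burst_set`: data frame `intervals`
#'   (start, end, duration_s, peak_envelope), `threshold_value`, `fs`.
#' @export
detect_bursts <- function(envelope, fs, percentile = 75, min_duration_s = 0.1,
                          good = NULL) {
  stopifnot(all(is.finite(envelope)), fs > 0)
  if (is.null(good)) good <- rep(TRUE, length(envelope))
  thr <- stats::quantile(envelope[good], percentile / 100, names = FALSE)
  above <- envelope > thr & good
  min_len <- ceiling(min_duration_s * fs)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  iv <- data.frame(start = starts[keep], end = ends[keep] + 1L)
  iv$duration_s <- (iv$end - iv$start) / fs
  iv$peak_envelope <- vapply(seq_len(nrow(iv)), function(i)
    max(envelope[iv$start[i]:(iv$end[i] - 1L)]), 0)
  structure(list(intervals = iv, threshold_value = thr, fs = fs,
                 n_samples = length(envelope)),
            class = "burst_set")
}

# logical burst indicator over n samples
burst_indicator <- function(bursts, n) {
  iv <- if (inherits(bursts, "burst_set")) bursts$intervals else bursts
  ind <- rep(FALSE, n)
  for (i in seq_len(nrow(iv)))
    ind[iv$start[i]:(iv$end[i] - 1L)] <- TRUE
  ind
}

#' Temporal overlap between bursts and a network state
#'
#' State activity is binarised as the per-sample argmax of gamma (ties to
#' the lowest index); the overlap is the percentage of the state's active
#' samples during which a burst was also active, and the contrast subtracts
#' the pooled overlap of all other states.
#'
#' @param bursts A `burst_set` (or intervals data frame).
#' @param gamma T x K posterior matrix on the same sample axis as the
#'   envelope (align with the embedding offset before calling).
#' @param state Target state index.
#' @param weighted If TRUE, use gamma-weighted rather than hard overlap.
#' @return List with `overlap_pct`, `other_pct`, `contrast_pct`.
#' @export
burst_state_overlap <- function(bursts, gamma, state, weighted = FALSE) {
  gamma <- as.matrix(gamma)
  n <- nrow(gamma)
  nb <- if (inherits(bursts, "burst_set")) bursts$n_samples else n
  if (nb != n) stop("bursts and gamma are on different sample axes")
  ind <- burst_indicator(bursts, n)
  ok <- stats::complete.cases(gamma)
  if (weighted) {
    w_k <- gamma[ok, state]
    w_o <- 1 - w_k
    denom_k <- sum(w_k); denom_o <- sum(w_o)
    ov_k <- if (denom_k > 0) 100 * sum(w_k * ind[ok]) / denom_k else NA_real_
    ov_o <- if (denom_o > 0) 100 * sum(w_o * ind[ok]) / denom_o else NA_real_
  } else {
    hard <- max.col(gamma[ok, , drop = FALSE], ties.method = "first")
    in_k <- hard == state
    denom_k <- sum(in_k); denom_o <- sum(!in_k)
    ov_k <- if (denom_k > 0) 100 * sum(ind[ok][in_k]) / denom_k else NA_real_
    ov_o <- if (denom_o > 0) 100 * sum(ind[ok][!in_k]) / denom_o else NA_real_
  }
  list(overlap_pct = ov_k, other_pct = ov_o, contrast_pct = ov_k - ov_o)
}
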