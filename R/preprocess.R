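# Recording conditioning: zero-phase Butterworth band-pass, notch filters,
# anti-aliased resampling, per-channel standardisation and window-based
# bad-segment detection with a GESD outlier test on window standard
# deviations.

#' Filtering/resampling specification
#'
#' @param band Length-2 numeric `(low, high)` in Hz; use `low = 0` for a pure
#'   low-pass and `high = Inf` (or `fs/2`) for a pure high-pass.
#' @param order Butterworth order (5 by default).
#' @param notches Frequencies (Hz) of IIR notch filters to apply after the
#'   band-pass; empty by default.
#' @param fs_out Output sampling rate in Hz; `NULL` keeps the input rate.
#' @export
filter_spec <- function(band = c(0.5, 125), order = 5, notches = numeric(0),
                        fs_out = NULL) {
  stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1], order >= 1,
            all(notches > 0))
  structure(list(band = band, order = order, notches = notches,
                 fs_out = fs_out), class = "filter_spec")
}

#' Zero-phase filter and resample a recording
#'
#' Applies the band-pass forward and backward (zero phase), then any
#' notches, then Fourier resampling to `fs_out`.  The bad mask is carried
#' over by nearest-sample mapping when the rate changes.
#'
#' @param rec A [recording()].
#' @param spec A [filter_spec()].
#' @return The filtered [recording()].
#' @export
filter_resample <- function(rec, spec) {
  validate_recording(rec)
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- rec$fs / 2
  lo <- spec$band[1]; hi <- spec$band[2]
  if (is.finite(hi) && hi > nyq) stop("band edge above Nyquist")
  if (any(spec$notches >= nyq)) stop("notch frequency above Nyquist")
  fs_out <- spec$fs_out %||% rec$fs
  if (fs_out > rec$fs) stop("upsampling is not supported (fs_out > fs)")

  X <- rec$data
  pass_all <- lo <= 0 && (!is.finite(hi) || hi >= nyq)
  if (!pass_all) {
    coefs <- if (lo <= 0) butter_design(spec$order, hi, rec$fs, "low")
    else if (!is.finite(hi) || hi >= nyq) butter_design(spec$order, lo, rec$fs, "high")
    else butter_design(spec$order, c(lo, hi), rec$fs, "pass")
    X <- filtfilt(coefs, X)
  }
  for (f0 in spec$notches) X <- filtfilt(notch_design(f0, rec$fs), X)
  bad <- rec$bad_mask
  if (fs_out != rec$fs) {
    X <- resample_fft(X, rec$fs, fs_out)
    idx <- pmin(length(bad), floor((seq_len(ncol(X)) - 1) * rec$fs / fs_out) + 1)
    bad <- bad[idx]
  }
  recording(X, fs = fs_out, channel_labels = rec$channel_labels,
            channel_roles = rec$channel_roles, bad_mask = bad,
            subject = rec$subject, condition = rec$condition)
}

#' Standardise each channel to zero mean, unit variance
#'
#' Moments are computed over good samples only; the transform is applied to
#' all samples so the series stays contiguous.
#'
#' @param rec A [recording()].
#' @return Standardised [recording()].
#' @export
standardize <- function(rec) {
  validate_recording(rec)
  good <- !rec$bad_mask
  if (!any(good)) stop("no good samples to standardise on")
  X <- rec$data
  for (i in seq_len(nrow(X))) {
    m <- mean(X[i, good])
    s <- stats::sd(X[i, good])
    if (!is.finite(s) || s == 0)
      stop(sprintf("channel '%s' has zero variance", rec$channel_labels[i]))
    X[i, ] <- (X[i, ] - m) / s
  }
  recording(X, fs = rec$fs, channel_labels = rec$channel_labels,
            channel_roles = rec$channel_roles, bad_mask = rec$bad_mask,
            subject = rec$subject, condition = rec$condition)
}

#' GESD-based bad-segment detection
#'
#' The recording is tiled into non-overlapping windows; per channel role and
#' per signal form (raw and first difference), the windowed standard
#' deviation (averaged over the role's channels) is screened with a GESD
#' outlier test, and samples in any flagged window are marked bad.  The
#' returned mask is the union over all role x form combinations.  A trailing
#' partial window is never tested and stays good.
#'
#' @param rec A [recording()].
#' @param window_s Window length in seconds (2 by default).
#' @param alpha GESD significance level.
#' @param max_outlier_frac Maximum fraction of windows flaggable.
#' @return Logical per-sample mask (`TRUE` = bad).
#' @export
detect_bad_segments <- function(rec, window_s = 2, alpha = 0.05,
                                max_outlier_frac = 0.20) {
  validate_recording(rec)
  wlen <- round(window_s * rec$fs)
  n <- ncol(rec$data)
  n_win <- n %/% wlen
  if (n_win < 2) stop("recording shorter than two windows")
  mask <- rep(FALSE, n)
  max_out <- max(1L, floor(max_outlier_frac * n_win))

  for (role in unique(rec$channel_roles)) {
    rows <- which(rec$channel_roles == role)
    for (form in c("raw", "diff")) {
      Y <- rec$data[rows, , drop = FALSE]
      if (form == "diff") Y <- cbind(Y[, 1, drop = FALSE], t(apply(Y, 1, diff)))
      # mean over channels of each window's standard deviation
      win_sd <- vapply(seq_len(n_win), function(w) {
        cols <- ((w - 1) * wlen + 1):(w * wlen)
        mean(apply(Y[, cols, drop = FALSE], 1, stats::sd))
      }, 0)
      res <- gesd(win_sd, alpha = alpha, max_outliers = min(max_out, n_win %/% 2 - 1L))
      for (w in res$outlier_indices)
        mask[((w - 1) * wlen + 1):(w * wlen)] <- TRUE
    }
  }
  mask
}
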