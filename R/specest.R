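# State-weighted multitaper cross-spectral estimation.  The recording is
# tiled into windows; each window's taper-averaged cross-spectral matrix is
# combined into per-state estimates using the mean posterior state
# probability of the window as the weight, so spectra are pooled over all
# periods in which a state occurred rather than over single visits.

#' Build a Slepian taper set
#'
#' @param window_s Window length in seconds (2 by default).
#' @param n_tapers Number of DPSS tapers (7 by default).
#' @param fs Sampling rate in Hz.
#' @return Object of class `taper_set` with the tapers (rows), the window
#'   length in samples, and the implied half-bandwidth
#'   `(n_tapers + 1) / (2 * window_s)` in Hz.
#' @export
make_tapers <- function(window_s = 2, n_tapers = 7, fs = 250) {
  stopifnot(window_s > 0, n_tapers >= 1, fs > 0)
  nw <- round(window_s * fs)
  half_bw <- (n_tapers + 1) / (2 * window_s)   # K = 2TW - 1 tapers
  w <- half_bw / fs
  if (n_tapers > 2 * window_s * half_bw - 1 + 1e-9)
    stop("taper count exceeds the 2TW - 1 stability bound")
  if (w >= 0.5) stop("half-bandwidth exceeds Nyquist")
  structure(list(window_s = window_s, n_tapers = n_tapers, fs = fs,
                 half_bandwidth_hz = half_bw, window_samples = nw,
                 tapers = dpss_tapers(nw, w, n_tapers)),
            class = "taper_set")
}

#' State-weighted multitaper cross-spectral density
#'
#' @param rec A [recording()] (or channels x samples matrix).
#' @param gamma T x K posterior matrix aligned to the recording samples;
#'   `offset` shifts gamma row 1 to recording sample `offset + 1` (use the
#'   embedding trim `L`).  `gamma = NULL` gives the plain (single-state)
#'   estimate.
#' @param tapers A [make_tapers()] taper set.
#' @param offset Alignment offset in samples (see above).
#' @param overlap Window overlap fraction, 0 (default) or 0.5.
#' @return Object of class `state_spectra`: `freqs` (Hz), `csd` (list over
#'   states of freq x C x C Hermitian arrays), `weights` (total gamma mass
#'   per state), `fo` (fractional occupancy over used windows), `n_windows`,
#'   `channels`.
#' @export
state_weighted_csd <- function(rec, gamma = NULL, tapers = make_tapers(fs = rec$fs),
                               offset = 0, overlap = 0) {
  if (inherits(rec, "recording")) {
    X <- rec$data; fs <- rec$fs; bad <- rec$bad_mask
    labels <- rec$channel_labels
  } else {
    X <- as.matrix(rec); fs <- tapers$fs; bad <- rep(FALSE, ncol(X))
    labels <- rownames(X) %||% paste0("ch", seq_len(nrow(X)))
  }
  if (abs(fs - tapers$fs) > 1e-9) stop("taper set built for a different sampling rate")
  nw <- tapers$window_samples
  Tn <- ncol(X); C <- nrow(X)
  if (Tn < nw) stop("recording shorter than one window")
  if (is.null(gamma)) gamma <- matrix(1, Tn, 1)
  gamma <- as.matrix(gamma)
  K <- ncol(gamma)
  step <- if (overlap > 0) nw %/% 2 else nw
  starts <- seq(1, Tn - nw + 1, by = step)
  # a window is usable if wholly good and wholly covered by gamma rows
  g_lo <- offset + 1; g_hi <- offset + nrow(gamma)

  nfreq <- nw %/% 2 + 1
  freqs <- (seq_len(nfreq) - 1) * fs / nw
  acc <- lapply(seq_len(K), function(k) array(0 + 0i, c(nfreq, C, C)))
  wsum <- numeric(K)
  fo_sum <- numeric(K)
  w2_sum <- numeric(K)
  n_used <- 0L

  scale <- 1 / fs   # unit-energy tapers; one-sided doubling applied below
  for (s0 in starts) {
    s1 <- s0 + nw - 1
    if (any(bad[s0:s1])) next
    if (s0 < g_lo || s1 > g_hi) next
    gw <- gamma[(s0 - offset):(s1 - offset), , drop = FALSE]
    if (anyNA(gw)) next
    wbar <- colMeans(gw)
    seg <- X[, s0:s1, drop = FALSE]
    seg <- seg - rowMeans(seg)
    # taper-averaged cross-spectra: F is nfreq x C per taper
    Pw <- array(0 + 0i, c(nfreq, C, C))
    for (m in seq_len(tapers$n_tapers)) {
      Fm <- stats::mvfft(t(seg * rep(tapers$tapers[m, ], each = C)))[seq_len(nfreq), , drop = FALSE]
      for (ci in seq_len(C)) {
        Pw[, ci, ] <- Pw[, ci, ] + Fm[, ci] * Conj(Fm)
      }
    }
    Pw <- Pw * (scale / tapers$n_tapers)
    # one-sided spectrum: double everything except DC (and Nyquist if even)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nw %% 2 == 0) dbl[nfreq] <- 1
    Pw <- Pw * dbl
    for (k in seq_len(K)) {
      if (wbar[k] > 0) acc[[k]] <- acc[[k]] + wbar[k] * Pw
      wsum[k] <- wsum[k] + wbar[k] * nw
      fo_sum[k] <- fo_sum[k] + wbar[k]
      w2_sum[k] <- w2_sum[k] + wbar[k]^2
    }
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable windows (all bad or not covered by gamma)")
  csd <- lapply(seq_len(K), function(k) {
    if (fo_sum[k] <= 0) return(NULL)   # zero-weight state: flagged as NULL
    acc[[k]] / fo_sum[k]
  })
  # effective number of independent windows per state under soft weighting
  eff_win <- ifelse(w2_sum > 0, fo_sum^2 / w2_sum, 0)
  structure(list(freqs = freqs, csd = csd, weights = wsum,
                 fo = fo_sum / sum(fo_sum), n_windows = n_used,
                 eff_dof = tapers$n_tapers * eff_win,
                 channels = labels, fs = fs),
            class = "state_spectra")
}

#' Coherence spectrum for a channel pair
#'
#' Magnitude coherence `|S_xy| / sqrt(S_xx S_yy)` or absolute imaginary
#' coherency `|Im(S_xy / sqrt(S_xx S_yy))|` (which discards zero-lag
#' contributions and so controls for instantaneous field spread).
#'
#' @param spectra A `state_spectra`.
#' @param pair Character or integer vector of length 2.
#' @param state State index (1 for the plain estimate).
#' @param kind `"magnitude"` or `"imaginary"`.
#' @param debias Subtract the small-sample coherence bias implied by the
#'   state's effective degrees of freedom L (E[coh^2] ~ 1/L under
#'   independence): `msc_u = (L msc - 1)/(L - 1)` clipped at zero, and
#'   `im_u^2 = im^2 - 1/(2L)` for the imaginary kind.  Needed when states
#'   with very different occupancies are compared on short scans.
#' @return List with `freqs`, `values` (in `[0, 1]`, `NA` where power
#'   vanishes) and `kind`.
#' @export
coherence <- function(spectra, pair, state = 1, kind = c("magnitude", "imaginary"),
                      debias = FALSE) {
  kind <- match.arg(kind)
  idx <- if (is.character(pair)) match(pair, spectra$channels) else as.integer(pair)
  if (anyNA(idx)) stop("pair channels not present")
  S <- spectra$csd[[state]]
  if (is.null(S)) stop("state has zero weight; coherence undefined")
  sxx <- Re(S[, idx[1], idx[1]])
  syy <- Re(S[, idx[2], idx[2]])
  sxy <- S[, idx[1], idx[2]]
  denom <- sqrt(sxx * syy)
  c_cplx <- ifelse(denom > 0, sxy / denom, NA_complex_)
  vals <- if (kind == "magnitude") Mod(c_cplx) else abs(Im(c_cplx))
  if (debias) {
    L <- spectra$eff_dof[state]
    if (is.null(L) || !is.finite(L) || L <= 1)
      warning("effective dof unavailable; returning raw coherence")
    else if (kind == "magnitude")
      vals <- sqrt(pmax(0, (L * vals^2 - 1) / (L - 1)))
    else
      vals <- sqrt(pmax(0, vals^2 - 1 / (2 * L)))
  }
  list(freqs = spectra$freqs, values = pmin(vals, 1), kind = kind)
}

#' Time-averaged spectrum across states
#'
#' Fractional-occupancy-weighted average of the per-state CSDs, which by the
#' weighting identity equals the all-window estimate.
#'
#' @param spectra A `state_spectra`.
#' @return A single-state `state_spectra`.
#' @export
time_average_spectrum <- function(spectra) {
  K <- length(spectra$csd)
  keep <- which(!vapply(spectra$csd, is.null, TRUE))
  fo <- spectra$fo[keep] / sum(spectra$fo[keep])
  avg <- Reduce(`+`, Map(function(k, w) spectra$csd[[k]] * w, keep, fo))
  structure(list(freqs = spectra$freqs, csd = list(avg),
                 weights = sum(spectra$weights), fo = 1,
                 n_windows = spectra$n_windows,
                 eff_dof = sum(spectra$eff_dof[keep]),
                 channels = spectra$channels, fs = spectra$fs),
            class = "state_spectra")
}

#' Per-channel power spectrum
#'
#' @param spectra A `state_spectra`.
#' @param channel Channel label or index.
#' @param state State index.
#' @return List with `freqs` and `power`.
#' @export
power_spectrum <- function(spectra, channel, state = 1) {
  idx <- if (is.character(channel)) match(channel, spectra$channels) else channel
  if (is.na(idx)) stop("unknown channel")
  S <- spectra$csd[[state]]
  if (is.null(S)) stop("state has zero weight; power undefined")
  list(freqs = spectra$freqs, power = Re(S[, idx, idx]))
}

#' Mean band power
#'
#' Mean of the power (or of any per-frequency values) over frequencies in
#' `[band[1], band[2]]` inclusive.
#'
#' @param spectrum List with `freqs` and `power` (or `values`).
#' @param band Length-2 numeric band in Hz, (13, 30) by default.
#' @export
band_power <- function(spectrum, band = c(13, 30)) {
  vals <- spectrum$power %||% spectrum$values
  sel <- spectrum$freqs >= band[1] & spectrum$freqs <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  mean(vals[sel])
}

#' Percentile-threshold a set of connection strengths
#'
#' Retains edges whose value strictly exceeds the given percentile of all
#' finite values; with all-equal values nothing survives.
#'
#' @param values Numeric vector (or matrix) of connection strengths.
#' @param percentile Percentile in `[0, 100)` (98 by default).
#' @return Logical vector/matrix marking retained edges.
#' @export
threshold_network <- function(values, percentile = 98) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to threshold")
  thr <- stats::quantile(v, percentile / 100, names = FALSE, type = 7)
  out <- values > thr
  out[!is.finite(values)] <- FALSE
  out
}
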