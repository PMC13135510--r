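# Core DSP primitives: Butterworth IIR design (zero-phase application),
# biquad notch, FFT resampling and the analytic signal.  Implemented on base
# R because the build environment provides no signal-processing package;
# each primitive is exercised against analytic oracles in the test suite.

#' Butterworth IIR filter design
#'
#' Designs a digital Butterworth filter by bilinear transform of the analog
#' prototype, returning transfer-function coefficients.
#'
#' @param order Filter order (per band edge; a band-pass/stop filter of order
#'   `n` has `2n` poles).
#' @param cutoff_hz Corner frequency in Hz; length 1 for `low`/`high`,
#'   length 2 for `pass`/`stop`.
#' @param fs Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return List with numerator `b` and denominator `a` (`a[1] == 1`).
#' @export
butter_design <- function(order, cutoff_hz, fs, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fs > 0, all(cutoff_hz > 0), all(cutoff_hz < fs / 2))
  if (type %in% c("pass", "stop") && length(cutoff_hz) != 2L)
    stop("band filters need two cutoff frequencies")
  if (type %in% c("low", "high") && length(cutoff_hz) != 1L)
    stop("one-sided filters need a single cutoff frequency")

  # analog Butterworth prototype: poles on the unit circle, no zeros
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  z <- complex(0)
  g <- 1

  warp <- function(f) 2 * fs * tan(pi * f / fs)  # bilinear pre-warping
  if (type == "low") {
    w0 <- warp(cutoff_hz)
    p <- p * w0
    g <- g * w0^order
  } else if (type == "high") {
    w0 <- warp(cutoff_hz)
    g <- g * Re(prod(-p))    # prototype gain at s -> w0/s
    p <- w0 / p
    z <- rep(0 + 0i, order)
  } else {
    w <- warp(sort(cutoff_hz))
    bw <- w[2] - w[1]
    w0 <- sqrt(w[1] * w[2])
    if (type == "pass") {
      ph <- p * bw / 2
      p <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
      z <- rep(0 + 0i, order)
      g <- g * bw^order
    } else {
      g <- g * Re(prod(-p))
      pi_ <- (bw / 2) / p
      p <- c(pi_ + sqrt(pi_^2 - w0^2), pi_ - sqrt(pi_^2 - w0^2))
      z <- rep(c(1i * w0, -1i * w0), order)
    }
  }

  # bilinear transform s = 2 fs (z-1)/(z+1)
  fs2 <- 2 * fs
  gd <- g * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c((fs2 + z) / (fs2 - z), rep(-1 + 0i, length(p) - length(z)))
  pd <- (fs2 + p) / (fs2 - p)

  b <- Re(gd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1], sos = zpk_to_sos(zd, pd, gd))
}

# split a zero/pole/gain design into second-order sections (biquads); the
# expanded transfer function of a high-order narrow-band IIR is numerically
# ill-conditioned, so filtering always runs through the cascade
zpk_to_sos <- function(z, p, k) {
  pr <- p; zr <- z
  secs <- list()
  is_real <- function(v) abs(Im(v)) < 1e-8
  while (length(pr) > 0) {
    i <- which.max(Mod(pr))
    p1 <- pr[i]; pr <- pr[-i]
    p2 <- NULL
    if (!is_real(p1)) {
      j <- which.min(Mod(pr - Conj(p1)))
      p2 <- pr[j]; pr <- pr[-j]
    } else {
      reals <- which(vapply(pr, is_real, TRUE))
      if (length(reals)) {
        j <- reals[which.min(abs(Re(pr[reals]) - Re(p1)))]
        p2 <- pr[j]; pr <- pr[-j]
      }
    }
    # assign up to as many zeros as poles in this section, nearest first
    zsel <- complex(0)
    n_z <- if (is.null(p2)) 1L else 2L
    while (length(zsel) < n_z && length(zr) > 0) {
      j <- which.min(Mod(zr - p1))
      z1 <- zr[j]; zr <- zr[-j]
      zsel <- c(zsel, z1)
      if (!is_real(z1) && length(zsel) < n_z) {
        jc <- which.min(Mod(zr - Conj(z1)))
        zsel <- c(zsel, zr[jc]); zr <- zr[-jc]
      }
    }
    b <- Re(poly_from_roots(zsel))
    a <- Re(poly_from_roots(c(p1, p2)))
    secs[[length(secs) + 1L]] <- c(b, rep(0, 3 - length(b)),
                                   a, rep(0, 3 - length(a)))
  }
  sos <- do.call(rbind, rev(secs))   # least-peaked sections first
  sos[nrow(sos), 1:3] <- sos[nrow(sos), 1:3] * Re(k)  # fold in the gain
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

# run a second-order-section cascade (single pass, zero initial conditions)
sos_filter <- function(sos, x) {
  for (i in seq_len(nrow(sos)))
    x <- iir_filter(sos[i, 1:3], sos[i, 4:6], x)
  x
}

# monic polynomial coefficients from roots (descending powers)
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs) * ri
  coefs
}

#' Second-order IIR notch filter
#'
#' @param f0 Notch frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param q Quality factor; the -3 dB bandwidth is `f0 / q`.
#' @return List with `b`, `a` coefficients.
#' @export
notch_design <- function(f0, fs, q = 30) {
  stopifnot(f0 > 0, f0 < fs / 2, q > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# single-pass IIR filtering (direct form, zero initial conditions) using the
# C implementations behind stats::filter
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1L) v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  v
}

#' Zero-phase IIR filtering
#'
#' Applies the filter forward and backward (squaring the magnitude response
#' and cancelling the phase), with odd reflection padding at both ends to
#' suppress start-up transients.
#'
#' @param coefs List with `b` and `a` from [butter_design()] or
#'   [notch_design()].
#' @param x Numeric vector or a channels-by-samples matrix (filtered row-wise).
#' @return Filtered data, same shape as `x`.
#' @export
filtfilt <- function(coefs, x) {
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- filtfilt(coefs, x[i, ])
    return(out)
  }
  b <- coefs$b; a <- coefs$a
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (length(x) <= npad) stop("series too short for the filter's edge padding")
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  run <- if (is.null(coefs$sos)) function(v) iir_filter(b, a, v)
         else function(v) sos_filter(coefs$sos, v)
  y <- run(c(pre, x, post))
  y <- rev(run(rev(y)))
  y[(npad + 1):(npad + length(x))]
}

#' Fourier-domain resampling
#'
#' Resamples to a new rate by truncating (or zero-padding) the discrete
#' spectrum, which is inherently anti-aliased for downsampling.
#'
#' @param x Numeric vector or channels-by-samples matrix.
#' @param fs Input sampling rate in Hz.
#' @param fs_out Output sampling rate in Hz.
#' @return Resampled data.
#' @export
resample_fft <- function(x, fs, fs_out) {
  if (fs_out == fs) return(x)
  if (is.matrix(x)) {
    n_out <- max(1L, round(ncol(x) * fs_out / fs))
    out <- matrix(0, nrow(x), n_out, dimnames = list(rownames(x), NULL))
    for (i in seq_len(nrow(x))) out[i, ] <- resample_fft(x[i, ], fs, fs_out)
    return(out)
  }
  n <- length(x)
  m <- max(1L, round(n * fs_out / fs))
  X <- stats::fft(x)
  Y <- complex(m)
  nh <- min(n, m)
  keep <- floor(nh / 2)
  Y[seq_len(keep + 1)] <- X[seq_len(keep + 1)]
  if (keep >= 1) Y[(m - keep + 1):m] <- X[(n - keep + 1):n]
  if (nh %% 2 == 0) {
    # split the shared Nyquist bin symmetrically
    if (m < n) {
      Y[keep + 1] <- X[keep + 1] + X[n - keep + 1]
      Y[keep + 1] <- Re(Y[keep + 1])  # keep the result real-symmetric
    } else if (m > n) {
      Y[keep + 1] <- X[keep + 1] / 2
      Y[m - keep + 1] <- X[keep + 1] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Analytic signal via the Hilbert transform
#'
#' @param x Real-valued numeric vector.
#' @return Complex vector whose modulus is the amplitude envelope.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Discrete prolate spheroidal (Slepian) sequences
#'
#' Computes the first `n_tapers` DPSS tapers of length `n` with normalised
#' half-bandwidth `w` by solving the classical symmetric tridiagonal
#' eigenproblem; tapers are returned with unit energy.
#'
#' @param n Taper length in samples.
#' @param w Normalised half-bandwidth (half_bandwidth_hz / fs), in (0, 0.5).
#' @param n_tapers Number of tapers.
#' @return `n_tapers` x `n` matrix, one taper per row, ordered by decreasing
#'   spectral concentration.
#' @export
dpss_tapers <- function(n, w, n_tapers) {
  stopifnot(n >= 2, w > 0, w < 0.5, n_tapers >= 1, n_tapers <= n)
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- i[-1] * (n - i[-1]) / 2
  M <- diag(d)
  M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  eg <- eigen(M, symmetric = TRUE)
  tap <- t(eg$vectors[, seq_len(n_tapers), drop = FALSE])
  for (k in seq_len(n_tapers)) {
    tap[k, ] <- tap[k, ] / sqrt(sum(tap[k, ]^2))
    # deterministic polarity: positive mean lobe (or positive leading slope)
    s <- sum(tap[k, ])
    if (abs(s) > 1e-8) { if (s < 0) tap[k, ] <- -tap[k, ] }
    else if (tap[k, 2] - tap[k, 1] < 0) tap[k, ] <- -tap[k, ]
  }
  tap
}
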