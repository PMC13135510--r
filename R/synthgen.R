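# Synthetic generator for state-switching multichannel oscillatory data:
# a Markov chain over K network states, each state gating band-limited
# stochastic oscillators on a set of cortical channels and one LFP channel,
# optional state-dependent LFP-cortex coupling via a shared band-limited
# component, and a paired "medication" condition that scales LFP beta
# amplitudes in designated states.

#' Markov chain specification
#'
#' @param transition K x K row-stochastic transition matrix.
#' @param initial Length-K initial distribution; defaults to the uniform
#'   distribution.
#' @return Object of class `markov_spec`.
#' @export
markov_spec <- function(transition, initial = NULL) {
  transition <- as.matrix(transition)
  K <- nrow(transition)
  if (ncol(transition) != K) stop("transition matrix must be square")
  if (any(transition < 0)) stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  if (is.null(initial)) initial <- rep(1 / K, K)
  if (length(initial) != K || any(initial < 0) || abs(sum(initial) - 1) > 1e-12)
    stop("initial distribution must be a length-K probability vector")
  structure(list(n_states = K, transition = transition, initial = initial),
            class = "markov_spec")
}

#' Uniform-leave Markov spec with a given mean dwell time
#'
#' Stay probability is `1 - 1/(dwell_s * fs)`; leaving mass is spread
#' uniformly over the other states, giving geometric dwell times with the
#' requested mean.
#'
#' @param n_states Number of states K.
#' @param dwell_s Mean state lifetime in seconds.
#' @param fs Sampling rate in Hz.
#' @export
uniform_markov_spec <- function(n_states, dwell_s, fs) {
  stopifnot(n_states >= 1, dwell_s * fs >= 1)
  stay <- 1 - 1 / (dwell_s * fs)
  A <- matrix(if (n_states > 1) (1 - stay) / (n_states - 1) else 0,
              n_states, n_states)
  diag(A) <- if (n_states > 1) stay else 1
  markov_spec(A)
}

#' Band-limited oscillator specification
#'
#' Oscillators are realised as band-pass-filtered Gaussian noise scaled to
#' standard deviation `amplitude`, so their envelope fluctuates naturally
#' and threshold crossings produce realistic bursts.
#'
#' @param center_hz Centre frequency in Hz.
#' @param bandwidth_hz Full bandwidth in Hz.
#' @param amplitude Standard deviation of the oscillatory component.
#' @export
oscillator_spec <- function(center_hz, bandwidth_hz, amplitude = 1) {
  stopifnot(center_hz > 0, bandwidth_hz > 0, amplitude >= 0)
  structure(list(center_hz = center_hz, bandwidth_hz = bandwidth_hz,
                 amplitude = amplitude), class = "oscillator_spec")
}

#' State-dependent coupling specification
#'
#' While any state in `active_states` holds, a shared band-limited component
#' `s(t)` (realised from `band`) is added to the source channel and
#' `mixing * s(t)` to the target channel, creating coherence confined to the
#' band and to the active states.
#'
#' @param source_channel,target_channel Channel labels (must differ).
#' @param active_states Integer set of states in which the coupling is on.
#' @param band An [oscillator_spec()] for the shared component.
#' @param mixing Non-negative gain applied on the target channel.
#' @export
coupling_spec <- function(source_channel, target_channel, active_states,
                          band, mixing = 1) {
  if (identical(source_channel, target_channel))
    stop("source and target channels must differ")
  stopifnot(inherits(band, "oscillator_spec"), mixing >= 0,
            all(active_states >= 1))
  structure(list(source_channel = source_channel,
                 target_channel = target_channel,
                 active_states = as.integer(active_states),
                 band = band, mixing = mixing), class = "coupling_spec")
}

#' Sample a hidden state sequence
#'
#' @param spec A [markov_spec()].
#' @param n_samples Sequence length (>= 1).
#' @param seed Integer seed; fixed seeds give bit-identical sequences.
#' @return Integer vector with values in `1..K`.
#' @export
sample_state_sequence <- function(spec, n_samples, seed) {
  stopifnot(inherits(spec, "markov_spec"), n_samples >= 1)
  K <- spec$n_states
  out <- integer(n_samples)
  withr_seed(seed, {
    out[1] <- sample.int(K, 1, prob = spec$initial)
    if (n_samples > 1) {
      # presample uniforms; invert the per-row transition CDF
      u <- stats::runif(n_samples - 1)
      cdf <- t(apply(spec$transition, 1, cumsum))
      for (t in 2:n_samples) {
        out[t] <- findInterval(u[t - 1], cdf[out[t - 1], ],
                               rightmost.closed = TRUE) + 1L
      }
    }
  })
  out
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# band-pass filtered unit-variance Gaussian noise, scaled to sd = amplitude
band_limited_noise <- function(n, osc, fs) {
  lo <- max(osc$center_hz - osc$bandwidth_hz / 2, 0.1)
  hi <- min(osc$center_hz + osc$bandwidth_hz / 2, fs / 2 * 0.99)
  coefs <- butter_design(4, c(lo, hi), fs, "pass")
  x <- filtfilt(coefs, stats::rnorm(n))
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * osc$amplitude
}

# smooth state-indicator gate: raised-cosine ramp at boundaries
smooth_gate <- function(indicator, fs, ramp_s = 0.02) {
  half <- max(1L, round(ramp_s * fs / 2))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(2 * half + 1) / (2 * half + 2)))
  w <- w / sum(w)
  g <- stats::filter(c(rep(indicator[1], half), indicator,
                       rep(indicator[length(indicator)], half)),
                     w, method = "convolution", sides = 2)
  as.numeric(g)[(half + 1):(half + length(indicator))]
}

#' Synthesise a state-gated multichannel recording
#'
#' Each channel is the sum of white noise and, per state, the state's
#' band-limited oscillators gated by a raised-cosine-smoothed indicator of
#' that state.  Couplings add a shared band-limited component to the source
#' channel and `mixing` times that component to the target channel while an
#' active state holds.
#'
#' @param states Integer state sequence (from [sample_state_sequence()]).
#' @param per_state_channel_spectra List over states; element `k` is a named
#'   list mapping channel label to a list of [oscillator_spec()]s active in
#'   state `k`.
#' @param couplings List of [coupling_spec()]s (possibly empty).
#' @param noise_sd White-noise standard deviation added to every channel.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param channel_roles Named character vector label -> role; unnamed
#'   channels default to `"cortical"`.
#' @param ramp_s Raised-cosine gate ramp length in seconds.
#' @param subject,condition Labels stored in the returned recording.
#' @return List with `recording` and `ground_truth` (state sequence, clean
#'   beta-band LFP burst intervals, couplings).
#' @export
synthesize_recording <- function(states, per_state_channel_spectra,
                                 couplings = list(), noise_sd = 1, fs = 250,
                                 seed = 1, channel_roles = NULL,
                                 ramp_s = 0.02, subject = "s1",
                                 condition = "off") {
  stopifnot(length(states) >= 1, noise_sd >= 0, fs > 0)
  K <- max(length(per_state_channel_spectra), max(states))
  labels <- unique(c(
    unlist(lapply(per_state_channel_spectra, names)),
    unlist(lapply(couplings, function(cp) c(cp$source_channel, cp$target_channel)))))
  if (length(labels) == 0) stop("no channels defined")
  roles <- rep("cortical", length(labels))
  names(roles) <- labels
  if (!is.null(channel_roles)) {
    unknown <- setdiff(names(channel_roles), labels)
    if (length(unknown)) stop("role given for unknown channel: ",
                              paste(unknown, collapse = ", "))
    roles[names(channel_roles)] <- channel_roles
  }
  n <- length(states)
  max_hz <- max(unlist(lapply(seq_len(K), function(k) {
    sp <- if (k <= length(per_state_channel_spectra))
      per_state_channel_spectra[[k]] else NULL
    vapply(unlist(sp, recursive = FALSE), function(o) o$center_hz, 0)
  })), 0)
  if (fs <= 2 * max_hz) stop("sampling rate must exceed twice the highest centre frequency")

  X <- NULL
  lfp_beta <- numeric(n)   # clean beta-band component on LFP channels
  withr_seed(seed, {
    X <- matrix(stats::rnorm(length(labels) * n, sd = noise_sd),
                nrow = length(labels), dimnames = list(labels, NULL))
    gates <- lapply(seq_len(K), function(k) smooth_gate(states == k, fs, ramp_s))
    for (k in seq_len(K)) {
      sp <- if (k <= length(per_state_channel_spectra))
        per_state_channel_spectra[[k]] else NULL
      if (is.null(sp)) next
      for (ch in names(sp)) {
        for (osc in sp[[ch]]) {
          if (osc$amplitude <= 0) next
          comp <- gates[[k]] * band_limited_noise(n, osc, fs)
          X[ch, ] <- X[ch, ] + comp
          if (roles[[ch]] == "lfp" && osc$center_hz >= 13 && osc$center_hz <= 30)
            lfp_beta <- lfp_beta + comp
        }
      }
    }
    for (cp in couplings) {
      if (!all(c(cp$source_channel, cp$target_channel) %in% labels))
        stop("coupling references an unknown channel")
      g <- smooth_gate(states %in% cp$active_states, fs, ramp_s)
      s <- band_limited_noise(n, cp$band, fs)
      X[cp$source_channel, ] <- X[cp$source_channel, ] + g * s
      X[cp$target_channel, ] <- X[cp$target_channel, ] + cp$mixing * g * s
      if (roles[[cp$target_channel]] == "lfp" && cp$band$center_hz >= 13 &&
          cp$band$center_hz <= 30)
        lfp_beta <- lfp_beta + cp$mixing * g * s
    }
  })

  rec <- recording(X, fs = fs, channel_labels = labels,
                   channel_roles = unname(roles[labels]),
                   subject = subject, condition = condition)
  # reference bursts: threshold rule applied to the noise-free beta component
  gt_bursts <- if (any(lfp_beta != 0) && n / fs > 1) {
    env <- Mod(analytic_signal(lfp_beta))
    detect_bursts(env, fs)$intervals
  } else data.frame(start = integer(0), end = integer(0))
  list(recording = rec,
       ground_truth = list(state_sequence = states,
                           burst_intervals = gt_bursts,
                           coupling_specs = couplings))
}

#' Default cohort design
#'
#' Describes the simulated world used by [make_paired_cohort()]: K network
#' states switching with ~2-s mean lifetime, four cortical channels and one
#' LFP ("STN") channel, state-specific oscillators, LFP-cortex coupling in
#' two designated states (an alpha-band coupling in state 1 and a beta-band
#' coupling in state `K - 2`), a beta oscillator on the LFP in every state,
#' and medication-sensitive beta amplitude in the non-coupled states.
#'
#' @param n_states Number of states (8 by default; 10 or 12 for robustness
#'   re-runs).
#' @param fs Sampling rate in Hz (250 by default, the post-resampling rate of
#'   the analysis this emulates).
#' @param duration_s Scan length per condition in seconds.
#' @param dwell_s Mean state lifetime in seconds.
#' @param noise_sd White-noise floor standard deviation.
#' @return List describing the design (markov spec, spectra, couplings,
#'   coupled/medication state sets, channel roles).
#' @export
cohort_design <- function(n_states = 8, fs = 250, duration_s = 1800,
                          dwell_s = 2, noise_sd = 1) {
  stopifnot(n_states >= 4)
  K <- n_states
  cortical <- c("SMA", "M1", "VIS", "FRT")
  lfp <- "STN"
  coupled_states <- c(1L, as.integer(K - 2))       # e.g. states 1 and 6 for K = 8
  med_states <- setdiff(seq_len(K), coupled_states)

  # distinct multi-region oscillator layouts make state covariances
  # separable: each state has a primary and a secondary cortical channel
  # with power at a state-specific frequency
  freqs <- seq(6, 38, length.out = K)
  spectra <- vector("list", K)
  for (k in seq_len(K)) {
    ch1 <- cortical[(k - 1) %% length(cortical) + 1]
    ch2 <- cortical[k %% length(cortical) + 1]
    sp <- list()
    sp[[ch1]] <- list(oscillator_spec(freqs[k], 6, 2.2))
    sp[[ch2]] <- list(oscillator_spec(freqs[k], 6, 1.5))
    # every state carries an LFP beta oscillator; coupled states carry more
    lfp_amp <- if (k %in% coupled_states) 1.5 else 1.2
    sp[[lfp]] <- list(oscillator_spec(21, 10, lfp_amp))
    if (k == coupled_states[1])
      sp[[lfp]] <- c(sp[[lfp]], list(oscillator_spec(10, 6, 1.2)))
    spectra[[k]] <- sp
  }
  # widespread alpha in state 1 (default-mode-like), beta-band sensorimotor
  # activation in the second coupled state
  for (ch in cortical) spectra[[1]][[ch]] <- list(oscillator_spec(10, 6, 2.0))
  spectra[[coupled_states[2]]][["SMA"]] <- list(oscillator_spec(22, 12, 2.2))
  spectra[[coupled_states[2]]][["M1"]] <- list(oscillator_spec(22, 12, 1.8))

  # within-state cortico-cortical phase coupling (networks are coherent
  # region sets) plus the two LFP-cortex couplings under study
  couplings <- lapply(seq_len(K), function(k) {
    ch1 <- cortical[(k - 1) %% length(cortical) + 1]
    ch2 <- cortical[k %% length(cortical) + 1]
    coupling_spec(ch1, ch2, k, oscillator_spec(freqs[k], 6, 1.5), 0.8)
  })
  couplings <- c(couplings, list(
    coupling_spec("SMA", "STN", coupled_states[1], oscillator_spec(11, 7, 2.0), 1.0),
    coupling_spec("SMA", "STN", coupled_states[2], oscillator_spec(22, 9, 1.8), 1.0)))

  list(n_states = K, fs = fs, duration_s = duration_s, noise_sd = noise_sd,
       markov = uniform_markov_spec(K, dwell_s, fs),
       spectra = spectra, couplings = couplings,
       coupled_states = coupled_states, med_states = med_states,
       channel_roles = c(STN = "lfp"),
       channels = c(cortical, lfp))
}

#' Generate a paired medication-off / medication-on cohort
#'
#' Every subject receives an off- and an on-condition recording generated
#' from the same design; in the on condition the amplitudes of LFP
#' beta-band oscillators in state `k` are multiplied by `med_beta_gain[k]`.
#' Subject-level random effects (log-normal amplitude factors, sd 10%) and
#' all realisations derive deterministically from per-subject seeds.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param med_beta_gain Length-K non-negative gains (1 = no effect).
#' @param seed Master seed.
#' @param design A [cohort_design()].
#' @return List of subjects, each with `off`, `on` (recordings) and
#'   `ground_truth` per condition.
#' @export
make_paired_cohort <- function(n_subjects, med_beta_gain = NULL, seed = 1,
                               design = cohort_design()) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  K <- design$n_states
  if (is.null(med_beta_gain)) med_beta_gain <- rep(1, K)
  if (length(med_beta_gain) == 1) med_beta_gain <- rep(med_beta_gain, K)
  if (length(med_beta_gain) != K) stop("med_beta_gain must have one entry per state")
  if (any(med_beta_gain < 0)) stop("medication gains must be non-negative")

  n <- round(design$duration_s * design$fs)
  lapply(seq_len(n_subjects), function(s) {
    sseed <- (seed + 7919 * s) %% .Machine$integer.max
    # subject random effect: one log-normal amplitude factor
    amp_fac <- withr_seed(sseed, exp(stats::rnorm(1, 0, 0.1)))
    scale_spectra <- function(gain_by_state) {
      sp <- design$spectra
      for (k in seq_len(K)) {
        for (ch in names(sp[[k]])) {
          sp[[k]][[ch]] <- lapply(sp[[k]][[ch]], function(o) {
            a <- o$amplitude * amp_fac
            is_lfp_beta <- !is.null(design$channel_roles[ch]) &&
              identical(unname(design$channel_roles[ch]), "lfp") &&
              o$center_hz >= 13 && o$center_hz <= 30
            if (is_lfp_beta) a <- a * gain_by_state[k]
            oscillator_spec(o$center_hz, o$bandwidth_hz, a)
          })
        }
      }
      sp
    }
    run <- function(condition, gain_by_state, sub_seed) {
      states <- sample_state_sequence(design$markov, n, sub_seed)
      synthesize_recording(states, scale_spectra(gain_by_state),
                           design$couplings, design$noise_sd, design$fs,
                           seed = sub_seed + 1,
                           channel_roles = design$channel_roles,
                           subject = sprintf("sub%02d", s),
                           condition = condition)
    }
    off <- run("off", rep(1, K), sseed + 100)
    on <- run("on", med_beta_gain, sseed + 200)
    list(subject = sprintf("sub%02d", s),
         off = off$recording, on = on$recording,
         ground_truth = list(off = off$ground_truth, on = on$ground_truth))
  })
}
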