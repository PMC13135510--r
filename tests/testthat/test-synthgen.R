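# Synthetic generator: Markov sampling, state-gated oscillators,
# state-dependent coupling, and the paired medication cohort.

test_that("sample_state_sequence follows the chain's law", {
  # absorbing chain stays put
  sp <- markov_spec(diag(2), initial = c(1, 0))
  expect_true(all(sample_state_sequence(sp, 100, seed = 1) == 1L))

  # mean dwell length 1/(1 - stay)
  sp2 <- uniform_markov_spec(2, dwell_s = 100, fs = 1)   # stay = 0.99
  s <- sample_state_sequence(sp2, 100000, seed = 2)
  dwell <- mean(rle(s)$lengths)
  expect_lt(abs(dwell - 100) / 100, 0.05)

  # stationary occupancy of a symmetric chain (dwell 10 mixes fast enough
  # for the 2% tolerance at this length)
  s3 <- sample_state_sequence(uniform_markov_spec(2, 10, 1), 200000, seed = 3)
  expect_lt(abs(mean(s3 == 1) - 0.5), 0.02)

  # reproducibility and seed sensitivity
  expect_identical(sample_state_sequence(sp2, 1000, seed = 9),
                   sample_state_sequence(sp2, 1000, seed = 9))
  expect_false(identical(sample_state_sequence(sp2, 1000, seed = 9),
                         sample_state_sequence(sp2, 1000, seed = 10)))
})

test_that("markov_spec rejects non-stochastic input", {
  expect_error(markov_spec(matrix(c(0.5, 0.4, 0.2, 0.8), 2)), "sum to 1")
  expect_error(markov_spec(matrix(c(1.2, -0.2, 0, 1), 2, byrow = TRUE)),
               "non-negative")
})

test_that("synthesize_recording: pure noise has unit variance", {
  st <- rep(1L, 20000)
  out <- synthesize_recording(st, list(list(ch1 = list())), noise_sd = 1,
                              fs = 100, seed = 4)
  expect_lt(abs(stats::var(out$recording$data[1, ]) - 1), 0.05)
})

test_that("coupling produces the closed-form in-band coherence", {
  # y1 = s + n1, y2 = a s + n2 with a one-state chain: msc =
  # a^2 Ps^2 / ((Ps + P1)(a^2 Ps + P2)) with P1 = P2 = white-noise level
  n <- 120000; fs <- 100; a <- 0.8
  st <- rep(1L, n)
  cp <- coupling_spec("c1", "c2", 1L, oscillator_spec(20, 8, 1.5), mixing = a)
  out <- synthesize_recording(st, list(list(c1 = list(), c2 = list())),
                              couplings = list(cp), noise_sd = 1, fs = fs,
                              seed = 5)
  tp <- make_tapers(2, 7, fs)
  sp <- state_weighted_csd(out$recording, NULL, tp)
  co <- coherence(sp, c("c1", "c2"))
  sel <- sp$freqs >= 17.5 & sp$freqs <= 22.5
  # predicted from the source band power measured on an identical clean run
  clean <- netstates:::withr_seed(5, {
    # replicate the generator's component draw order: noise first, then s
    stats::rnorm(2 * n)
    netstates:::band_limited_noise(n, oscillator_spec(20, 8, 1.5), fs)
  })
  sps <- state_weighted_csd(matrix(clean, 1), NULL, tp)
  Ps <- Re(sps$csd[[1]][sel, 1, 1])
  Pn <- 2 / fs   # one-sided white-noise PSD at unit variance
  pred <- (a^2 * Ps^2) / ((Ps + Pn) * (a^2 * Ps + Pn))
  expect_lt(abs(mean(co$values[sel]^2) - mean(pred)), 0.05)
})

test_that("coupling inactive in a state stays at the bias floor", {
  n <- 60000; fs <- 100
  st <- rep(rep(c(1L, 2L), each = 1000), length.out = n)
  cp <- coupling_spec("c1", "c2", 2L, oscillator_spec(20, 8, 2), mixing = 1)
  out <- synthesize_recording(st, list(list(c1 = list(), c2 = list())),
                              couplings = list(cp), noise_sd = 1, fs = fs,
                              seed = 6)
  gamma <- cbind(st == 1, st == 2) * 1
  tp <- make_tapers(2, 7, fs)
  sp <- state_weighted_csd(out$recording, gamma, tp)
  co1 <- coherence(sp, c("c1", "c2"), state = 1)
  co2 <- coherence(sp, c("c1", "c2"), state = 2)
  sel <- sp$freqs >= 17 & sp$freqs <= 23
  # bias floor from matched uncoupled surrogates
  floor_vals <- vapply(1:10, function(r) {
    set.seed(100 + r)
    Xs <- matrix(rnorm(2 * n), 2)
    sps <- state_weighted_csd(Xs, gamma, tp)
    mean(coherence(sps, c(1, 2), state = 1)$values[sel])
  }, 0)
  expect_lt(mean(co1$values[sel]), max(floor_vals) * 1.5)
  expect_gt(mean(co2$values[sel]), 3 * max(floor_vals))
})

test_that("state gating confines oscillator power to the active state", {
  n <- 40000; fs <- 100
  st <- rep(rep(c(1L, 2L), each = 500), length.out = n)
  spectra <- list(list(ch = list(oscillator_spec(20, 6, 2))),
                  list(ch = list()))
  out <- synthesize_recording(st, spectra, noise_sd = 1, fs = fs, seed = 7)
  gamma <- cbind(st == 1, st == 2) * 1
  sp <- state_weighted_csd(out$recording, gamma, make_tapers(2, 7, fs))
  p1 <- power_spectrum(sp, "ch", 1); p2 <- power_spectrum(sp, "ch", 2)
  sel <- sp$freqs >= 17 & sp$freqs <= 23
  expect_gt(mean(p1$power[sel]) / mean(p2$power[sel]), 3)
  # spectral peak lands within one bin of the centre frequency
  expect_lt(abs(p1$freqs[which.max(p1$power)] - 20), 0.5 + 1e-9)
})

test_that("identical seeds give identical recordings, new seeds differ", {
  st <- rep(1L, 3000)
  spl <- list(list(a = list(oscillator_spec(10, 4, 1)), b = list()))
  r1 <- synthesize_recording(st, spl, noise_sd = 1, fs = 100, seed = 11)
  r2 <- synthesize_recording(st, spl, noise_sd = 1, fs = 100, seed = 11)
  r3 <- synthesize_recording(st, spl, noise_sd = 1, fs = 100, seed = 12)
  expect_identical(r1$recording$data, r2$recording$data)
  expect_false(identical(r1$recording$data, r3$recording$data))
})

test_that("make_paired_cohort scales LFP beta power by gain squared", {
  design <- cohort_design(n_states = 4, fs = 100, duration_s = 120,
                          dwell_s = 2)
  gains <- rep(1, 4); gains[design$med_states] <- 0.5
  cohort <- make_paired_cohort(4, gains, seed = 21, design = design)
  # conditional LFP beta power during medication states, on vs off
  ratios <- vapply(cohort, function(sub) {
    pow <- vapply(c(off = "off", on = "on"), function(cond) {
      rec <- sub[[cond]]
      st <- sub$ground_truth[[cond]]$state_sequence
      sel <- st %in% design$med_states
      co <- butter_design(4, c(13, 30), rec$fs, "pass")
      x <- filtfilt(co, rec$data[channel_idx <- which(rec$channel_roles == "lfp"), ])
      # remove the state-independent floor using non-med states
      stats::var(x[sel])
    }, 0)
    pow["on"] / pow["off"]
  }, 0)
  # LFP beta in med states: oscillator (amp a) scaled by 0.5 plus coupling-free
  # noise floor; the oscillator-dominated ratio should fall well below 1 and
  # near 0.25 once the shared noise floor is accounted for loosely
  expect_true(all(ratios < 0.6))
  expect_lt(abs(mean(ratios) - 0.35), 0.25)
})

test_that("cohort input validation", {
  design <- cohort_design(n_states = 4, fs = 100, duration_s = 30)
  expect_error(make_paired_cohort(0, design = design), "at least 2")
  expect_error(make_paired_cohort(2, med_beta_gain = c(-1, 1, 1, 1),
                                  seed = 1, design = design), "non-negative")
  expect_error(make_paired_cohort(2, med_beta_gain = c(1, 1), seed = 1,
                                  design = design), "one entry per state")
})

test_that("paired cohort with unit gains is a medication null", {
  # 120-s scans with 1-s dwells give enough state visits for the paired t
  # to hold its level at n = 8; fully seeded, so deterministic
  design <- cohort_design(n_states = 4, fs = 100, duration_s = 120, dwell_s = 1)
  pvals <- vapply(1:20, function(r) {
    cohort <- make_paired_cohort(8, rep(1, 4), seed = 500 + r, design = design)
    bp <- vapply(cohort, function(sub) {
      vapply(c("off", "on"), function(cond) {
        rec <- sub[[cond]]
        co <- butter_design(4, c(13, 30), rec$fs, "pass")
        stats::var(filtfilt(co, rec$data[which(rec$channel_roles == "lfp"), ]))
      }, 0)
    }, c(0, 0))
    stats::t.test(bp[1, ], bp[2, ], paired = TRUE)$p.value
  }, 0)
  expect_gte(mean(pvals > 0.05), 0.9)
})
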