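# End-to-end orchestration on synthetic cohorts: generate -> preprocess ->
# embed/PCA -> canonical-state HMM inference -> state-weighted spectra ->
# state-vs-time-averaged contrasts (power, coherence, imaginary-coherence
# control) -> burst overlap -> medication contrasts (with and without GESD
# outlier exclusion), all under one seed registry.

#' Pipeline configuration
#'
#' Central registry of the analysis parameters; every value is validated
#' against the module preconditions before any stage runs.
#'
#' @param n_states Number of HMM states K (8; 10 and 12 for robustness).
#' @param n_subjects Number of simulated subjects.
#' @param fs Sampling rate in Hz.
#' @param duration_s Scan duration per condition in seconds.
#' @param n_lags Embedding lags each side (7).
#' @param n_pca Principal components kept (120, capped at the embedded
#'   dimension).
#' @param window_s,n_tapers Multitaper window and taper count (2 s, 7).
#' @param analysis_band Frequency band for spectral contrasts in Hz.
#' @param beta_band Beta band in Hz for burst detection and power summaries.
#' @param burst_percentile,burst_min_s Burst rule (75th percentile, 0.1 s).
#' @param n_perm Permutations for all tests (1000).
#' @param cluster_alpha Cluster-forming significance level (0.05).
#' @param alpha Family-wise alpha before Bonferroni (0.05).
#' @param med_beta_gain Per-state medication gain on LFP beta amplitude;
#'   default 1 (null) everywhere except the design's medication-sensitive
#'   states, which get `med_gain_value`.
#' @param med_gain_value Gain applied in the designed medication states.
#' @param normative_duration_s Length of the simulated normative scan used
#'   for the canonical-state fit (3x the subject scan by default, mirroring
#'   the larger external datasets canonical states are learned from).
#' @param dwell_s Mean state lifetime of the simulated chain in seconds.
#' @param seed Master seed.
#' @param n_restarts HMM restarts for the canonical fit.
#' @param hmm_max_iter EM iteration cap.
#' @export
pipeline_config <- function(n_states = 8, n_subjects = 25, fs = 250,
                            duration_s = 1800, n_lags = 7, n_pca = 120,
                            window_s = 2, n_tapers = 7,
                            analysis_band = c(1, 45), beta_band = c(13, 30),
                            burst_percentile = 75, burst_min_s = 0.1,
                            n_perm = 1000, cluster_alpha = 0.05, alpha = 0.05,
                            med_beta_gain = NULL, med_gain_value = 0.5,
                            normative_duration_s = NULL,
                            dwell_s = 2, seed = 1, n_restarts = 3,
                            hmm_max_iter = 60) {
  stopifnot(n_states >= 2, n_subjects >= 2, fs > 0, duration_s * fs > 2 * n_lags,
            n_lags >= 0, window_s > 0, n_tapers >= 1, n_perm >= 1,
            cluster_alpha > 0, cluster_alpha < 1,
            beta_band[2] < fs / 2, analysis_band[2] < fs / 2)
  design <- cohort_design(n_states = n_states, fs = fs,
                          duration_s = duration_s, dwell_s = dwell_s)
  if (is.null(normative_duration_s)) normative_duration_s <- 3 * duration_s
  if (is.null(med_beta_gain)) {
    med_beta_gain <- rep(1, n_states)
    med_beta_gain[design$med_states] <- med_gain_value
  }
  stopifnot(length(med_beta_gain) == n_states, all(med_beta_gain >= 0))
  structure(list(n_states = n_states, n_subjects = n_subjects, fs = fs,
                 duration_s = duration_s, n_lags = n_lags, n_pca = n_pca,
                 window_s = window_s, n_tapers = n_tapers,
                 analysis_band = analysis_band, beta_band = beta_band,
                 burst_percentile = burst_percentile, burst_min_s = burst_min_s,
                 n_perm = n_perm, cluster_alpha = cluster_alpha, alpha = alpha,
                 med_beta_gain = med_beta_gain, dwell_s = dwell_s, seed = seed,
                 normative_duration_s = normative_duration_s,
                 n_restarts = n_restarts, hmm_max_iter = hmm_max_iter,
                 design = design),
            class = "pipeline_config")
}

# preprocess one recording: band-pass to the analysis band, flag bad
# segments, standardise
preprocess_recording <- function(rec, config) {
  spec <- filter_spec(band = config$analysis_band, order = 5)
  rec <- filter_resample(rec, spec)
  rec$bad_mask <- rec$bad_mask | detect_bad_segments(rec, window_s = config$window_s)
  standardize(rec)
}

#' Fit a canonical state model on a normative recording
#'
#' Embeds and PCA-reduces the recording, fits the HMM, and matches the
#' estimated states to the ground-truth state sequence (when provided) so
#' that downstream reporting uses ground-truth state numbering.
#'
#' @param rec A preprocessed [recording()].
#' @param config A [pipeline_config()].
#' @param true_states Optional ground-truth state sequence for relabelling.
#' @return List with `model`, `basis`, `embedding`, and `fit` diagnostics.
#' @export
fit_canonical_model <- function(rec, config, true_states = NULL) {
  emb <- time_delay_embed(rec$data, embedding_config(config$n_lags),
                          bad_mask = rec$bad_mask)
  P <- min(config$n_pca, ncol(emb$Y))
  basis <- fit_pca(emb, P = P)
  Y <- pca_project(basis, emb)
  fit <- fit_hmm(Y, K = config$n_states, seed = config$seed,
                 n_restarts = config$n_restarts,
                 max_iter = config$hmm_max_iter, good = emb$good)
  model <- fit$model
  post <- fit$posterior
  if (!is.null(true_states)) {
    # overlap matrix between hard assignments and true labels
    hard <- post$viterbi_path
    truth <- true_states[(emb$offset + 1):(length(true_states) - emb$offset)]
    K <- config$n_states
    ov <- matrix(0, K, K)
    ok <- !is.na(hard)
    for (k in seq_len(K))
      for (j in seq_len(K))
        ov[k, j] <- sum(hard[ok] == k & truth[ok] == j)
    perm <- hungarian_max(ov / max(ov))
    model <- permute_states(model, perm)
  }
  list(model = model, basis = basis,
       embedding = embedding_config(config$n_lags), fit = fit)
}

# posterior for one recording under the canonical model
infer_subject_gamma <- function(rec, canonical, config) {
  emb <- time_delay_embed(rec$data, canonical$embedding, bad_mask = rec$bad_mask)
  Y <- pca_project(canonical$basis, emb)
  post <- infer_with_canonical_states(canonical$model, Y, good = emb$good,
                                      max_iter = 25)
  list(post = post, offset = emb$offset)
}

# state-specific + time-averaged spectra and derived summaries per recording
subject_spectra <- function(rec, gamma_info, config, tapers) {
  sp <- state_weighted_csd(rec, gamma_info$post$gamma, tapers,
                           offset = gamma_info$offset)
  avg <- time_average_spectrum(sp)
  list(state = sp, avg = avg)
}

# matrix (subjects x freqs) of state-minus-average differences of a
# per-frequency quantity; extractor(spectra, state) -> values over freqs
state_vs_avg_matrix <- function(per_subject, extractor, state, sel) {
  do.call(rbind, lapply(per_subject, function(ss) {
    v_state <- extractor(ss$state, state)
    v_avg <- extractor(ss$avg, NULL)
    (v_state - v_avg)[sel]
  }))
}

#' Run the full analysis on a synthetic cohort
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional cohort from [make_paired_cohort()]; generated from
#'   the config when omitted.
#' @param canonical Optional canonical model from [fit_canonical_model()];
#'   when omitted, a normative scan is simulated (coupling-free state
#'   dynamics with the same observation design) and the model fit on it.
#' @param out_dir Optional directory for the report bundle (JSON manifest +
#'   CSV tables).
#' @return Report list: per-state coherence/power contrasts, imaginary
#'   coherence control, burst overlap test, medication contrasts (with and
#'   without GESD exclusion), fractional occupancies, seeds and parameters.
#' @export
run_full_analysis <- function(config, cohort = NULL, canonical = NULL,
                              out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  K <- config$n_states
  design <- config$design
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  if (is.null(cohort))
    cohort <- stage("simulate",
                    make_paired_cohort(config$n_subjects, config$med_beta_gain,
                                       seed = config$seed, design = design))
  n_sub <- length(cohort)

  if (is.null(canonical)) {
    canonical <- stage("canonical-fit", {
      norm_states <- sample_state_sequence(design$markov,
                                           round(config$normative_duration_s * design$fs),
                                           seed = config$seed + 31L)
      norm <- synthesize_recording(norm_states, design$spectra, design$couplings,
                                   design$noise_sd, design$fs,
                                   seed = config$seed + 32L,
                                   channel_roles = design$channel_roles,
                                   subject = "normative")
      rec <- preprocess_recording(norm$recording, config)
      fit_canonical_model(rec, config, true_states = norm_states)
    })
  }

  tapers <- make_tapers(config$window_s, config$n_tapers, config$fs)
  lfp_lab <- "STN"; sma_lab <- "SMA"
  sel_band <- NULL

  per_subject <- stage("spectra", lapply(cohort, function(sub) {
    out <- list()
    for (cond in c("off", "on")) {
      rec <- preprocess_recording(sub[[cond]], config)
      gi <- infer_subject_gamma(rec, canonical, config)
      sp <- subject_spectra(rec, gi, config, tapers)
      # burst overlap on the gamma-covered portion of the scan
      lfp_row <- rec$data[channel_index(rec, lfp_lab), ]
      env <- amplitude_envelope(lfp_row, config$beta_band, rec$fs)
      rng <- (gi$offset + 1):(gi$offset + nrow(gi$post$gamma))
      bs <- detect_bursts(env[rng], rec$fs, config$burst_percentile,
                          config$burst_min_s, good = !rec$bad_mask[rng])
      overlap <- vapply(seq_len(K), function(k)
        burst_state_overlap(bs, gi$post$gamma, k)$contrast_pct, 0)
      out[[cond]] <- list(spectra = sp, fo = fractional_occupancy(gi$post),
                          overlap = overlap,
                          beta_power = vapply(seq_len(K), function(k) {
                            if (is.null(sp$state$csd[[k]])) return(NA_real_)
                            band_power(power_spectrum(sp$state, lfp_lab, k),
                                       config$beta_band)
                          }, 0),
                          beta_power_avg = band_power(
                            power_spectrum(sp$avg, lfp_lab, 1), config$beta_band))
    }
    out
  }))

  freqs <- per_subject[[1]]$off$spectra$state$freqs
  sel_band <- freqs >= config$analysis_band[1] & freqs <= config$analysis_band[2]
  fsel <- freqs[sel_band]
  bonf <- bonferroni_threshold(config$alpha, K)

  coh_extract <- function(sp, state, kind = "magnitude") {
    st <- if (is.null(state)) 1 else state
    coherence(sp, c(sma_lab, lfp_lab), state = st, kind = kind,
              debias = TRUE)$values
  }
  pow_extract <- function(sp, state) {
    st <- if (is.null(state)) 1 else state
    power_spectrum(sp, lfp_lab, st)$power
  }

  # per-subject spectra averaged over the two scans, as in a two-scan design
  both <- lapply(per_subject, function(s) s)   # keep structure; averaging below

  contrast_per_state <- function(extractor, kind = NULL) {
    lapply(seq_len(K), function(k) {
      M <- do.call(rbind, lapply(per_subject, function(s) {
        rows <- lapply(c("off", "on"), function(cond) {
          sp <- s[[cond]]$spectra
          if (is.null(sp$state$csd[[k]])) return(NULL)
          v_state <- if (is.null(kind)) extractor(sp$state, k)
                     else coh_extract(sp$state, k, kind)
          v_avg <- if (is.null(kind)) extractor(sp$avg, NULL)
                   else coh_extract(sp$avg, NULL, kind)
          (v_state - v_avg)[sel_band]
        })
        rows <- rows[!vapply(rows, is.null, TRUE)]
        if (!length(rows)) return(NULL)
        colMeans(do.call(rbind, rows))
      }))
      if (is.null(M) || nrow(M) < 2) return(NULL)
      M[is.na(M)] <- 0
      cluster_permutation_test(M, freqs = fsel, n_perm = config$n_perm,
                               cluster_alpha = config$cluster_alpha,
                               seed = config$seed + 100L + k)
    })
  }

  coh_results <- stage("coherence-contrasts", contrast_per_state(NULL, "magnitude"))
  icoh_results <- stage("imaginary-coherence-control",
                        contrast_per_state(NULL, "imaginary"))
  pow_results <- stage("power-contrasts", contrast_per_state(pow_extract))

  # burst-overlap contrast per state (subject means over scans), max-t pooled
  overlap_mat <- do.call(rbind, lapply(per_subject, function(s)
    colMeans(rbind(s$off$overlap, s$on$overlap), na.rm = TRUE)))
  overlap_test <- stage("burst-overlap",
                        max_t_permutation(overlap_mat, n_perm = config$n_perm,
                                          seed = config$seed + 200L))

  # medication contrasts on state-specific LFP beta power (off - on)
  med_diff <- do.call(rbind, lapply(per_subject, function(s)
    s$off$beta_power - s$on$beta_power))
  med_avg_diff <- vapply(per_subject, function(s)
    s$off$beta_power_avg - s$on$beta_power_avg, 0)
  run_med <- function(M) {
    ok <- stats::complete.cases(M)
    if (sum(ok) < 2) return(NULL)
    max_t_permutation(M[ok, , drop = FALSE], n_perm = config$n_perm,
                      seed = config$seed + 300L)
  }
  med_test_all <- stage("medication-contrast", run_med(med_diff))
  # GESD exclusion on the subject-level time-averaged beta-power differences
  ges <- gesd(med_avg_diff, alpha = config$alpha)
  keep <- setdiff(seq_len(n_sub), ges$outlier_indices)
  med_test_gesd <- stage("medication-contrast-gesd",
                         run_med(med_diff[keep, , drop = FALSE]))
  med_timeavg <- stage("medication-timeavg",
                       max_t_permutation(matrix(med_avg_diff, ncol = 1),
                                         n_perm = config$n_perm,
                                         seed = config$seed + 301L))

  fo_mat <- do.call(rbind, lapply(per_subject, function(s)
    colMeans(rbind(s$off$fo, s$on$fo))))

  sig_states <- function(results, positive = TRUE) {
    which(vapply(seq_len(K), function(k) {
      r <- results[[k]]
      if (is.null(r) || nrow(r$clusters) == 0) return(FALSE)
      cl <- r$clusters
      if (positive) cl <- cl[cl$mean_t > 0, , drop = FALSE]
      any(cl$p_value < bonf)
    }, TRUE))
  }

  report <- list(
    parameters = unclass(config)[setdiff(names(unclass(config)), "design")],
    bonferroni_threshold = bonf,
    freqs = fsel,
    coherence = coh_results,
    imaginary_coherence = icoh_results,
    power = pow_results,
    significant_coherence_states = sig_states(coh_results),
    significant_power_states = sig_states(pow_results),
    burst_overlap = c(overlap_test,
                      list(mean_contrast_pct = colMeans(overlap_mat, na.rm = TRUE))),
    medication = list(all = med_test_all, gesd_excluded = med_test_gesd,
                      outliers = ges$outlier_indices,
                      time_averaged = med_timeavg,
                      significant_states =
                        if (!is.null(med_test_all))
                          which(med_test_all$p_corrected < config$alpha &
                                med_test_all$t > 0)
                        else integer(0),
                      significant_states_gesd =
                        if (!is.null(med_test_gesd))
                          which(med_test_gesd$p_corrected < config$alpha &
                                med_test_gesd$t > 0)
                        else integer(0)),
    fractional_occupancy = fo_mat,
    coupled_states = design$coupled_states,
    med_states = design$med_states,
    seed = config$seed)

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# serialise the report bundle: JSON manifest + CSV summary tables
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summarise_clusters <- function(results, label) {
    rows <- lapply(seq_along(results), function(k) {
      r <- results[[k]]
      if (is.null(r) || nrow(r$clusters) == 0) return(NULL)
      cbind(contrast = label, state = k, r$clusters)
    })
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  }
  tab <- rbind(summarise_clusters(report$coherence, "coherence"),
               summarise_clusters(report$imaginary_coherence, "imaginary_coherence"),
               summarise_clusters(report$power, "power"))
  if (!is.null(tab))
    utils::write.csv(tab, file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$fractional_occupancy),
                   file.path(out_dir, "fractional_occupancy.csv"),
                   row.names = FALSE)
  manifest <- list(
    parameters = report$parameters,
    bonferroni_threshold = report$bonferroni_threshold,
    significant_coherence_states = report$significant_coherence_states,
    significant_power_states = report$significant_power_states,
    medication = list(
      t = report$medication$all$t,
      p_corrected = report$medication$all$p_corrected,
      significant_states = report$medication$significant_states,
      significant_states_gesd = report$medication$significant_states_gesd,
      outliers = report$medication$outliers),
    burst_overlap = list(t = report$burst_overlap$t,
                         p_corrected = report$burst_overlap$p_corrected),
    coupled_states = report$coupled_states,
    med_states = report$med_states,
    seed = report$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Robustness sweep over the number of states
#'
#' Re-runs the full analysis for each K, refitting the canonical model, and
#' reports the per-K significant-state sets and fractional occupancies.
#'
#' @param config A [pipeline_config()] (its K is replaced per run).
#' @param K_list State counts to sweep (8, 10, 12 by default).
#' @return List per K with the significant coherence/medication states and
#'   occupancies.
#' @export
robustness_sweep <- function(config, K_list = c(8, 10, 12)) {
  stopifnot(all(K_list >= 2))
  lapply(stats::setNames(K_list, paste0("K", K_list)), function(K) {
    cfg <- pipeline_config(
      n_states = K, n_subjects = config$n_subjects, fs = config$fs,
      duration_s = config$duration_s, n_lags = config$n_lags,
      n_pca = config$n_pca, window_s = config$window_s,
      n_tapers = config$n_tapers, analysis_band = config$analysis_band,
      beta_band = config$beta_band, n_perm = config$n_perm,
      cluster_alpha = config$cluster_alpha, alpha = config$alpha,
      dwell_s = config$dwell_s, seed = config$seed,
      n_restarts = config$n_restarts, hmm_max_iter = config$hmm_max_iter)
    rep <- run_full_analysis(cfg)
    list(n_states = K,
         significant_coherence_states = rep$significant_coherence_states,
         significant_power_states = rep$significant_power_states,
         medication_significant_states = rep$medication$significant_states,
         coupled_states = rep$coupled_states,
         fractional_occupancy = colMeans(rep$fractional_occupancy))
  })
}
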