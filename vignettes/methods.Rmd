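---
title: "Methods: dynamic network states and subcortical coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic network states and subcortical coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and estimators it
implements, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## 1. The model

### State model (TDE-HMM)

Multichannel recordings (cortical parcel channels plus one subcortical LFP
channel, standardised per channel) are modelled as switching between K
transient network states.  Each sample is time-delay embedded with ±L lags
(default L = 7, so a C-channel recording becomes C·(2L+1)-dimensional),
reduced to P principal components (default P = 120, capped at the embedded
dimension), and the projected series Y is modelled by a hidden Markov model
with zero-mean, full-covariance Gaussian emissions:

- hidden chain: `z_t ∈ {1..K}`, row-stochastic transition matrix A,
  initial distribution π;
- emissions: `y_t | z_t = k ~ N(0, Σ_k)` with Σ_k a P×P covariance.

Because the embedding stacks lagged copies of every channel, Σ_k encodes
the state's multichannel auto- and cross-covariance over a ±L-sample
horizon — i.e. its spectral power and phase-coupling pattern, which is what
distinguishes large-scale networks.  Means are fixed at zero by design
(the data are standardised; states are covariance-defined).

Inference is maximum-likelihood EM (Baum–Welch) rather than variational
Bayes: every downstream quantity in this package consumes the posterior
state probabilities γ (the "state time courses") and the fitted
covariances, not Bayesian model evidence, so the extra machinery of a
variational treatment buys nothing here.  Numerical safeguards:

- the forward–backward recursions (compiled, `src/forward_backward.cpp`)
  are scaled per sample, with the per-sample maximum log-density factored
  out, so no K or P can underflow them;
- every M-step covariance receives a ridge of `1e-6 × mean(diag)` for
  positive definiteness in high dimension;
- EM restarts (default 3) start from covariances of a random contiguous
  block segmentation of the data — a data-informed initialisation that
  keeps initial states spectrally diverse and, in our recovery tests, finds
  substantially better optima than perturbations of the global covariance;
- bad samples split the series into contiguous good segments; the chain
  restarts (with π) at each segment and the log evidence sums over
  segments.

### Canonical-state inference

For short or noisy recordings, fitting K states per subject is unstable.
The package therefore supports *canonical* state inference: observation
covariances are learned once on a normative recording
(`fit_canonical_model`) and held fixed while only the state time courses
(and, by default, the transition matrix) are estimated per subject
(`infer_with_canonical_states`).  Whether the transition matrix should be
re-estimated under canonical states is not settled; re-estimation is the
default and a flag disables it.  The pipeline matches fitted states to
ground-truth states with an exact Hungarian assignment on a similarity that
combines the correlation of vectorised covariances with a normalised
Frobenius distance — correlation alone is scale-invariant and cannot
separate states that share a pattern at different power levels.

### State-weighted multitaper spectra

Per-state spectra are estimated post hoc by pooling over all periods in
which a state occurred.  The recording is tiled into non-overlapping 2-s
windows (50% overlap by flag); each window w yields a taper-averaged
cross-spectral matrix P(w) (7 DPSS tapers, half-bandwidth
(n_tapers+1)/(2·window) = 2 Hz); the state-k estimate is

    S_k(f) = Σ_w w̄_k(w) P(w, f) / Σ_w w̄_k(w),

with w̄_k(w) the mean posterior probability of state k in window w.  The
window-mean weighting (rather than per-sample reweighting of the waveform)
preserves the within-window stationarity assumptions of the multitaper.
Two exact identities follow and are tested to 1e-12/1e-10: with γ ≡ 1 the
estimator reduces to the plain multitaper, and the occupancy-weighted
average of the S_k equals the all-window estimate.

Magnitude-squared coherence and absolute imaginary coherency (the
zero-lag-insensitive control) derive from S_k.  **Small-sample bias:** a
coherence estimated from L independent tapered windows has
E[coh²] ≈ 1/L under independence, so states with low occupancy are biased
upward relative to the time-averaged baseline.  At the 30-minute scan
lengths of real studies this is negligible; at desk scale it produced
systematic false-positive "coherence increases" in rarely visited states.
`coherence(..., debias = TRUE)` therefore applies the standard dof
correction `msc_u = (L·msc − 1)/(L − 1)` (clipped at zero), with
L = n_tapers × effective windows, where the effective window count under
soft weighting is `(Σ w̄)² / Σ w̄²`.  The pipeline's contrasts use the
debiased estimator; display-oriented functions default to the raw one.

### Bursts and overlap

LFP beta bursts are maximal runs where the amplitude envelope (z-score →
13–30 Hz zero-phase band-pass → |analytic signal|) strictly exceeds the
scan's 75th percentile for at least 100 ms.  Strict exceedance is
deliberate: a constant envelope yields no bursts, and boundary samples
equal to the threshold never count.  Overlap with state k is
`100 · |burst ∧ state_k| / |state_k|` with states binarised by per-sample
argmax of γ (ties to the lowest index; probability-weighted overlap is
available by flag for sensitivity analysis), and the reported contrast
subtracts the pooled overlap of all other states.

### Statistics

- **First level:** per-subject OLS; for a paired two-condition design with
  contrast (1, −1) this is exactly the within-subject difference.
- **Cluster permutation over frequency:** group one-sample t per frequency;
  sign-specific supra-threshold runs (|t| above the two-sided parametric
  critical value at α = 0.05, df = n − 1) form clusters scored by summed
  |t|; the null records the maximum cluster mass over subject-level sign
  flips; p = (1 + #{null ≥ obs}) / (1 + n_perm).  Positive and negative
  excursions form separate clusters — merging adjacent opposite-sign runs
  (a literal "|t| runs" reading) produced meaningless merged clusters with
  near-zero mean t.  Bonferroni (α/K) is applied to cluster p-values across
  the K state-wise tests.
- **Max-t permutation across states:** the null pools the maximum |t| over
  states per sign flip, yielding family-wise corrected per-state p-values.
- **GESD outlier test:** iterative removal of the most extreme studentized
  value, with t-based critical values; defaults α = 0.05, max outliers
  ⌈0.2 n⌉.  Degenerate inputs (n < 3, or max_outliers < 1) return no
  outliers rather than erroring, which is the behaviour bad-segment
  screening needs on two-window recordings.
- **Group contrasts** adjust for age and sex by OLS and compute the
  permutation p with the Freedman–Lane scheme (permute covariate-model
  residuals).
- All permutation p-values include the observed statistic (never 0) and are
  deterministic given the seed.

## 2. Key parameters

| parameter | default | units | why |
|---|---|---|---|
| embedding lags L | 7 | samples | ±7-sample window captures the autocovariance structure that separates oscillatory states at a 250-Hz rate |
| PCA components P | 120 (≤ embedded dim) | — | retains the covariance structure while making K full covariances estimable |
| states K | 8 (10, 12 robustness) | — | the operating point of the analysis this package reproduces; `robustness_sweep` re-runs at other K |
| multitaper window | 2 | s | 0.5-Hz frequency resolution; long enough for 7 orthogonal tapers |
| tapers | 7 | — | K = 2TW − 1 with W = 2 Hz half-bandwidth |
| beta band | 13–30 | Hz | the canonical beta range for STN pathology |
| burst rule | 75th pct / 0.1 | — / s | scan-relative amplitude threshold with a minimum duration that excludes noise blips |
| n_perm | 1000 | — | p-granularity 1/1001, fine enough for α/K Bonferroni decisions |
| cluster α | 0.05 | — | two-sided parametric cluster-forming threshold, df = n − 1 |
| GESD α / max frac | 0.05 / 0.20 | — | unstated in the source analyses; exposed in the config |

## 3. The synthetic world

`cohort_design()` states the simulated world once: K network states
switching with ~2-s mean lifetime; four cortical channels and one LFP
("STN") channel; each state activates a primary and a secondary cortical
channel at a state-specific frequency (6–38 Hz) via band-pass-filtered
Gaussian noise (so envelopes fluctuate and bursts emerge naturally, unlike
deterministic sinusoids), plus a within-state cortico-cortical shared
component (networks are coherent region sets, and covariance-defined state
inference needs that cross-channel signature); the LFP carries a beta
oscillator in every state; states 1 and K−2 additionally carry LFP–cortex
coupling, realised as a shared band-limited component injected into both
channels (alpha-band in state 1, beta-band in state K−2); the "on"
medication condition multiplies LFP beta amplitudes in the non-coupled
states by a per-state gain (default 0.5 → power ratio 0.25).  Subject-level
random effects are a single log-normal amplitude factor (sd 10%), drawn
from per-subject seeds derived from the master seed.  State gates use a
20-ms raised-cosine ramp to avoid filter-edge clicks; all intervals are
half-open `[start, end)` in samples.

Because the source data's empirical coupling SNR is uncharacterised, the
coupling amplitudes/mixing (1.8–2.0 / 0.9–1.0 relative to unit noise) were
chosen for testability — strong enough that a 12-subject, 180-s desk-scale
cohort has the power the acceptance criteria demand — and are not claimed
to be physiologically calibrated.

What the generator does **not** emulate: volume conduction / leakage (so
magnitude coherence is interpretable without leakage correction here,
which is *not* true of real MEG), 1/f background spectra (white noise
floor only), head geometry or sensor-level noise, heavy-tailed dwell-time
distributions, and electrode/contact selection.  A green end-to-end test
therefore establishes that the estimators and statistics recover the
stated generative structure — not that the pipeline is robust to real-MEG
artefacts that are out of scope here.

## 4. Scaled-down acceptance world

The end-to-end acceptance test runs 20 replicates of: K = 6, 12 subjects,
180-s scans per condition at 100 Hz, embedding ±7, PCA to 40 of 75
dimensions, canonical model fit once on a 360-s normative scan and reused
(exactly how canonical states are meant to be used), n_perm = 1000.  Two
constraints drove this scaling:

- **Permutation resolution.** A subject-level sign-flip test has at most
  2^n distinct sign patterns; with n = 8 the smallest achievable two-sided
  p (≈ 2/256) already exceeds the Bonferroni threshold α/K — detection is
  *impossible by construction*.  n = 12 with 1000 permutations gives a
  floor of 1/1001 with usable headroom below α/6.
- **Occupancy.** With mean 2-s dwells, a 180-s scan gives each of 6 states
  roughly 15 visits (~11 windows), enough for a stable debiased coherence
  estimate; K = 8 on such short scans leaves some states nearly unvisited
  in some subjects.

The medication criterion counts a state as "detected" only when the
corrected p is below α **and** the off−on effect is positive (a
reduction): per-scan variance standardisation mechanically inflates
standardised beta power in unaffected states of the on condition, a small
apparent *increase* that a sign-blind criterion would miscount as a
medication effect.

## 5. Numerical choices

- **Filtering** is zero-phase (forward–backward) everywhere, so burst
  timing and state alignment are never phase-shifted; high-order
  Butterworth filters are applied as cascaded second-order sections
  (the expanded transfer function of an order-10 narrow-band IIR is
  ill-conditioned enough to break linearity at the 1e-2 level in double
  precision; the SOS cascade holds it at 1e-12).
- **Resampling** is Fourier-domain (spectrum truncation), inherently
  anti-aliased for downsampling; upsampling is refused.
- **DPSS tapers** come from the classical symmetric tridiagonal
  eigenproblem, unit-normalised, polarity fixed deterministically.
- **Window tiling**: windows tile the recording without overlap; a trailing
  partial window is never tested for artefacts and inherits "good"; bad
  samples are masked, not deleted, so indices stay aligned with state time
  courses, and spectral windows touching any bad or γ-uncovered sample are
  skipped.
- **Ties and degenerate cases**: argmax state binarisation breaks ties to
  the lowest index; all-equal connection strengths yield an empty
  thresholded network (strict inequality); a state with zero posterior
  mass has no spectrum (flagged `NULL`) and drops the affected subject
  from that contrast.
- **Seeds**: every stochastic routine takes an explicit seed; derived seeds
  (restarts, subjects, permutations) are fixed offsets from the master
  seed, all below 2^31.

## 6. Known limitations

- Maximum-likelihood EM can merge or split states on short recordings; the
  canonical-state route exists precisely because per-subject fits at
  realistic K are fragile.
- The coherence debiasing is a first-order correction; at very low
  occupancies (effective L close to 1) the clipped estimator is still
  noisy, and the pipeline's per-subject contrasts inherit that noise.
- The GESD-based exclusion operates on subject-level summary values in the
  medication contrast; the source analyses do not specify the exact
  exclusion variable, and a different choice could flag different
  subjects.
- The overlap statistic uses hard state assignments by default; with very
  uncertain posteriors the probability-weighted variant (flag) is the more
  faithful summary.
- `robustness_sweep` re-fits canonical models per K; state identities
  across different K are matched to ground truth in simulation but have no
  canonical correspondence on real data.
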