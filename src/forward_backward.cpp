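#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a Gaussian-emission HMM.
//
// logB       T x K log emission densities for the concatenated good samples
// pi0        length-K initial distribution (restarted at every segment)
// A          K x K row-stochastic transition matrix
// seg_start  1-based first index of each contiguous segment
// seg_end    1-based last index of each contiguous segment
//
// Returns gamma (T x K posteriors), xi (K x K expected transition counts
// summed over time and segments), per-segment restart posteriors summed
// (for the initial-distribution M-step) and the total log evidence.
//
// Emission densities are exponentiated after subtracting the per-sample
// maximum; the subtracted constant is folded back into the log evidence via
// the scaling factors, so the recursion never under/overflows for any K.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(const NumericMatrix& logB, const NumericVector& pi0,
            const NumericMatrix& A, const IntegerVector& seg_start,
            const IntegerVector& seg_end) {
  const int T = logB.nrow(), K = logB.ncol(), S = seg_start.size();
  NumericMatrix gamma(T, K), xi(K, K);
  NumericVector first(K);
  double loglik = 0.0;

  std::vector<double> alpha(static_cast<size_t>(T) * K);
  std::vector<double> b(static_cast<size_t>(T) * K);
  std::vector<double> cs(T), beta(K), beta_new(K);

  for (int s = 0; s < S; ++s) {
    const int t0 = seg_start[s] - 1, t1 = seg_end[s] - 1;

    // rescaled emission probabilities
    for (int t = t0; t <= t1; ++t) {
      double m = logB(t, 0);
      for (int k = 1; k < K; ++k) m = std::max(m, logB(t, k));
      if (!R_finite(m)) stop("non-finite emission log-density at sample %d", t + 1);
      for (int k = 0; k < K; ++k) b[(size_t)t * K + k] = std::exp(logB(t, k) - m);
      loglik += m;
    }

    // forward pass with per-sample normalisation
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[(size_t)t0 * K + k] = pi0[k] * b[(size_t)t0 * K + k];
      c += alpha[(size_t)t0 * K + k];
    }
    if (c <= 0.0) stop("all emission probabilities vanished at sample %d", t0 + 1);
    cs[t0] = c;
    for (int k = 0; k < K; ++k) alpha[(size_t)t0 * K + k] /= c;
    for (int t = t0 + 1; t <= t1; ++t) {
      c = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha[(size_t)(t - 1) * K + j] * A(j, k);
        a *= b[(size_t)t * K + k];
        alpha[(size_t)t * K + k] = a;
        c += a;
      }
      if (c <= 0.0) stop("all emission probabilities vanished at sample %d", t + 1);
      cs[t] = c;
      for (int k = 0; k < K; ++k) alpha[(size_t)t * K + k] /= c;
    }
    for (int t = t0; t <= t1; ++t) loglik += std::log(cs[t]);

    // backward pass, gamma and xi accumulation
    for (int k = 0; k < K; ++k) {
      beta[k] = 1.0;
      gamma(t1, k) = alpha[(size_t)t1 * K + k];
    }
    for (int t = t1 - 1; t >= t0; --t) {
      for (int j = 0; j < K; ++j) {
        double v = 0.0;
        for (int k = 0; k < K; ++k)
          v += A(j, k) * b[(size_t)(t + 1) * K + k] * beta[k];
        beta_new[j] = v / cs[t + 1];
      }
      double g = 0.0;
      for (int j = 0; j < K; ++j) {
        double val = alpha[(size_t)t * K + j] * beta_new[j];
        gamma(t, j) = val;
        g += val;
      }
      // xi_t(j,k) ∝ alpha_t(j) A(j,k) b_{t+1}(k) beta_{t+1}(k) / c_{t+1}
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xi(j, k) += alpha[(size_t)t * K + j] * A(j, k) *
                      b[(size_t)(t + 1) * K + k] * beta[k] / cs[t + 1];
      for (int j = 0; j < K; ++j) beta[j] = beta_new[j];
      if (g > 0.0) for (int j = 0; j < K; ++j) gamma(t, j) /= g;
    }
    for (int k = 0; k < K; ++k) first[k] += gamma(t0, k);
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["first"] = first, _["loglik"] = loglik);
}
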