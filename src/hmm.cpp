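// Five-state copy-number HMM core: emission log-likelihoods for LRR + BAF,
// Viterbi decoding and scaled forward-backward posteriors. States are
// ordered by copy number: CN0, CN1, CN2, CN3, CN4. Transitions are
// distance-dependent: a_ij(d) = pi_j * (1 - exp(-d/D)) for i != j, with the
// diagonal absorbing the remainder, so each row sums to 1 for every d >= 0.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 5;
// copies per state (CN2 is the diploid background)
static const int COPIES[NSTATE] = {0, 1, 2, 3, 4};

static inline double norm_pdf(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

static inline double norm_cdf(double x) {
  return 0.5 * std::erfc(-x / 1.4142135623730951);
}

// BAF mixture likelihood for one observation under one state.
// Bands sit at j/copies with binomial(copies, pfb) weights; each band is a
// normal clipped to [0,1], so observations exactly at 0 or 1 carry the
// clipped tail mass. CN0 has no allelic signal: uniform on [0,1]. A uniform
// outlier component with weight eps guards against stray values.
static double baf_lik(double b, int state, double pfb, double baf_sd,
                      double eps) {
  if (state == 0) return 1.0; // CN0: uniform, outlier mixing is a no-op
  int copies = COPIES[state];
  double mix = 0.0;
  // binomial weights
  double w = std::pow(1.0 - pfb, copies); // j = 0
  for (int j = 0; j <= copies; ++j) {
    double mu = (double)j / copies;
    double contrib;
    if (b <= 0.0) {
      contrib = norm_cdf((0.0 - mu) / baf_sd);
    } else if (b >= 1.0) {
      contrib = 1.0 - norm_cdf((1.0 - mu) / baf_sd);
    } else {
      contrib = norm_pdf(b, mu, baf_sd);
    }
    mix += w * contrib;
    // advance binomial weight to j+1
    if (j < copies)
      w *= ((double)(copies - j) / (double)(j + 1)) * (pfb / (1.0 - pfb));
  }
  return (1.0 - eps) * mix + eps;
}

// [[Rcpp::export]]
NumericMatrix cpp_emission_loglik(NumericVector lrr, NumericVector baf,
                                  NumericVector pfb, NumericVector lrr_mean,
                                  NumericVector lrr_sd, double baf_sd,
                                  double eps_out) {
  int n = lrr.size();
  NumericMatrix out(n, NSTATE);
  for (int t = 0; t < n; ++t) {
    bool has_l = !NumericVector::is_na(lrr[t]);
    bool has_b = !NumericVector::is_na(baf[t]);
    double p = pfb[t];
    if (p < 1e-4) p = 1e-4;
    if (p > 1.0 - 1e-4) p = 1.0 - 1e-4;
    for (int s = 0; s < NSTATE; ++s) {
      double ll = 0.0;
      if (has_l) ll += std::log(norm_pdf(lrr[t], lrr_mean[s], lrr_sd[s]) +
                                1e-300);
      if (has_b) ll += std::log(baf_lik(baf[t], s, p, baf_sd, eps_out) +
                                1e-300);
      out(t, s) = ll;
    }
  }
  return out;
}

// log transition matrix for one inter-marker distance
static void log_trans(double d, double D, const NumericVector& pi,
                      double lt[NSTATE][NSTATE]) {
  double f = 1.0 - std::exp(-d / D);
  for (int i = 0; i < NSTATE; ++i) {
    double diag = 1.0;
    for (int j = 0; j < NSTATE; ++j) {
      if (j != i) {
        double a = pi[j] * f;
        lt[i][j] = std::log(a + 1e-300);
        diag -= a;
      }
    }
    lt[i][i] = std::log(diag + 1e-300);
  }
}

// Viterbi decoding over one chromosome. Ties prefer the lower copy number
// (earlier state index), which the strict '>' comparisons below enforce.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericMatrix logem, NumericVector pos,
                          NumericVector pi, double D) {
  int n = logem.nrow();
  IntegerVector path(n);
  if (n == 0) return path;
  NumericMatrix delta(n, NSTATE);
  IntegerMatrix psi(n, NSTATE);
  for (int s = 0; s < NSTATE; ++s)
    delta(0, s) = std::log(pi[s] + 1e-300) + logem(0, s);
  double lt[NSTATE][NSTATE];
  for (int t = 1; t < n; ++t) {
    log_trans(pos[t] - pos[t - 1], D, pi, lt);
    for (int s = 0; s < NSTATE; ++s) {
      int best = 0;
      double bv = delta(t - 1, 0) + lt[0][s];
      for (int j = 1; j < NSTATE; ++j) {
        double v = delta(t - 1, j) + lt[j][s];
        if (v > bv) { bv = v; best = j; }
      }
      delta(t, s) = bv + logem(t, s);
      psi(t, s) = best;
    }
  }
  int best = 0;
  double bv = delta(n - 1, 0);
  for (int s = 1; s < NSTATE; ++s)
    if (delta(n - 1, s) > bv) { bv = delta(n - 1, s); best = s; }
  path[n - 1] = best;
  for (int t = n - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  return path;
}

// log-probability of a given state path (for oracle comparisons)
// [[Rcpp::export]]
double cpp_path_loglik(IntegerVector path, NumericMatrix logem,
                       NumericVector pos, NumericVector pi, double D) {
  int n = logem.nrow();
  double ll = std::log(pi[path[0]] + 1e-300) + logem(0, path[0]);
  double lt[NSTATE][NSTATE];
  for (int t = 1; t < n; ++t) {
    log_trans(pos[t] - pos[t - 1], D, pi, lt);
    ll += lt[path[t - 1]][path[t]] + logem(t, path[t]);
  }
  return ll;
}

// Scaled forward-backward; returns n x 5 posterior matrix.
// [[Rcpp::export]]
NumericMatrix cpp_forward_backward(NumericMatrix logem, NumericVector pos,
                                   NumericVector pi, double D) {
  int n = logem.nrow();
  NumericMatrix post(n, NSTATE);
  if (n == 0) return post;
  // per-row max subtraction keeps exp() in range
  NumericMatrix e(n, NSTATE);
  for (int t = 0; t < n; ++t) {
    double mx = logem(t, 0);
    for (int s = 1; s < NSTATE; ++s) if (logem(t, s) > mx) mx = logem(t, s);
    for (int s = 0; s < NSTATE; ++s) e(t, s) = std::exp(logem(t, s) - mx);
  }
  NumericMatrix alpha(n, NSTATE), beta(n, NSTATE);
  NumericVector cs(n);
  double c0 = 0.0;
  for (int s = 0; s < NSTATE; ++s) {
    alpha(0, s) = pi[s] * e(0, s);
    c0 += alpha(0, s);
  }
  for (int s = 0; s < NSTATE; ++s) alpha(0, s) /= c0;
  cs[0] = c0;
  double lt[NSTATE][NSTATE];
  double A[NSTATE][NSTATE];
  for (int t = 1; t < n; ++t) {
    log_trans(pos[t] - pos[t - 1], D, pi, lt);
    for (int i = 0; i < NSTATE; ++i)
      for (int j = 0; j < NSTATE; ++j) A[i][j] = std::exp(lt[i][j]);
    double ct = 0.0;
    for (int s = 0; s < NSTATE; ++s) {
      double acc = 0.0;
      for (int j = 0; j < NSTATE; ++j) acc += alpha(t - 1, j) * A[j][s];
      alpha(t, s) = acc * e(t, s);
      ct += alpha(t, s);
    }
    for (int s = 0; s < NSTATE; ++s) alpha(t, s) /= ct;
    cs[t] = ct;
  }
  for (int s = 0; s < NSTATE; ++s) beta(n - 1, s) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    log_trans(pos[t + 1] - pos[t], D, pi, lt);
    for (int i = 0; i < NSTATE; ++i)
      for (int j = 0; j < NSTATE; ++j) A[i][j] = std::exp(lt[i][j]);
    for (int s = 0; s < NSTATE; ++s) {
      double acc = 0.0;
      for (int j = 0; j < NSTATE; ++j)
        acc += A[s][j] * e(t + 1, j) * beta(t + 1, j);
      beta(t, s) = acc / cs[t + 1];
    }
  }
  for (int t = 0; t < n; ++t) {
    double z = 0.0;
    for (int s = 0; s < NSTATE; ++s) {
      post(t, s) = alpha(t, s) * beta(t, s);
      z += post(t, s);
    }
    for (int s = 0; s < NSTATE; ++s) post(t, s) /= z;
  }
  return post;
}
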