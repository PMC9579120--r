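// Fast negative log-likelihood kernels for the von Mises mixture models.
// These mirror the plain-R density definitions in R/models.R (the test suite
// asserts agreement); they exist because the multi-start fits in the
// recovery studies evaluate the likelihood millions of times.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG_2PI = std::log(2.0 * M_PI);

// log I0(kappa), via the exponentially scaled Bessel function so large
// concentrations do not overflow
static inline double log_bessel_i0(double kappa) {
  return std::log(R::bessel_i(kappa, 0.0, 2.0)) + kappa;
}

// mean resultant length A(kappa) = I1/I0 (scaled ratio is exact)
static inline double bessel_ratio(double kappa) {
  if (kappa == 0.0) return 0.0;
  return R::bessel_i(kappa, 1.0, 2.0) / R::bessel_i(kappa, 0.0, 2.0);
}

// numeric inverse of kappa -> circular sd = sqrt(-2 log A(kappa))
static double sd_to_kappa_c(double sd) {
  double R_target = std::exp(-0.5 * sd * sd);
  if (R_target >= 1.0) return R_PosInf;
  double lo = 0.0, hi = 1.0;
  while (bessel_ratio(hi) < R_target && hi < 1e8) hi *= 10.0;
  for (int i = 0; i < 200; ++i) {
    double mid = 0.5 * (lo + hi);
    if (bessel_ratio(mid) < R_target) lo = mid; else hi = mid;
    if (hi - lo < 1e-10 * (1.0 + hi)) break;
  }
  return 0.5 * (lo + hi);
}

// log-sum-exp of a small component array
static inline double lse(const double* x, int m) {
  double mx = R_NegInf;
  for (int j = 0; j < m; ++j) if (x[j] > mx) mx = x[j];
  if (!std::isfinite(mx)) return R_NegInf;
  double s = 0.0;
  for (int j = 0; j < m; ++j) s += std::exp(x[j] - mx);
  return mx + std::log(s);
}

// Two/three-component mixture NLL.
// cos_t: cos(response - target) per trial; cos_nt: n x k matrix of
// cos(response - non_target_j), NA where a trial has fewer non-targets.
// [[Rcpp::export]]
double nll_mixture_cpp(double kappa, double p_u, double p_n,
                       NumericVector cos_t, NumericMatrix cos_nt) {
  const int n = cos_t.size(), k = cos_nt.ncol();
  if (!(kappa > 0.0) || p_u < 0.0 || p_n < 0.0 || p_u + p_n > 1.0)
    return R_PosInf;
  const double p_t = 1.0 - p_u - p_n;
  const double li0 = log_bessel_i0(kappa);
  const double lt = (p_t > 0.0) ? std::log(p_t) - li0 - LOG_2PI : R_NegInf;
  const double lu = (p_u > 0.0) ? std::log(p_u) - LOG_2PI : R_NegInf;
  std::vector<double> comp(k + 2);
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    if (p_t > 0.0) comp[m++] = lt + kappa * cos_t[i];
    if (p_u > 0.0) comp[m++] = lu;
    if (p_n > 0.0) {
      int kn = 0;
      for (int j = 0; j < k; ++j) if (!NumericMatrix::is_na(cos_nt(i, j))) ++kn;
      if (kn == 0) return R_PosInf;  // p_n > 0 needs non-targets on every trial
      const double ln = std::log(p_n / kn) - li0 - LOG_2PI;
      for (int j = 0; j < k; ++j) {
        double c = cos_nt(i, j);
        if (!NumericMatrix::is_na(c)) comp[m++] = ln + kappa * c;
      }
    }
    double ld = lse(comp.data(), m);
    if (!std::isfinite(ld)) return R_PosInf;
    nll -= ld;
  }
  return nll;
}

// Slots / slots-plus-averaging NLL. Items carry floor(K/N) or floor(K/N)+1
// slots (fraction frac(K/N) carries the extra); 0 slots -> uniform guess,
// m slots -> von Mises with sd(kappa)/sqrt(m). spa = false restricts to the
// plain slots rule p_u = max(0, 1 - K/N) with unaveraged kappa.
// [[Rcpp::export]]
double nll_slots_cpp(double K, double kappa, bool spa,
                     NumericVector cos_t, NumericVector set_size) {
  const int n = cos_t.size();
  if (!(kappa > 0.0) || K < 0.0) return R_PosInf;
  const double sd1 = std::sqrt(-2.0 * std::log(bessel_ratio(kappa)));

  // cache per distinct set size (few per data set)
  std::vector<double> cache_N, cache_w0, cache_w1, cache_w2, cache_k1,
      cache_k2, cache_li1, cache_li2;
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double N = set_size[i];
    int ci = -1;
    for (size_t j = 0; j < cache_N.size(); ++j)
      if (cache_N[j] == N) { ci = (int)j; break; }
    if (ci < 0) {
      double w0 = 0.0, w1 = 0.0, w2 = 0.0, k1 = kappa, k2 = kappa;
      if (!spa) {
        double pu = (K >= N) ? 0.0 : 1.0 - K / N;
        w0 = pu; w1 = 1.0 - pu; k1 = kappa;
      } else {
        double q = K / N;
        double m_low = std::floor(q), f_high = q - m_low;
        // component with m_low slots
        if (m_low == 0.0) w0 += 1.0 - f_high;
        else { w1 = 1.0 - f_high; k1 = (m_low == 1.0) ? kappa : sd_to_kappa_c(sd1 / std::sqrt(m_low)); }
        // component with m_low + 1 slots
        if (f_high > 0.0) {
          w2 = f_high;
          double mh = m_low + 1.0;
          k2 = (mh == 1.0) ? kappa : sd_to_kappa_c(sd1 / std::sqrt(mh));
        }
      }
      cache_N.push_back(N);
      cache_w0.push_back(w0); cache_w1.push_back(w1); cache_w2.push_back(w2);
      cache_k1.push_back(k1); cache_k2.push_back(k2);
      cache_li1.push_back((w1 > 0.0) ? log_bessel_i0(k1) : 0.0);
      cache_li2.push_back((w2 > 0.0) ? log_bessel_i0(k2) : 0.0);
      ci = (int)cache_N.size() - 1;
    }
    double comp[3];
    int m = 0;
    if (cache_w0[ci] > 0.0) comp[m++] = std::log(cache_w0[ci]) - LOG_2PI;
    if (cache_w1[ci] > 0.0)
      comp[m++] = std::log(cache_w1[ci]) - cache_li1[ci] - LOG_2PI + cache_k1[ci] * cos_t[i];
    if (cache_w2[ci] > 0.0)
      comp[m++] = std::log(cache_w2[ci]) - cache_li2[ci] - LOG_2PI + cache_k2[ci] * cos_t[i];
    double ld = lse(comp, m);
    if (!std::isfinite(ld)) return R_PosInf;
    nll -= ld;
  }
  return nll;
}
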