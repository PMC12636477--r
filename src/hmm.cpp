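#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state HMM dynamic programming in log space. Fibers are ~20 kb so the
// per-bp recursions are the package hot loop; emissions are precomputed in R
// and passed as an L x 2 matrix of log emission probabilities (0 for
// uninformative positions in both states).

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix emis_log, NumericVector log_pi,
                              NumericMatrix log_T) {
  int L = emis_log.nrow();
  IntegerVector path(L);
  if (L == 0) return path;
  std::vector<double> v0(L), v1(L);
  std::vector<unsigned char> bp0(L), bp1(L);
  v0[0] = log_pi[0] + emis_log(0, 0);
  v1[0] = log_pi[1] + emis_log(0, 1);
  for (int t = 1; t < L; ++t) {
    double a00 = v0[t - 1] + log_T(0, 0), a10 = v1[t - 1] + log_T(1, 0);
    double a01 = v0[t - 1] + log_T(0, 1), a11 = v1[t - 1] + log_T(1, 1);
    // ties break toward the lower-indexed previous state (deterministic)
    if (a00 >= a10) { v0[t] = a00; bp0[t] = 0; } else { v0[t] = a10; bp0[t] = 1; }
    if (a01 >= a11) { v1[t] = a01; bp1[t] = 0; } else { v1[t] = a11; bp1[t] = 1; }
    v0[t] += emis_log(t, 0);
    v1[t] += emis_log(t, 1);
  }
  int s = (v0[L - 1] >= v1[L - 1]) ? 0 : 1;
  path[L - 1] = s;
  for (int t = L - 1; t > 0; --t) {
    s = (s == 0) ? bp0[t] : bp1[t];
    path[t - 1] = s;
  }
  return path;
}

// Forward-backward. Returns per-position posteriors (gamma), the summed
// expected transition counts (xi, probability scale), the position-1
// posterior, and the log-likelihood -- the sufficient statistics for
// Baum-Welch updates of start/transition probabilities.
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericMatrix emis_log, NumericVector log_pi,
                              NumericMatrix log_T) {
  int L = emis_log.nrow();
  NumericMatrix gamma(L, 2);
  NumericMatrix xi(2, 2);
  if (L == 0)
    return List::create(_["loglik"] = R_NegInf, _["gamma"] = gamma,
                        _["xi"] = xi);
  std::vector<double> a0(L), a1(L), b0(L), b1(L);
  a0[0] = log_pi[0] + emis_log(0, 0);
  a1[0] = log_pi[1] + emis_log(0, 1);
  for (int t = 1; t < L; ++t) {
    a0[t] = logsumexp2(a0[t - 1] + log_T(0, 0), a1[t - 1] + log_T(1, 0)) +
            emis_log(t, 0);
    a1[t] = logsumexp2(a0[t - 1] + log_T(0, 1), a1[t - 1] + log_T(1, 1)) +
            emis_log(t, 1);
  }
  double loglik = logsumexp2(a0[L - 1], a1[L - 1]);
  b0[L - 1] = 0.0;
  b1[L - 1] = 0.0;
  for (int t = L - 2; t >= 0; --t) {
    b0[t] = logsumexp2(log_T(0, 0) + emis_log(t + 1, 0) + b0[t + 1],
                       log_T(0, 1) + emis_log(t + 1, 1) + b1[t + 1]);
    b1[t] = logsumexp2(log_T(1, 0) + emis_log(t + 1, 0) + b0[t + 1],
                       log_T(1, 1) + emis_log(t + 1, 1) + b1[t + 1]);
  }
  for (int t = 0; t < L; ++t) {
    double g0 = a0[t] + b0[t] - loglik;
    double g1 = a1[t] + b1[t] - loglik;
    gamma(t, 0) = std::exp(g0);
    gamma(t, 1) = std::exp(g1);
  }
  for (int t = 0; t < L - 1; ++t) {
    xi(0, 0) += std::exp(a0[t] + log_T(0, 0) + emis_log(t + 1, 0) + b0[t + 1] - loglik);
    xi(0, 1) += std::exp(a0[t] + log_T(0, 1) + emis_log(t + 1, 1) + b1[t + 1] - loglik);
    xi(1, 0) += std::exp(a1[t] + log_T(1, 0) + emis_log(t + 1, 0) + b0[t + 1] - loglik);
    xi(1, 1) += std::exp(a1[t] + log_T(1, 1) + emis_log(t + 1, 1) + b1[t + 1] - loglik);
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}
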