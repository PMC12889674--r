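#include <Rcpp.h>
using namespace Rcpp;

// log-space forward/backward and Viterbi recursions for a hidden Markov
// chain over one sequence. logB is T x K: log emission probability of the
// observed bin vector under each state (precomputed in R as a matrix
// product, since marks are conditionally independent Bernoullis).

static inline double logsumexp(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!R_FINITE(m)) return R_NegInf;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// [[Rcpp::export(name = ".fb_pass")]]
List fb_pass(NumericVector logpi, NumericMatrix logA, NumericMatrix logB) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix la(T, K), lb(T, K), gamma(T, K);
  NumericMatrix xi(K, K);
  std::vector<double> buf(K);

  for (int k = 0; k < K; ++k) la(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) buf[j] = la(t - 1, j) + logA(j, k);
      la(t, k) = logsumexp(buf) + logB(t, k);
    }
  for (int k = 0; k < K; ++k) buf[k] = la(T - 1, k);
  const double loglik = logsumexp(buf);

  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        buf[j] = logA(k, j) + logB(t + 1, j) + lb(t + 1, j);
      lb(t, k) = logsumexp(buf);
    }

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      gamma(t, k) = std::exp(la(t, k) + lb(t, k) - loglik);

  // expected transition counts summed over t
  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += std::exp(la(t, j) + logA(j, k) + logB(t + 1, k) +
                             lb(t + 1, k) - loglik);

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}

// [[Rcpp::export(name = ".viterbi_path")]]
List viterbi_path(NumericVector logpi, NumericMatrix logA,
                  NumericMatrix logB) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta(t - 1, 0) + logA(0, k);
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }  // ties keep lower index
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }

  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }

  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based for R

  return List::create(_["path"] = path, _["logprob"] = best);
}
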