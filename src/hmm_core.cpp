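#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward for one chromosome.
//
// Transition kernel between markers separated by d Morgans:
//   A[c,c'] = exp(-R_c d) * 1{c==c'} + (1 - exp(-R_c d)) * m_{c'}
// i.e. the current segment survives with probability exp(-R_c d), otherwise a
// new segment is drawn from the mixing distribution m. The O(S) structure of
// the kernel is exploited; no S x S matrix is formed.
//
// B: n x S emission likelihoods (already floored away from 0 where needed)
// Returns per-marker posteriors (gamma), log-likelihood, expected segment-start
// counts: the chromosome-start occupancy and the expected number of reset
// events into each state (the sufficient statistics for the EM update of m).
// E: (n-1) x S matrix of survival probabilities exp(-R_s * d_t), precomputed
// once per fit since rates and distances never change across EM iterations.
// [[Rcpp::export]]
List fb_chrom_cpp(NumericMatrix B, NumericMatrix E, NumericVector mixing) {
  const int n = B.nrow(), S = B.ncol();
  const double floor_p = 1e-300;
  NumericMatrix gamma(n, S), ahat(n, S);
  NumericVector cs(n);
  double ll = 0.0;

  double c0 = 0.0;
  for (int s = 0; s < S; ++s) { ahat(0, s) = mixing[s] * B(0, s); c0 += ahat(0, s); }
  if (c0 < floor_p) c0 = floor_p;
  for (int s = 0; s < S; ++s) ahat(0, s) /= c0;
  cs[0] = c0; ll += std::log(c0);

  for (int t = 1; t < n; ++t) {
    double w = 0.0;  // probability mass that resets between t-1 and t
    for (int s = 0; s < S; ++s) w += (1.0 - E(t - 1, s)) * ahat(t - 1, s);
    double ct = 0.0;
    for (int s = 0; s < S; ++s) {
      double pred = E(t - 1, s) * ahat(t - 1, s) + mixing[s] * w;
      double v = pred * B(t, s);
      ahat(t, s) = v; ct += v;
    }
    if (ct < floor_p) ct = floor_p;
    for (int s = 0; s < S; ++s) ahat(t, s) /= ct;
    cs[t] = ct; ll += std::log(ct);
  }

  std::vector<double> bh(S, 1.0), bh_new(S);
  NumericVector start_counts(S), reset_counts(S);
  for (int s = 0; s < S; ++s) gamma(n - 1, s) = ahat(n - 1, s);

  for (int t = n - 2; t >= 0; --t) {
    double mix = 0.0;  // sum_c' m_c' B(t+1,c') bh_{t+1}(c')
    for (int s = 0; s < S; ++s) mix += mixing[s] * B(t + 1, s) * bh[s];
    double w = 0.0;    // sum_c ahat_t(c) (1 - exp(-R_c d))
    for (int s = 0; s < S; ++s) w += ahat(t, s) * (1.0 - E(t, s));
    for (int s = 0; s < S; ++s)
      reset_counts[s] += w * mixing[s] * B(t + 1, s) * bh[s] / cs[t + 1];
    for (int s = 0; s < S; ++s) {
      const double e = E(t, s);
      bh_new[s] = (e * B(t + 1, s) * bh[s] + (1.0 - e) * mix) / cs[t + 1];
    }
    for (int s = 0; s < S; ++s) {
      bh[s] = bh_new[s];
      gamma(t, s) = ahat(t, s) * bh[s];
    }
  }
  for (int s = 0; s < S; ++s) start_counts[s] = gamma(0, s);

  return List::create(_["gamma"] = gamma, _["loglik"] = ll,
                      _["start_counts"] = start_counts,
                      _["reset_counts"] = reset_counts);
}

// Log-space Viterbi for one chromosome; ties broken toward the lowest state
// index (most recent HBD class). States returned 1-based.
// [[Rcpp::export]]
List viterbi_chrom_cpp(NumericMatrix B, NumericVector d, NumericVector rates,
                       NumericVector mixing) {
  const int n = B.nrow(), S = B.ncol();
  const double floor_p = 1e-300;
  NumericMatrix delta(n, S);
  IntegerMatrix psi(n, S);

  for (int s = 0; s < S; ++s)
    delta(0, s) = std::log(std::max(mixing[s] * B(0, s), floor_p));

  std::vector<double> e(S);
  for (int t = 1; t < n; ++t) {
    const double dd = d[t - 1];
    for (int s = 0; s < S; ++s) e[s] = std::exp(-rates[s] * dd);
    for (int s2 = 0; s2 < S; ++s2) {
      double best = -INFINITY; int arg = 0;
      for (int s1 = 0; s1 < S; ++s1) {
        double a = (s1 == s2 ? e[s1] : 0.0) + (1.0 - e[s1]) * mixing[s2];
        double v = delta(t - 1, s1) + std::log(std::max(a, floor_p));
        if (v > best) { best = v; arg = s1; }  // strict >: first (lowest) wins ties
      }
      delta(t, s2) = best + std::log(std::max(B(t, s2), floor_p));
      psi(t, s2) = arg;
    }
  }

  IntegerVector path(n);
  double best = -INFINITY; int arg = 0;
  for (int s = 0; s < S; ++s)
    if (delta(n - 1, s) > best) { best = delta(n - 1, s); arg = s; }
  path[n - 1] = arg + 1;
  for (int t = n - 1; t > 0; --t) { arg = psi(t, arg); path[t - 1] = arg + 1; }

  return List::create(_["path"] = path, _["logp"] = best);
}
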