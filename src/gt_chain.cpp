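#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Markov chain over genotype count tables with fixed allele counts, for the
// exact Hardy-Weinberg test. State: symmetric k x k genotype table n_ij.
// Proposal: draw an ordered allele quadruple (i1, j1, i2, j2) uniformly on
// {1..k}^4 and apply the degree-2 switch
//   n{i1,j1}--, n{i2,j2}--, n{i1,j2}++, n{i2,j1}++,
// which preserves every allele count. Each forward quadruple has a unique
// reverse quadruple of equal probability, so the proposal is symmetric and
// Metropolis acceptance min(1, P'/P) targets the conditional distribution
//   P(T) = N! / prod n_ij! * 2^het * prod m_i! / (2N)! .
// Only the log-probability *difference* is tracked; it is re-derived from
// the table every resync_every steps to stop float drift from swamping the
// tie tolerance.

static inline int cell(int i, int j, int k) {
  // index of unordered cell {i, j} in a k x k row-major lower triangle
  if (i < j) std::swap(i, j);
  return i * (i + 1) / 2 + j;
}

static double table_log_prob_core(const std::vector<int>& n, int k,
                                  const std::vector<double>& lfact) {
  int N = 0, het = 0;
  std::vector<int> m(k, 0);
  double sum_lf = 0.0;
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j <= i; ++j) {
      int c = n[cell(i, j, k)];
      N += c;
      sum_lf += lfact[c];
      m[i] += c;
      m[j] += c;
      if (i != j) het += c;
    }
  }
  double lp = lfact[N] - sum_lf + het * std::log(2.0);
  for (int i = 0; i < k; ++i) lp += lfact[m[i]];
  lp -= lfact[2 * N];
  return lp;
}

// [[Rcpp::export(name = ".gt_chain_cpp")]]
List gt_chain_cpp(IntegerMatrix counts, int steps, int dememorization,
                  bool trace = false, int resync_every = 10000) {
  int k = counts.nrow();
  std::vector<int> n(k * (k + 1) / 2, 0);
  int N = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j <= i; ++j) {
      n[cell(i, j, k)] = counts(i, j);
      N += counts(i, j);
    }
  int maxf = 2 * N + 2;
  std::vector<double> lfact(maxf + 1, 0.0);
  for (int i = 2; i <= maxf; ++i) lfact[i] = lfact[i - 1] + std::log((double)i);

  const double lp_obs = table_log_prob_core(n, k, lfact);
  const double tie_tol = 1e-9;  // absolute, on the log scale
  double lp = lp_obs;
  const double log2 = std::log(2.0);

  RNGScope scope;
  long long below = 0;
  std::vector<double> batch_means;
  int n_batches = 100;
  int batch_size = steps / n_batches;
  if (batch_size < 1) { batch_size = steps; n_batches = 1; }
  long long batch_below = 0;
  IntegerVector het_trace(trace ? steps : 0);

  int total = dememorization + steps;
  for (int t = 0; t < total; ++t) {
    int i1 = (int)(unif_rand() * k), j1 = (int)(unif_rand() * k);
    int i2 = (int)(unif_rand() * k), j2 = (int)(unif_rand() * k);
    int c1 = cell(i1, j1, k), c2 = cell(i2, j2, k);
    int c3 = cell(i1, j2, k), c4 = cell(i2, j1, k);
    bool valid = (c1 == c2) ? (n[c1] >= 2) : (n[c1] >= 1 && n[c2] >= 1);
    bool identity = (c1 == c3 && c2 == c4) || (c1 == c4 && c2 == c3);
    if (valid && !identity) {
      // delta log P from the four cell updates (sequential, multiset-safe)
      double dlp = 0.0;
      n[c1]--; dlp += lfact[n[c1] + 1] - lfact[n[c1]];
      n[c2]--; dlp += lfact[n[c2] + 1] - lfact[n[c2]];
      n[c3]++; dlp += lfact[n[c3] - 1] - lfact[n[c3]];
      n[c4]++; dlp += lfact[n[c4] - 1] - lfact[n[c4]];
      int dhet = (i1 != j2) + (i2 != j1) - (i1 != j1) - (i2 != j2);
      dlp += dhet * log2;
      if (dlp >= 0.0 || unif_rand() < std::exp(dlp)) {
        lp += dlp;  // accept
      } else {      // reject: undo
        n[c4]--; n[c3]--; n[c2]++; n[c1]++;
      }
    }
    if (((t + 1) % resync_every) == 0) lp = table_log_prob_core(n, k, lfact);
    if (t >= dememorization) {
      int s = t - dememorization;
      bool le = (lp <= lp_obs + tie_tol);
      if (le) { ++below; ++batch_below; }
      if (trace) {
        int het = 0;
        for (int i = 0; i < k; ++i)
          for (int j = 0; j < i; ++j) het += n[cell(i, j, k)];
        het_trace[s] = het;
      }
      if ((s + 1) % batch_size == 0 && (int)batch_means.size() < n_batches) {
        batch_means.push_back((double)batch_below / batch_size);
        batch_below = 0;
      }
    }
  }
  double p = (double)below / steps;
  // Monte-Carlo s.e. from batch means (accounts for chain autocorrelation)
  double se = NA_REAL;
  int B = batch_means.size();
  if (B > 1) {
    double mb = 0.0;
    for (double b : batch_means) mb += b;
    mb /= B;
    double v = 0.0;
    for (double b : batch_means) v += (b - mb) * (b - mb);
    v /= (B - 1);
    se = std::sqrt(v / B);
  }
  return List::create(_["p"] = p, _["se"] = se,
                      _["log_p_obs"] = lp_obs,
                      _["het_trace"] = het_trace);
}
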