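// Conditional permutation null for the local Moran statistic of
// conservation (LMIC).  For each residue i the observed value and its own
// position are held fixed while the remaining attribute values are permuted
// over the remaining residues; only the n_i values landing in N(i) matter,
// so each replicate draws a simple random sample (partial Fisher-Yates)
// from the other N-1 values.  Uses R's RNG so
// set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export(name = ".lmic_perm_cpp")]]
List lmic_perm_cpp(NumericVector values, List nbrs, double mu, double sigma2,
                   int n_perm, int k_rank) {
  const int n = values.size();
  if (n_perm < 1) stop("n_perm must be positive");
  if (k_rank < 1 || k_rank > n_perm) stop("invalid threshold rank");
  if (!(sigma2 > 0)) stop("constant conservation, LMIC undefined");

  NumericVector obs(n), thresh(n);
  IntegerVector n_greater(n), n_done(n);
  std::vector<double> centered(n);
  for (int i = 0; i < n; ++i) centered[i] = values[i] - mu;

  RNGScope scope;
  std::vector<double> perm_stat(n_perm);
  std::vector<int> idx;
  std::vector<double> others;

  for (int i = 0; i < n; ++i) {
    IntegerVector nb = nbrs[i];
    const int ni = nb.size();
    double s = 0.0;
    for (int j = 0; j < ni; ++j) s += centered[nb[j] - 1];
    obs[i] = centered[i] * s / sigma2;
    if (ni == 0) {
      thresh[i] = NA_REAL;
      n_greater[i] = NA_INTEGER;
      n_done[i] = 0;
      continue;
    }

    others.clear();
    for (int j = 0; j < n; ++j)
      if (j != i) others.push_back(centered[j]);
    const int m = (int)others.size();
    if (ni > m) stop("neighborhood larger than candidate pool");

    idx.resize(m);
    for (int j = 0; j < m; ++j) idx[j] = j;

    int greater = 0;
    for (int r = 0; r < n_perm; ++r) {
      double ps = 0.0;
      for (int j = 0; j < ni; ++j) {
        int pick = j + (int)(unif_rand() * (m - j));
        if (pick >= m) pick = m - 1;
        std::swap(idx[j], idx[pick]);
        ps += others[idx[j]];
      }
      // no undo needed: a partial Fisher-Yates over any starting
      // permutation still yields a uniform sample without replacement
      perm_stat[r] = centered[i] * ps / sigma2;
      if (perm_stat[r] > obs[i]) ++greater;
    }
    n_done[i] = n_perm;
    n_greater[i] = greater;
    std::nth_element(perm_stat.begin(), perm_stat.begin() + (k_rank - 1),
                     perm_stat.begin() + n_perm,
                     std::greater<double>());
    thresh[i] = perm_stat[k_rank - 1];
  }

  return List::create(_["lmic"] = obs, _["threshold"] = thresh,
                      _["n_greater"] = n_greater, _["n_perm"] = n_done);
}
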