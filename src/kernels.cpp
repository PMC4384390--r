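#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Nearest-medoid assignment. `medoids` holds 0-based motif indices.
// Returns, per motif, the motif index of its owning medoid; ties go to the
// lowest medoid index (medoids are scanned in ascending order with strict
// improvement).
// [[Rcpp::export(name = ".assign_cpp")]]
IntegerVector assign_cpp(const NumericMatrix& D, IntegerVector medoids) {
  const int n = D.nrow();
  std::vector<int> med(medoids.begin(), medoids.end());
  std::sort(med.begin(), med.end());
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    int best = med[0];
    double bd = D(i, med[0]);
    for (size_t j = 1; j < med.size(); ++j) {
      double d = D(i, med[j]);
      if (d < bd) { bd = d; best = med[j]; }
    }
    labels[i] = best;
  }
  return labels;
}

static double config_cost(const NumericMatrix& D, const std::vector<int>& med) {
  const int n = D.nrow();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double bd = D(i, med[0]);
    for (size_t j = 1; j < med.size(); ++j) {
      double d = D(i, med[j]);
      if (d < bd) bd = d;
    }
    total += bd;
  }
  return total;
}

// [[Rcpp::export(name = ".cost_cpp")]]
double cost_cpp(const NumericMatrix& D, IntegerVector medoids) {
  std::vector<int> med(medoids.begin(), medoids.end());
  return config_cost(D, med);
}

// One greedy swap pass of k-medoids: slots are visited in ascending order of
// their medoid index at the start of the pass; for each slot every current
// non-medoid (ascending motif index) is tried as a replacement and the swap
// is committed immediately whenever it strictly lowers the configuration
// cost (running baseline). No second pass.
// [[Rcpp::export(name = ".one_round_cpp")]]
IntegerVector one_round_cpp(const NumericMatrix& D, IntegerVector medoids) {
  const int n = D.nrow();
  std::vector<int> med(medoids.begin(), medoids.end());
  const int K = (int) med.size();
  std::vector<int> slots(K);
  for (int s = 0; s < K; ++s) slots[s] = s;
  std::sort(slots.begin(), slots.end(),
            [&](int a, int b) { return med[a] < med[b]; });
  std::vector<bool> is_med(n, false);
  for (int s = 0; s < K; ++s) is_med[med[s]] = true;
  double cur = config_cost(D, med);
  for (int si = 0; si < K; ++si) {
    const int slot = slots[si];
    for (int j = 0; j < n; ++j) {
      if (is_med[j]) continue;
      const int old = med[slot];
      med[slot] = j;
      double trial = config_cost(D, med);
      if (trial < cur) {
        cur = trial;
        is_med[old] = false;
        is_med[j] = true;
      } else {
        med[slot] = old;
      }
    }
  }
  return IntegerVector(med.begin(), med.end());
}

// Per-point silhouette. `labels` are 0-based cluster codes 0..K-1.
// a(i) = mean distance to the other members of i's cluster; b(i) = the
// smallest mean distance from i to another cluster; s = (b-a)/max(a,b),
// with s := 0 for singleton-cluster members and for a == b == 0.
// [[Rcpp::export(name = ".silhouette_cpp")]]
NumericVector silhouette_cpp(const NumericMatrix& D, IntegerVector labels,
                             int K) {
  const int n = D.nrow();
  std::vector<int> size(K, 0);
  for (int i = 0; i < n; ++i) size[labels[i]]++;
  NumericVector s(n);
  std::vector<double> sums(K);
  for (int i = 0; i < n; ++i) {
    std::fill(sums.begin(), sums.end(), 0.0);
    for (int j = 0; j < n; ++j) sums[labels[j]] += D(i, j);
    const int ci = labels[i];
    if (size[ci] <= 1) { s[i] = 0.0; continue; }
    double a = sums[ci] / (size[ci] - 1);   // D(i,i) = 0 drops out
    double b = R_PosInf;
    for (int c = 0; c < K; ++c) {
      if (c == ci || size[c] == 0) continue;
      double m = sums[c] / size[c];
      if (m < b) b = m;
    }
    double denom = std::max(a, b);
    s[i] = (denom > 0.0) ? (b - a) / denom : 0.0;
  }
  return s;
}
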