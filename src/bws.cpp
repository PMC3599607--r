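#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Mid-ranks of the pooled sample (x, y), split back into the two groups and
// sorted ascending so that position i is the i-th order statistic's rank.
static void pooled_midranks(const NumericVector& x, const NumericVector& y,
                            std::vector<double>& rx, std::vector<double>& ry) {
  const int n1 = x.size(), n2 = y.size(), N = n1 + n2;
  std::vector<double> v(N);
  std::vector<int> idx(N);
  for (int i = 0; i < n1; ++i) v[i] = x[i];
  for (int j = 0; j < n2; ++j) v[n1 + j] = y[j];
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  std::vector<double> r(N);
  int i = 0;
  while (i < N) {
    int j = i;
    while (j + 1 < N && v[idx[j + 1]] == v[idx[i]]) ++j;
    const double avg = 0.5 * (i + j) + 1.0;  // mid-rank of the tied block
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    i = j + 1;
  }
  rx.assign(r.begin(), r.begin() + n1);
  ry.assign(r.begin() + n1, r.end());
  std::sort(rx.begin(), rx.end());
  std::sort(ry.begin(), ry.end());
}

// One group's weighted signed-square rank discrepancy:
// (1/na) * sum_i [ (R_i - (N/na) i) |R_i - (N/na) i| ] /
//                [ (i/(na+1))(1 - i/(na+1)) * nb*N/na ]
// where R is the ascending rank vector of the group of size na and nb is the
// other group's size.
static double b_component(const std::vector<double>& R, int na, int nb) {
  const double N = na + nb;
  double acc = 0.0;
  for (int i = 1; i <= na; ++i) {
    const double d = R[i - 1] - (N / na) * i;
    const double t = static_cast<double>(i) / (na + 1);
    acc += d * std::fabs(d) / (t * (1.0 - t) * (nb * N / na));
  }
  return acc / na;
}

// [[Rcpp::export]]
List bws_stat_cpp(NumericVector control, NumericVector case_) {
  const int n1 = control.size(), n2 = case_.size();
  std::vector<double> G, H;
  pooled_midranks(control, case_, G, H);
  const double B1 = b_component(G, n1, n2);
  const double B2 = b_component(H, n2, n1);
  const double B = 0.5 * (B1 - B2);
  return List::create(_["B1"] = B1, _["B2"] = B2, _["B"] = B, _["D"] = -B);
}

// Null permutation distribution of B for group sizes (n1, n2): the statistic
// is rank-based, so permuting any continuous pooled sample is equivalent to
// assigning a uniformly random n1-subset of the ranks 1..N to group 1.
// Uses R's RNG (seeded from R with set.seed()).
// [[Rcpp::export]]
NumericVector bws_perm_null_cpp(int n1, int n2, int n_perm) {
  const int N = n1 + n2;
  NumericVector out(n_perm);
  std::vector<double> pool(N), g(n1), h(n2);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < N; ++i) pool[i] = i + 1;
    // partial Fisher-Yates: the first n1 slots become group 1's ranks
    for (int i = 0; i < n1; ++i) {
      int j = i + static_cast<int>(unif_rand() * (N - i));
      if (j >= N) j = N - 1;
      std::swap(pool[i], pool[j]);
    }
    std::copy(pool.begin(), pool.begin() + n1, g.begin());
    std::copy(pool.begin() + n1, pool.end(), h.begin());
    std::sort(g.begin(), g.end());
    std::sort(h.begin(), h.end());
    out[p] = 0.5 * (b_component(g, n1, n2) - b_component(h, n2, n1));
  }
  return out;
}
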