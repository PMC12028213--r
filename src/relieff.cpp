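#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>
using namespace Rcpp;

// Multi-class ReliefF with k nearest hits/misses, Manhattan distance,
// misses weighted by class prior P(C)/(1 - P(class(x))), all samples used.
// X must be pre-scaled so per-feature differences are comparable (the R
// wrapper scales to [0, 1] by range).  Returns the observed weight vector
// and, when nperm > 0, the null weights under label permutation (labels are
// permuted, distances and neighbour order are label-free and fixed).

static void relieff_weights(const NumericMatrix& X,
                            const std::vector<int>& y, int ncls, int k,
                            const std::vector<std::vector<int> >& order,
                            double* w) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> prior(ncls, 0.0);
  for (int i = 0; i < n; ++i) prior[y[i]] += 1.0 / n;
  std::fill(w, w + p, 0.0);
  std::vector<int> taken(ncls);
  for (int i = 0; i < n; ++i) {
    const int yi = y[i];
    std::fill(taken.begin(), taken.end(), 0);
    const double missnorm = 1.0 - prior[yi];
    for (size_t t = 0; t < order[i].size(); ++t) {
      const int j = order[i][t];
      const int yj = y[j];
      if (taken[yj] >= k) continue;
      taken[yj]++;
      double scale;
      if (yj == yi) scale = -1.0 / (n * k);
      else scale = (missnorm > 0 ? prior[yj] / missnorm : 0.0) / (n * k);
      for (int f = 0; f < p; ++f)
        w[f] += scale * std::fabs(X(i, f) - X(j, f));
      bool done = true;
      for (int c = 0; c < ncls; ++c) if (taken[c] < k) { done = false; break; }
      if (done) break;
    }
  }
}

// [[Rcpp::export]]
List cpp_relieff(NumericMatrix X, IntegerVector y, int ncls, int k,
                 int nperm, int seed) {
  const int n = X.nrow(), p = X.ncol();
  // pairwise Manhattan distances and per-sample neighbour order
  std::vector<std::vector<double> > D(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int f = 0; f < p; ++f) d += std::fabs(X(i, f) - X(j, f));
      D[i][j] = D[j][i] = d;
    }
  std::vector<std::vector<int> > order(n);
  for (int i = 0; i < n; ++i) {
    order[i].reserve(n - 1);
    for (int j = 0; j < n; ++j) if (j != i) order[i].push_back(j);
    const std::vector<double>& Di = D[i];
    std::stable_sort(order[i].begin(), order[i].end(),
                     [&Di](int a, int b) { return Di[a] < Di[b]; });
  }
  std::vector<int> yy(y.begin(), y.end());
  NumericVector w(p);
  relieff_weights(X, yy, ncls, k, order, REAL(w));
  NumericMatrix nullw(nperm, p);
  if (nperm > 0) {
    std::mt19937 rng(seed);
    std::vector<double> wp(p);
    std::vector<int> yp(yy);
    for (int b = 0; b < nperm; ++b) {
      std::shuffle(yp.begin(), yp.end(), rng);
      relieff_weights(X, yp, ncls, k, order, wp.data());
      for (int f = 0; f < p; ++f) nullw(b, f) = wp[f];
    }
  }
  return List::create(_["weights"] = w, _["null"] = nullw);
}
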