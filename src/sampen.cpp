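#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

// Fenwick (binary indexed) tree over compressed ranks
struct Fenwick {
  std::vector<int> t;
  explicit Fenwick(int n) : t(n + 1, 0) {}
  void add(int i, int v) {
    for (++i; i < (int)t.size(); i += i & -i) t[i] += v;
  }
  int prefix(int i) const {  // count of ranks <= i
    int s = 0;
    for (++i; i > 0; i -= i & -i) s += t[i];
    return s;
  }
};

}  // namespace

// Template-match pair counts for sample entropy.
//
// B counts unordered pairs of distinct length-m templates (all n - m + 1 of
// them) whose Chebyshev distance is <= r; A counts the same over the
// n - m length-(m+1) templates.
//
// m == 1 uses an O(n log n) sweep: points (x_i, x_{i+1}) are sorted by the
// first component; a sliding window keeps the points within r in the first
// component while a Fenwick tree over second-component ranks counts, for
// each point, how many window members lie within r in the second component.
// m > 1 falls back to a sorted pairwise scan with early exit.
//
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (m < 1 || n < m + 2 || r <= 0) {
    return NumericVector::create(NA_REAL, NA_REAL);
  }
  int nB = n - m + 1;  // length-m templates
  int nA = n - m;      // length-(m+1) templates

  if (m == 1) {
    std::vector<std::pair<double, double>> v(n);
    for (int i = 0; i < n; ++i) {
      v[i].first = x[i];
      v[i].second = (i < nA) ? x[i + 1] : NA_REAL;  // NA: no length-2 template
    }
    std::sort(v.begin(), v.end(),
              [](const std::pair<double, double> &a,
                 const std::pair<double, double> &b) {
                return a.first < b.first;
              });
    // rank-compress the valid second components
    std::vector<double> ys;
    ys.reserve(nA);
    for (int i = 0; i < n; ++i) {
      if (!ISNA(v[i].second)) ys.push_back(v[i].second);
    }
    std::sort(ys.begin(), ys.end());
    ys.erase(std::unique(ys.begin(), ys.end()), ys.end());
    Fenwick fen((int)ys.size());
    auto rank_of = [&](double y) {
      return (int)(std::lower_bound(ys.begin(), ys.end(), y) - ys.begin());
    };
    auto count_le = [&](double y) {  // window members with second comp <= y
      int k = (int)(std::upper_bound(ys.begin(), ys.end(), y) - ys.begin());
      return k == 0 ? 0 : fen.prefix(k - 1);
    };
    auto count_lt = [&](double y) {  // window members with second comp < y
      int k = (int)(std::lower_bound(ys.begin(), ys.end(), y) - ys.begin());
      return k == 0 ? 0 : fen.prefix(k - 1);
    };

    double B = 0.0, A = 0.0;
    int hi = 0;  // window is (a, hi]: points with x - x_a <= r
    int in_tree = 0;
    for (int a = 0; a < n; ++a) {
      // every index in [1, hi] has been added exactly once; remove a itself
      if (a > 0 && a <= hi && !ISNA(v[a].second)) {
        fen.add(rank_of(v[a].second), -1);
        --in_tree;
      }
      if (hi < a) hi = a;  // window never lags behind a
      while (hi + 1 < n && v[hi + 1].first - v[a].first <= r) {
        ++hi;
        if (!ISNA(v[hi].second)) {
          fen.add(rank_of(v[hi].second), +1);
          ++in_tree;
        }
      }
      B += hi - a;  // all window members match in the first component
      if (!ISNA(v[a].second) && in_tree > 0) {
        A += count_le(v[a].second + r) - count_lt(v[a].second - r);
      }
    }
    return NumericVector::create(B, A);
  }

  std::vector<int> idx(nB);
  for (int i = 0; i < nB; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double B = 0.0, A = 0.0;
  for (int a = 0; a < nB; ++a) {
    int i = idx[a];
    for (int b = a + 1; b < nB; ++b) {
      int j = idx[b];
      if (x[j] - x[i] > r) break;  // sorted: later first components only grow
      bool matchB = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { matchB = false; break; }
      }
      if (!matchB) continue;
      B += 1.0;
      if (i < nA && j < nA && std::fabs(x[i + m] - x[j + m]) <= r) {
        A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}
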