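#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// type-7 quantiles per column (the R default)
// [[Rcpp::export]]
NumericMatrix cpp_col_quantiles(NumericMatrix X, NumericVector probs) {
  int n = X.nrow(), p = X.ncol(), q = probs.size();
  NumericMatrix out(q, p);
  std::vector<double> col(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = X(i, j);
    std::sort(col.begin(), col.end());
    for (int k = 0; k < q; ++k) {
      double h = (n - 1) * probs[k];
      int lo = (int)std::floor(h);
      double frac = h - lo;
      double v = col[lo];
      if (frac > 0 && lo + 1 < n) v += frac * (col[lo + 1] - col[lo]);
      out(k, j) = v;
    }
  }
  return out;
}

static inline double impurity(double pr, bool gini) {
  if (gini) return 2.0 * pr * (1.0 - pr);
  if (pr <= 0.0 || pr >= 1.0) return 0.0;
  return -(pr * std::log2(pr) + (1.0 - pr) * std::log2(1.0 - pr));
}

// best-split impurity decrease per column for a binary label
// [[Rcpp::export]]
NumericVector cpp_split_gain(NumericMatrix X, IntegerVector y01,
                             bool gini) {
  int n = X.nrow(), p = X.ncol();
  double tot1 = 0;
  for (int i = 0; i < n; ++i) tot1 += y01[i];
  double parent = impurity(tot1 / n, gini);
  NumericVector out(p);
  std::vector<int> ord(n);
  std::vector<double> xs(n);
  std::vector<int> ys(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    NumericMatrix::Column cj = X(_, j);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return cj[a] < cj[b]; });
    for (int i = 0; i < n; ++i) {
      xs[i] = cj[ord[i]];
      ys[i] = y01[ord[i]];
    }
    double cum1 = 0, best = 0;
    for (int i = 0; i < n - 1; ++i) {
      cum1 += ys[i];
      if (xs[i] >= xs[i + 1]) continue;
      double nl = i + 1, nr = n - nl;
      double child = (nl * impurity(cum1 / nl, gini) +
                      nr * impurity((tot1 - cum1) / nr, gini)) / n;
      double gain = parent - child;
      if (gain > best) best = gain;
    }
    out[j] = best;
  }
  return out;
}

// mutual information (bits) of quartile-binned columns with a binary label
// [[Rcpp::export]]
NumericVector cpp_mi_quartile(NumericMatrix X, IntegerVector y01) {
  int n = X.nrow(), p = X.ncol();
  NumericVector out(p);
  std::vector<double> col(n), srt(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = X(i, j);
    srt = col;
    std::sort(srt.begin(), srt.end());
    double qs[3];
    for (int k = 0; k < 3; ++k) {
      double h = (n - 1) * 0.25 * (k + 1);
      int lo = (int)std::floor(h);
      double frac = h - lo;
      double v = srt[lo];
      if (frac > 0 && lo + 1 < n) v += frac * (srt[lo + 1] - srt[lo]);
      qs[k] = v;
    }
    // unique strictly-increasing boundaries; bin = #(boundaries <= x),
    // matching findInterval on the deduplicated quartiles
    std::vector<double> uq;
    for (int k = 0; k < 3; ++k)
      if (uq.empty() || qs[k] > uq.back()) uq.push_back(qs[k]);
    double cnt[4][2] = {{0, 0}, {0, 0}, {0, 0}, {0, 0}};
    for (int i = 0; i < n; ++i) {
      int b = 0;
      for (size_t k = 0; k < uq.size(); ++k)
        if (col[i] >= uq[k]) ++b;
      cnt[b][y01[i]] += 1.0;
    }
    double mi = 0;
    double py[2] = {0, 0};
    double pb[4] = {0, 0, 0, 0};
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < 2; ++c) {
        pb[b] += cnt[b][c] / n;
        py[c] += cnt[b][c] / n;
      }
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < 2; ++c) {
        double pj = cnt[b][c] / n;
        if (pj > 0) mi += pj * std::log2(pj / (pb[b] * py[c]));
      }
    out[j] = mi;
  }
  return out;
}
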