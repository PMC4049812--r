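#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

// Squared Euclidean distance between delay-embedded points starting at
// 0-based sample indices i and j of x, with m coordinates spaced tau apart.
static inline double embed_dist2(const NumericVector &x, int i, int j,
                                 int m, int tau) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double diff = x[i + k * tau] - x[j + k * tau];
    d += diff * diff;
  }
  return d;
}

// Largest Lyapunov exponent, Rosenstein-style: for each reference point find
// its nearest neighbour outside a Theiler exclusion window, track the mean
// log separation of the pair over fit_steps forward samples, and return the
// least-squares slope of that divergence curve (nats per sample).
// max_points > 0 subsamples the reference/candidate set with a uniform
// stride to cap the O(n^2) neighbour search.
// [[Rcpp::export]]
double cpp_max_lyapunov(NumericVector x, int m, int tau, int theiler,
                        int fit_steps, int max_points) {
  int n = x.size();
  int span = (m - 1) * tau;
  int npts = n - span - fit_steps;
  if (npts < theiler + 10) return NA_REAL;

  int stride = 1;
  if (max_points > 0 && npts > max_points)
    stride = (npts + max_points - 1) / max_points;
  std::vector<int> idx;
  for (int i = 0; i < npts; i += stride) idx.push_back(i);
  int M = (int)idx.size();

  std::vector<double> sumlog(fit_steps + 1, 0.0);
  std::vector<int> cnt(fit_steps + 1, 0);

  for (int a = 0; a < M; ++a) {
    int i = idx[a];
    double best = R_PosInf;
    int bj = -1;
    for (int b = 0; b < M; ++b) {
      int j = idx[b];
      if (std::abs(i - j) <= theiler) continue;
      double d = embed_dist2(x, i, j, m, tau);
      if (d < best) { best = d; bj = j; }
    }
    if (bj < 0 || best <= 0.0) continue;
    for (int s = 0; s <= fit_steps; ++s) {
      double d = embed_dist2(x, i + s, bj + s, m, tau);
      if (d > 0.0) { sumlog[s] += 0.5 * std::log(d); cnt[s] += 1; }
    }
  }

  // least-squares slope of mean log distance against step
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  int np = 0;
  for (int s = 0; s <= fit_steps; ++s) {
    if (cnt[s] == 0) continue;
    double y = sumlog[s] / cnt[s];
    sx += s; sy += y; sxx += (double)s * s; sxy += s * y;
    np += 1;
  }
  if (np < 2) return NA_REAL;
  double denom = np * sxx - sx * sx;
  if (denom <= 0) return NA_REAL;
  return (np * sxy - sx * sy) / denom;
}

// Pair counts for the Grassberger-Procaccia correlation integral: number of
// embedded-point pairs (|i-j| > theiler) closer than each radius. Returns the
// counts; the total number of admissible pairs is attached as an attribute.
// [[Rcpp::export]]
IntegerVector cpp_corr_counts(NumericVector x, int m, int tau, int theiler,
                              NumericVector radii, int max_points) {
  int n = x.size();
  int span = (m - 1) * tau;
  int npts = n - span;
  int nr = radii.size();
  IntegerVector counts(nr);
  if (npts < theiler + 10) {
    counts.attr("npairs") = 0;
    return counts;
  }
  int stride = 1;
  if (max_points > 0 && npts > max_points)
    stride = (npts + max_points - 1) / max_points;
  std::vector<int> idx;
  for (int i = 0; i < npts; i += stride) idx.push_back(i);
  int M = (int)idx.size();

  std::vector<double> r2(nr);
  for (int r = 0; r < nr; ++r) r2[r] = radii[r] * radii[r];

  long long npairs = 0;
  std::vector<long long> cnt(nr, 0);
  for (int a = 0; a < M; ++a) {
    for (int b = a + 1; b < M; ++b) {
      if (std::abs(idx[a] - idx[b]) <= theiler) continue;
      npairs += 1;
      double d = embed_dist2(x, idx[a], idx[b], m, tau);
      for (int r = 0; r < nr; ++r)
        if (d < r2[r]) cnt[r] += 1;
    }
  }
  for (int r = 0; r < nr; ++r) counts[r] = (int)std::min<long long>(cnt[r], INT_MAX);
  counts.attr("npairs") = (double)npairs;
  return counts;
}

// Multi-class ReliefF weight updates (Robnik-Sikonja & Kononenko). X must be
// min-max scaled to [0, 1] so |x1 - x2| is the diff() contribution directly.
// y holds 0-based class codes, priors the class prior probabilities, samp the
// 0-based rows to iterate over (sampled in R for seed control). For each
// sampled row the k nearest hits and, per other class, k nearest misses are
// found under Manhattan distance; nearer ties broken by lower row index.
// [[Rcpp::export]]
NumericVector cpp_relieff(NumericMatrix X, IntegerVector y,
                          NumericVector priors, int k, IntegerVector samp) {
  int n = X.nrow(), f = X.ncol();
  int ncls = priors.size();
  int m_iter = samp.size();
  NumericVector W(f);

  std::vector<double> dist(n);
  // per-class candidate lists (index), rebuilt each iteration as (dist, idx)
  std::vector<std::vector<std::pair<double, int> > > byclass(ncls);

  for (int it = 0; it < m_iter; ++it) {
    int r = samp[it];
    int cr = y[r];
    for (int c = 0; c < ncls; ++c) byclass[c].clear();
    for (int j = 0; j < n; ++j) {
      if (j == r) continue;
      double d = 0.0;
      for (int a = 0; a < f; ++a) d += std::fabs(X(r, a) - X(j, a));
      byclass[y[j]].push_back(std::make_pair(d, j));
    }
    for (int c = 0; c < ncls; ++c) {
      std::vector<std::pair<double, int> > &v = byclass[c];
      if (v.empty()) continue;
      int kk = std::min<int>(k, (int)v.size());
      std::partial_sort(v.begin(), v.begin() + kk, v.end());
      double coef;
      if (c == cr) {
        coef = -1.0 / ((double)m_iter * kk);
      } else {
        coef = priors[c] / (1.0 - priors[cr]) / ((double)m_iter * kk);
      }
      for (int q = 0; q < kk; ++q) {
        int j = v[q].second;
        for (int a = 0; a < f; ++a)
          W[a] += coef * std::fabs(X(r, a) - X(j, a));
      }
    }
  }
  return W;
}
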