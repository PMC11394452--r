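#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Uniform-grid spatial hash over 3D points with cell edge = radius.
// Results are exact (contractually equal to brute force); the grid only
// prunes the candidate set.

namespace {

struct Grid {
  double cell;
  double ox, oy, oz;
  std::unordered_map<std::uint64_t, std::vector<int> > cells;

  static std::uint64_t key(int ix, int iy, int iz) {
    // offset into non-negative range, pack 21 bits each
    const std::uint64_t B = 1u << 20;
    return ((std::uint64_t)(ix + B) << 42) |
           ((std::uint64_t)(iy + B) << 21) |
           (std::uint64_t)(iz + B);
  }

  void build(const NumericMatrix& p, double cellsize) {
    cell = cellsize;
    int n = p.nrow();
    ox = oy = oz = 0.0;
    if (n > 0) { ox = p(0, 0); oy = p(0, 1); oz = p(0, 2); }
    cells.reserve(n);
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor((p(i, 0) - ox) / cell);
      int iy = (int)std::floor((p(i, 1) - oy) / cell);
      int iz = (int)std::floor((p(i, 2) - oz) / cell);
      cells[key(ix, iy, iz)].push_back(i);
    }
  }

  template <typename F>
  void for_neighbors(const NumericMatrix& p, double x, double y, double z,
                     F fn) const {
    int ix = (int)std::floor((x - ox) / cell);
    int iy = (int)std::floor((y - oy) / cell);
    int iz = (int)std::floor((z - oz) / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) fn(j);
        }
  }
};

inline double sqdist(const NumericMatrix& p, int i, double x, double y,
                     double z) {
  double dx = p(i, 0) - x, dy = p(i, 1) - y, dz = p(i, 2) - z;
  return dx * dx + dy * dy + dz * dz;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_radius_counts(NumericMatrix pts, double radius) {
  int n = pts.nrow();
  IntegerVector out(n);
  if (n == 0) return out;
  Grid g;
  g.build(pts, radius);
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    g.for_neighbors(pts, pts(i, 0), pts(i, 1), pts(i, 2), [&](int j) {
      if (j != i && sqdist(pts, j, pts(i, 0), pts(i, 1), pts(i, 2)) <= r2)
        ++cnt;
    });
    out[i] = cnt;
  }
  return out;
}

// counts of points of `pts` (excluding identical index when query_idx >= 1)
// within radius of each queried point; query_idx is 1-based or 0 to disable
// self-exclusion
// [[Rcpp::export]]
IntegerVector cpp_radius_counts_query(NumericMatrix pts, NumericMatrix query,
                                      IntegerVector query_idx, double radius) {
  int m = query.nrow();
  IntegerVector out(m);
  if (pts.nrow() == 0) return out;
  Grid g;
  g.build(pts, radius);
  double r2 = radius * radius;
  for (int q = 0; q < m; ++q) {
    int self = q < query_idx.size() ? query_idx[q] - 1 : -1;
    int cnt = 0;
    g.for_neighbors(pts, query(q, 0), query(q, 1), query(q, 2), [&](int j) {
      if (j != self &&
          sqdist(pts, j, query(q, 0), query(q, 1), query(q, 2)) <= r2)
        ++cnt;
    });
    out[q] = cnt;
  }
  return out;
}

// For each center (1-based index into pts): up to kmax point indices within
// radius, nearest-first (ties by lower index), padded with the center index.
// [[Rcpp::export]]
IntegerMatrix cpp_ball_group(NumericMatrix pts, IntegerVector centers,
                             double radius, int kmax) {
  int nc = centers.size();
  IntegerMatrix out(nc, kmax);
  Grid g;
  g.build(pts, radius);
  double r2 = radius * radius;
  std::vector<std::pair<double, int> > cand;
  for (int c = 0; c < nc; ++c) {
    int ci = centers[c] - 1;
    double x = pts(ci, 0), y = pts(ci, 1), z = pts(ci, 2);
    cand.clear();
    g.for_neighbors(pts, x, y, z, [&](int j) {
      double d2 = sqdist(pts, j, x, y, z);
      if (d2 <= r2) cand.push_back(std::make_pair(d2, j));
    });
    std::sort(cand.begin(), cand.end());
    int k = std::min((int)cand.size(), kmax);
    for (int j = 0; j < k; ++j) out(c, j) = cand[j].second + 1;
    for (int j = k; j < kmax; ++j) out(c, j) = ci + 1;
  }
  return out;
}

// brute-force k nearest neighbors of each query among ref rows
// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix ref, int k) {
  int m = query.nrow(), n = ref.nrow();
  k = std::min(k, n);
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<std::pair<double, int> > d(n);
  for (int q = 0; q < m; ++q) {
    for (int j = 0; j < n; ++j)
      d[j] = std::make_pair(sqdist(ref, j, query(q, 0), query(q, 1),
                                   query(q, 2)), j);
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) {
      idx(q, j) = d[j].second + 1;
      dist(q, j) = std::sqrt(d[j].first);
    }
  }
  return List::create(Named("idx") = idx, Named("dist") = dist);
}

// iterative farthest point sampling from a given start (1-based)
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix pts, int n1, int start) {
  int n = pts.nrow();
  IntegerVector out(n1);
  std::vector<double> mind(n, R_PosInf);
  int cur = start - 1;
  for (int s = 0; s < n1; ++s) {
    out[s] = cur + 1;
    double best = -1.0;
    int bestj = cur;
    for (int j = 0; j < n; ++j) {
      double d2 = sqdist(pts, j, pts(cur, 0), pts(cur, 1), pts(cur, 2));
      if (d2 < mind[j]) mind[j] = d2;
      if (mind[j] > best) { best = mind[j]; bestj = j; }
    }
    cur = bestj;
  }
  return out;
}
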