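// Low-level image primitives for nuclei/cell-body segmentation.
// The environment ships no R image-analysis stack, so the classical
// operators (separable Gaussian blur, connected components, chamfer
// distance transform, seeded priority-flood watershed, contour-based
// perimeter) are implemented here.
#include <Rcpp.h>
#include <functional>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// reflect index into [0, n)
static inline int reflect(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *src = img.begin();
  double *dst = tmp.begin();
  // vertical pass (column-contiguous)
  for (int c = 0; c < nc; ++c) {
    const double *col = src + (R_xlen_t)c * nr;
    double *tcol = dst + (R_xlen_t)c * nr;
    int lo = std::min(radius, nr);
    for (int r = 0; r < lo; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * col[reflect(r + i, nr)];
      tcol[r] = acc;
    }
    for (int r = radius; r < nr - radius; ++r) {
      double acc = 0.0;
      const double *p = col + r - radius;
      for (int i = 0; i <= 2 * radius; ++i) acc += k[i] * p[i];
      tcol[r] = acc;
    }
    for (int r = std::max(nr - radius, lo); r < nr; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * col[reflect(r + i, nr)];
      tcol[r] = acc;
    }
  }
  // horizontal pass: accumulate shifted columns into out
  double *o = out.begin();
  for (int c = 0; c < nc; ++c) {
    double *ocol = o + (R_xlen_t)c * nr;
    for (int i = -radius; i <= radius; ++i) {
      const double *tcol = dst + (R_xlen_t)reflect(c + i, nc) * nr;
      double kv = k[i + radius];
      for (int r = 0; r < nr; ++r) ocol[r] += kv * tcol[r];
    }
  }
  return out;
}

// Two-pass connected components with union-find; 8-connectivity default.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix bin, bool eight = true) {
  int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!bin(r, c)) continue;
      int up = (r > 0) ? lab(r - 1, c) : 0;
      int lf = (c > 0) ? lab(r, c - 1) : 0;
      int ul = (eight && r > 0 && c > 0) ? lab(r - 1, c - 1) : 0;
      int ur = 0; // up-right neighbour: column c-1, row r+1 in column-major scan
      if (eight && c > 0 && r + 1 < nr) ur = lab(r + 1, c - 1);
      int m = 0;
      int nb[4] = {up, lf, ul, ur};
      for (int i = 0; i < 4; ++i)
        if (nb[i] > 0 && (m == 0 || nb[i] < m)) m = nb[i];
      if (m == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = m;
        for (int i = 0; i < 4; ++i) if (nb[i] > 0) unite(m, nb[i]);
      }
    }
  }
  // relabel consecutively
  std::vector<int> remap(next, 0);
  int K = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) {
        int root = find(lab(r, c));
        if (remap[root] == 0) remap[root] = ++K;
        lab(r, c) = remap[root];
      }
  lab.attr("n_objects") = K;
  return lab;
}

// Chamfer 3-4 distance transform to the background, rescaled to ~pixels.
// [[Rcpp::export(name = ".distance_transform_cpp")]]
NumericMatrix distance_transform_cpp(LogicalMatrix bin) {
  int nr = bin.nrow(), nc = bin.ncol();
  const double BIG = 1e12, A = 3.0, B = 4.0;
  NumericMatrix d(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) = bin(r, c) ? BIG : 0.0;
  // forward pass
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (d(r, c) == 0.0) continue;
      double v = d(r, c);
      if (r > 0) v = std::min(v, d(r - 1, c) + A);
      if (c > 0) v = std::min(v, d(r, c - 1) + A);
      if (r > 0 && c > 0) v = std::min(v, d(r - 1, c - 1) + B);
      if (r + 1 < nr && c > 0) v = std::min(v, d(r + 1, c - 1) + B);
      d(r, c) = v;
    }
  // backward pass
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      if (d(r, c) == 0.0) continue;
      double v = d(r, c);
      if (r + 1 < nr) v = std::min(v, d(r + 1, c) + A);
      if (c + 1 < nc) v = std::min(v, d(r, c + 1) + A);
      if (r + 1 < nr && c + 1 < nc) v = std::min(v, d(r + 1, c + 1) + B);
      if (r > 0 && c + 1 < nc) v = std::min(v, d(r - 1, c + 1) + B);
      d(r, c) = v;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) /= A;
  return d;
}

struct WsNode {
  double elev;
  long order;
  int r, c, lab;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.elev != b.elev) return a.elev > b.elev; // min-heap on elevation
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Seeded watershed: flood `mask` from `seeds` in order of increasing
// elevation. Unseeded mask pixels unreachable from any seed stay 0.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerMatrix watershed_cpp(NumericMatrix elev, IntegerMatrix seeds,
                            LogicalMatrix mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push({elev(r, c), order++, r, c, seeds(r, c)});
      }
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    for (int i = 0; i < 8; ++i) {
      int r2 = nd.r + dr[i], c2 = nd.c + dc[i];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
      lab(r2, c2) = nd.lab;
      pq.push({std::max(elev(r2, c2), nd.elev), order++, r2, c2, nd.lab});
    }
  }
  return lab;
}

// Perimeter per label via Moore boundary tracing with the classical
// corner-corrected chain weights (0.948 straight, 1.340 diagonal).
// [[Rcpp::export(name = ".perimeter_cpp")]]
NumericVector perimeter_cpp(IntegerMatrix lab, int nlab) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(nlab);
  std::vector<char> done(nlab + 1, 0);
  // Moore neighbourhood in clockwise order starting at W
  const int mr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int mc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return lab(r, c);
  };
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int L = lab(r, c);
      if (L == 0 || done[L]) continue;
      done[L] = 1;
      // count object size quickly? trace boundary from (r, c); the scan order
      // guarantees the background is at direction W-ish of the start pixel.
      int ne = 0, no = 0;
      int cr = r, cc = c;
      int backtrack = 0; // came from W
      int startR = r, startC = c, startDir = -1;
      int guard = 8 * (nr + nc) * 8;
      bool single = true;
      for (int i = 0; i < 8; ++i)
        if (at(r + mr[i], c + mc[i]) == L) { single = false; break; }
      if (single) {
        per[L - 1] = 3.55; // matched-area small-object convention (~2*sqrt(pi))
        continue;
      }
      int steps = 0;
      while (guard-- > 0) {
        int found = -1;
        for (int i = 0; i < 8; ++i) {
          int dir = (backtrack + i) % 8;
          int r2 = cr + mr[dir], c2 = cc + mc[dir];
          if (at(r2, c2) == L) { found = dir; break; }
        }
        if (found < 0) break;
        if (startDir < 0) startDir = found;
        else if (cr == startR && cc == startC && found == startDir && steps > 0)
          break;
        if (mr[found] != 0 && mc[found] != 0) ++no; else ++ne;
        cr += mr[found];
        cc += mc[found];
        // new backtrack: direction pointing back to previous pixel, +1 cw
        backtrack = (found + 5) % 8;
        ++steps;
      }
      per[L - 1] = 0.948 * ne + 1.340 * no;
    }
  }
  return per;
}

// Local maxima of img within a square window of half-width min_dist,
// restricted to pixels where mask is true and img >= threshold.
// Returns 2-column matrix of 1-based (row, col).
// [[Rcpp::export(name = ".local_maxima_cpp")]]
IntegerMatrix local_maxima_cpp(NumericMatrix img, LogicalMatrix mask,
                               int min_dist, double threshold) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> rows, cols;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || img(r, c) < threshold) continue;
      double v = img(r, c);
      bool is_max = true;
      for (int dc2 = -min_dist; dc2 <= min_dist && is_max; ++dc2)
        for (int dr2 = -min_dist; dr2 <= min_dist; ++dr2) {
          int r2 = r + dr2, c2 = c + dc2;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (img(r2, c2) > v ||
              (img(r2, c2) == v && (c2 < c || (c2 == c && r2 < r)))) {
            is_max = false;
            break;
          }
        }
      if (is_max) { rows.push_back(r + 1); cols.push_back(c + 1); }
    }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}
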