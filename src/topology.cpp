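#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Raster conventions used throughout: a square grid of `resolution` pixels per
// side covering [lo, hi]^2; matrix row i corresponds to y, column j to x
// (1-based at the R level).  Pixel (i, j) has center
//   x = lo + (j - 0.5) * px,  y = lo + (i - 0.5) * px,   px = (hi - lo)/res.

static inline int clamp_int(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trace the closed polyline through (xs, ys) onto the grid: every pixel
// containing a vertex is set, plus the Bresenham line between consecutive
// vertices (8-connected), including the closing edge.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize(NumericVector xs, NumericVector ys,
                            int resolution, double lo, double hi) {
  const int n = xs.size();
  LogicalMatrix grid(resolution, resolution);
  const double px = (hi - lo) / resolution;
  std::vector<int> ci(n), ri(n);
  for (int k = 0; k < n; ++k) {
    ci[k] = clamp_int((int)std::floor((xs[k] - lo) / px), 0, resolution - 1);
    ri[k] = clamp_int((int)std::floor((ys[k] - lo) / px), 0, resolution - 1);
  }
  for (int k = 0; k < n; ++k) {
    int k2 = (k + 1) % n;
    int x0 = ci[k], y0 = ri[k], x1 = ci[k2], y1 = ri[k2];
    int dx = std::abs(x1 - x0), sx = x0 < x1 ? 1 : -1;
    int dy = -std::abs(y1 - y0), sy = y0 < y1 ? 1 : -1;
    int err = dx + dy;
    while (true) {
      grid(y0, x0) = true;
      if (x0 == x1 && y0 == y1) break;
      int e2 = 2 * err;
      if (e2 >= dy) { err += dy; x0 += sx; }
      if (e2 <= dx) { err += dx; y0 += sy; }
    }
  }
  return grid;
}

// Gaussian density estimator, exactly as defined for the contour point cloud:
// Phi(q) = (1/n) * sum_i (1/sqrt(2*pi)) * exp(-((|q - y_i|)/h)^2 / 2).
// Note the kernel constant is 1/sqrt(2*pi) with no bandwidth factor in the
// normalizer; the estimator is a dimensionless neighbor-density score, not a
// probability density.
// [[Rcpp::export]]
NumericVector cpp_gaussian_density(NumericVector qx, NumericVector qy,
                                   NumericVector px, NumericVector py,
                                   double h) {
  const int nq = qx.size(), np = px.size();
  const double c = 1.0 / std::sqrt(2.0 * M_PI);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double s = 0.0;
    const double x = qx[q], y = qy[q];
    for (int i = 0; i < np; ++i) {
      const double dx = x - px[i], dy = y - py[i];
      s += std::exp(-(dx * dx + dy * dy) * inv2h2);
    }
    out[q] = c * s / np;
  }
  return out;
}

// Euler characteristic of a binary mask: number of 8-connected foreground
// components minus number of 4-connected background components not touching
// the grid border (holes).  Iterative flood fill.
// [[Rcpp::export]]
int cpp_euler(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> lab((size_t)nr * nc, 0);
  std::vector<int> stack;
  int ncomp = 0;
  auto idx = [nc](int r, int c) { return (size_t)r * nc + c; };

  // foreground, 8-connected
  for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
    if (!mask(r, c) || lab[idx(r, c)]) continue;
    ++ncomp;
    lab[idx(r, c)] = 1;
    stack.clear();
    stack.push_back((int)idx(r, c));
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pr = p / nc, pc = p % nc;
      for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
        if (!dr && !dc) continue;
        int qr = pr + dr, qc = pc + dc;
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (mask(qr, qc) && !lab[idx(qr, qc)]) {
          lab[idx(qr, qc)] = 1;
          stack.push_back((int)idx(qr, qc));
        }
      }
    }
  }

  // background, 4-connected; components touching the border are not holes
  int nholes = 0;
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
    if (mask(r, c) || lab[idx(r, c)]) continue;
    bool border = false;
    lab[idx(r, c)] = 2;
    stack.clear();
    stack.push_back((int)idx(r, c));
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pr = p / nc, pc = p % nc;
      if (pr == 0 || pr == nr - 1 || pc == 0 || pc == nc - 1) border = true;
      for (int k = 0; k < 4; ++k) {
        int qr = pr + dr4[k], qc = pc + dc4[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (!mask(qr, qc) && !lab[idx(qr, qc)]) {
          lab[idx(qr, qc)] = 2;
          stack.push_back((int)idx(qr, qc));
        }
      }
    }
    if (!border) ++nholes;
  }
  return ncomp - nholes;
}

// Contribution of one 2x2 block to 4 * EC under the 8-connected foreground /
// 4-connected hole convention (Gray's local-pattern count):
//   one foreground pixel -> +1, three -> -1, two diagonal -> -2, else 0.
static inline int quad_contrib(const std::vector<unsigned char>& img,
                               int nr, int nc, int r, int c) {
  // block with top-left pixel (r, c); out-of-range cells count as background
  auto at = [&](int rr, int cc) -> int {
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) return 0;
    return img[(size_t)rr * nc + cc];
  };
  const int a = at(r, c), b = at(r, c + 1), d = at(r + 1, c), e = at(r + 1, c + 1);
  const int s = a + b + d + e;
  if (s == 1) return 1;
  if (s == 3) return -1;
  if (s == 2 && ((a && e) || (b && d))) return -2;
  return 0;
}

// Euler characteristic curve of a superlevel-set filtration.  Pixels (rows,
// cols: 0-based) carry density values; thresholds are given in descending
// order.  Entry j is the EC of the mask { pixel : value >= thresholds[j] },
// computed incrementally: pixels are inserted in order of decreasing value and
// the EC is maintained through local 2x2 block-pattern updates.
// [[Rcpp::export]]
IntegerVector cpp_ec_curve(IntegerVector rows, IntegerVector cols,
                           NumericVector values, int nr, int nc,
                           NumericVector thresholds) {
  const int n = rows.size(), nl = thresholds.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return values[a] > values[b];
  });
  std::vector<unsigned char> img((size_t)nr * nc, 0);
  IntegerVector out(nl);
  long ec4 = 0;   // 4 * Euler characteristic
  int ptr = 0;
  for (int j = 0; j < nl; ++j) {
    const double thr = thresholds[j];
    while (ptr < n && values[ord[ptr]] >= thr) {
      const int r = rows[ord[ptr]], c = cols[ord[ptr]];
      // remove old contributions of the 4 blocks containing (r, c), flip, re-add
      for (int dr = -1; dr <= 0; ++dr) for (int dc = -1; dc <= 0; ++dc)
        ec4 -= quad_contrib(img, nr, nc, r + dr, c + dc);
      img[(size_t)r * nc + c] = 1;
      for (int dr = -1; dr <= 0; ++dr) for (int dc = -1; dc <= 0; ++dc)
        ec4 += quad_contrib(img, nr, nc, r + dr, c + dc);
      ++ptr;
    }
    out[j] = (int)(ec4 / 4);
  }
  return out;
}
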