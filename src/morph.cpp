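// Zhang-Suen thinning and Gaussian tube rendering: small dense raster
// loops that are far off the vectorization grain of R.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalMatrix zhang_suen_cpp(const LogicalMatrix& bin, int max_iter) {
  const int nr = bin.nrow(), nc = bin.ncol();
  std::vector<unsigned char> B((nr + 2) * (nc + 2), 0);
  auto at = [&](int i, int j) -> unsigned char& { return B[i + j * (nr + 2)]; };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) at(i + 1, j + 1) = bin(i, j) ? 1 : 0;

  std::vector<std::pair<int, int>> del;
  for (int iter = 0; iter < max_iter; ++iter) {
    bool changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int j = 1; j <= nc; ++j) {
        for (int i = 1; i <= nr; ++i) {
          if (!at(i, j)) continue;
          // P2..P9 clockwise from north (north = smaller row index)
          const int p[8] = { at(i - 1, j), at(i - 1, j + 1), at(i, j + 1),
                             at(i + 1, j + 1), at(i + 1, j), at(i + 1, j - 1),
                             at(i, j - 1), at(i - 1, j - 1) };
          int bsum = 0, a = 0;
          for (int q = 0; q < 8; ++q) {
            bsum += p[q];
            if (!p[q] && p[(q + 1) % 8]) ++a;
          }
          if (bsum < 2 || bsum > 6 || a != 1) continue;
          const bool c1 = step == 0 ? !(p[0] && p[2] && p[4]) : !(p[0] && p[2] && p[6]);
          const bool c2 = step == 0 ? !(p[2] && p[4] && p[6]) : !(p[0] && p[4] && p[6]);
          if (c1 && c2) del.emplace_back(i, j);
        }
      }
      for (auto& ij : del) at(ij.first, ij.second) = 0;
      if (!del.empty()) changed = true;
    }
    if (!changed) break;
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = at(i + 1, j + 1) != 0;
  return out;
}

// max-composites Gaussian cross-sections exp(-d^2 / (2 w^2)) centred at
// (x, y) (0-based pixel-centre coords) onto an s x s canvas
// [[Rcpp::export]]
NumericMatrix render_tubes_cpp(const NumericMatrix& points, int s) {
  NumericMatrix vm(s, s);
  for (int r = 0; r < points.nrow(); ++r) {
    const double x = points(r, 0), y = points(r, 1), w = points(r, 2);
    const int hw = (int)std::ceil(3.0 * w);
    const int x0 = std::max(0, (int)std::floor(x) - hw);
    const int x1 = std::min(s - 1, (int)std::ceil(x) + hw);
    const int y0 = std::max(0, (int)std::floor(y) - hw);
    const int y1 = std::min(s - 1, (int)std::ceil(y) + hw);
    const double inv = 1.0 / (2.0 * w * w);
    for (int cx = x0; cx <= x1; ++cx) {
      const double dx2 = (cx - x) * (cx - x);
      for (int cy = y0; cy <= y1; ++cy) {
        const double d2 = dx2 + (cy - y) * (cy - y);
        const double v = std::exp(-d2 * inv);
        if (v > vm(cy, cx)) vm(cy, cx) = v;
      }
    }
  }
  return vm;
}
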