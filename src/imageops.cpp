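#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// symmetric (half-sample) reflection of an index into [0, n)
static inline int reflect(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// 3x3 Sobel gradient magnitude, border handled by reflection.
// gx responds to horizontal (column-direction) intensity change,
// gy to vertical (row-direction) change.
// [[Rcpp::export(name = ".sobel_mag_cpp")]]
NumericMatrix sobel_mag_cpp(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double gx = 0.0, gy = 0.0;
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          double v = img(reflect(r + dr, nr), reflect(c + dc, nc));
          // Sobel weights: smooth along one axis, differentiate the other
          int wx = dc * (dr == 0 ? 2 : 1);
          int wy = dr * (dc == 0 ? 2 : 1);
          gx += wx * v;
          gy += wy * v;
        }
      }
      out(r, c) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return out;
}

// Hysteresis thresholding: keep pixels >= high, plus pixels >= low that are
// 8-connected (through other kept pixels) to a >= high pixel.
// [[Rcpp::export(name = ".hysteresis_cpp")]]
LogicalMatrix hysteresis_cpp(NumericMatrix mag, double low, double high) {
  const int nr = mag.nrow(), nc = mag.ncol();
  LogicalMatrix keep(nr, nc);
  std::vector<char> weak(static_cast<size_t>(nr) * nc, 0);
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = mag(r, c);
      if (v >= high) {
        keep(r, c) = TRUE;
        q.push(std::make_pair(r, c));
      } else if (v >= low) {
        weak[r + static_cast<size_t>(nr) * c] = 1;
      }
    }
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        int r = p.first + dr, c = p.second + dc;
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        size_t i = r + static_cast<size_t>(nr) * c;
        if (weak[i] && !keep(r, c)) {
          keep(r, c) = TRUE;
          q.push(std::make_pair(r, c));
        }
      }
  }
  return keep;
}
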