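// Binary morphology and connected components on 3-D (or 2-D, nz = 1)
// voxel grids, plus paired bilinear/nearest image warps used by the
// standardization and augmentation steps.
//
// Arrays arrive as logical/numeric vectors with a dim attribute
// (nz, ny, nx), column-major.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline R_xlen_t lin(const int z, const int y, const int x,
                           const int nz, const int ny) {
  return static_cast<R_xlen_t>(x) * nz * ny + static_cast<R_xlen_t>(y) * nz + z;
}

// 6-connected component labelling (axis neighbours only); labels 1..K by
// discovery order, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const LogicalVector& mask, const int nz,
                          const int ny, const int nx) {
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t cur = q.front();
      q.pop();
      const int x = cur / (static_cast<R_xlen_t>(nz) * ny);
      const int rem = cur % (static_cast<R_xlen_t>(nz) * ny);
      const int y = rem / nz, z = rem % nz;
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        const int z2 = z + dz[d], y2 = y + dy[d], x2 = x + dx[d];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        const R_xlen_t s2 = lin(z2, y2, x2, nz, ny);
        if (mask[s2] && !lab[s2]) {
          lab[s2] = next;
          q.push(s2);
        }
      }
    }
  }
  return lab;
}

// Separable box dilation: sliding "any" along each axis with the given
// radii (voxels), O(N) per axis via a running window count. Outside the
// grid counts as background.
static void dilate_axis(std::vector<char>& m, const int nz, const int ny,
                        const int nx, const int axis, const int r) {
  if (r <= 0) return;
  const int n[3] = {nz, ny, nx};
  const int len = n[axis];
  const R_xlen_t stride =
      axis == 0 ? 1
                : (axis == 1 ? static_cast<R_xlen_t>(nz)
                             : static_cast<R_xlen_t>(nz) * ny);
  std::vector<char> line(len);
  for (int a = 0; a < (axis == 0 ? ny : nz); ++a)
    for (int b = 0; b < (axis == 2 ? ny : nx); ++b) {
      // base index of this 1-D line
      R_xlen_t base;
      if (axis == 0) base = lin(0, a, b, nz, ny);
      else if (axis == 1) base = lin(a, 0, b, nz, ny);
      else base = lin(a, b, 0, nz, ny);
      int count = 0;  // set voxels inside the sliding window
      for (int t = 0; t < std::min(r, len); ++t)
        count += m[base + t * stride] != 0;
      for (int t = 0; t < len; ++t) {
        if (t + r < len) count += m[base + (t + r) * stride] != 0;
        line[t] = count > 0;
        if (t - r >= 0) count -= m[base + (t - r) * stride] != 0;
      }
      for (int t = 0; t < len; ++t) m[base + t * stride] = line[t];
    }
}

// [[Rcpp::export]]
LogicalVector cpp_dilate_box(const LogicalVector& mask, const int nz,
                             const int ny, const int nx, const int rz,
                             const int ry, const int rx) {
  std::vector<char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;
  dilate_axis(m, nz, ny, nx, 0, rz);
  dilate_axis(m, nz, ny, nx, 1, ry);
  dilate_axis(m, nz, ny, nx, 2, rx);
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  return out;
}

// Sample img (nr x nc) at fractional 0-based coordinates; out-of-range
// samples take `fill`. map_r/map_c give, per output pixel, the source
// row/column.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(const NumericMatrix& img,
                                const NumericMatrix& map_r,
                                const NumericMatrix& map_c,
                                const double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const int onr = map_r.nrow(), onc = map_r.ncol();
  NumericMatrix out(onr, onc);
  for (int j = 0; j < onc; ++j)
    for (int i = 0; i < onr; ++i) {
      const double r = map_r(i, j), c = map_c(i, j);
      if (r < 0 || c < 0 || r > nr - 1 || c > nc - 1) {
        out(i, j) = fill;
        continue;
      }
      const int r0 = static_cast<int>(std::floor(r));
      const int c0 = static_cast<int>(std::floor(c));
      const int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
      const double fr = r - r0, fc = c - c0;
      out(i, j) = (1 - fr) * (1 - fc) * img(r0, c0) +
                  fr * (1 - fc) * img(r1, c0) +
                  (1 - fr) * fc * img(r0, c1) + fr * fc * img(r1, c1);
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_nearest(const NumericMatrix& img,
                               const NumericMatrix& map_r,
                               const NumericMatrix& map_c,
                               const double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const int onr = map_r.nrow(), onc = map_r.ncol();
  NumericMatrix out(onr, onc);
  for (int j = 0; j < onc; ++j)
    for (int i = 0; i < onr; ++i) {
      const double r = map_r(i, j), c = map_c(i, j);
      const int ri = static_cast<int>(std::floor(r + 0.5));
      const int ci = static_cast<int>(std::floor(c + 0.5));
      out(i, j) = (ri < 0 || ci < 0 || ri >= nr || ci >= nc) ? fill
                                                             : img(ri, ci);
    }
  return out;
}
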