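#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// All arrays come in as R arrays with dim = c(nz, ny, nx): the first index
// (fastest-varying in memory) is z, then y, then x. Linear index of voxel
// (iz, iy, ix), 0-based: iz + nz * (iy + ny * ix).

// 3D connected-component labeling by breadth-first flood fill.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full neighborhood).
// Seeds are scanned in increasing linear index, so labels are deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_3d(const LogicalVector& mask, const IntegerVector& dims,
                          const int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offset table
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nn = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++current;
    labels[seed] = current;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int iz = (int)(v % nz);
      int iy = (int)((v / nz) % ny);
      int ix = (int)(v / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nn; ++k) {
        int z2 = iz + dz[k], y2 = iy + dy[k], x2 = ix + dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        R_xlen_t w = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

static inline int reflect_index(int i, const int n) {
  // scipy-style 'reflect' boundary: (d c b a | a b c d)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 1D convolution along one axis of a 3D array with reflecting boundary.
// kernel has odd length; axis is 1 (z), 2 (y) or 3 (x).
// [[Rcpp::export]]
NumericVector conv_axis3d(const NumericVector& vol, const IntegerVector& dims,
                          const NumericVector& kernel, const int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (vol.size() != n) stop("volume length does not match dims");
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int r = kl / 2;

  NumericVector out(n);
  const int len = dims[axis - 1];
  R_xlen_t stride;
  if (axis == 1) stride = 1;
  else if (axis == 2) stride = nz;
  else if (axis == 3) stride = (R_xlen_t)nz * ny;
  else stop("axis must be 1, 2 or 3");

  // iterate over all lines along `axis`
  const int d1 = (axis == 1) ? ny : nz;
  const int d2 = (axis == 3) ? ny : nx;
  R_xlen_t s1, s2;
  if (axis == 1)      { s1 = nz;                 s2 = (R_xlen_t)nz * ny; }
  else if (axis == 2) { s1 = 1;                  s2 = (R_xlen_t)nz * ny; }
  else                { s1 = 1;                  s2 = nz; }

  std::vector<double> line(len);
  for (int j = 0; j < d2; ++j) {
    for (int i = 0; i < d1; ++i) {
      const R_xlen_t base = i * s1 + j * s2;
      for (int t = 0; t < len; ++t) line[t] = vol[base + t * stride];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k)
          acc += kernel[k + r] * line[reflect_index(t + k, len)];
        out[base + t * stride] = acc;
      }
    }
  }
  return out;
}

// Greedy measuring-sphere packing.
//
// Candidate centers are the mask voxels, visited in order of decreasing
// `intensity`, ties broken by lowest (z, y, x) tuple. A sphere is accepted
// at a candidate iff (a) the candidate is not yet covered, (b) at least
// fit_fraction of the sphere's voxels (out-of-bounds voxels count against
// the fraction) are uncovered mask voxels, and (c) its center lies at a
// physical distance >= diameter from every previously accepted center.
// Accepted spheres mark all their in-bounds voxels covered.
//
// offsets: m x 3 integer matrix of (dz, dy, dx) voxel offsets of the
// sphere stencil; spacing_um = c(z, y, x) voxel spacing.
// Returns a k x 3 matrix of 1-based (iz, iy, ix) centers in acceptance order.
// [[Rcpp::export]]
IntegerMatrix pack_spheres_cpp(const NumericVector& intensity,
                               const LogicalVector& mask,
                               const IntegerVector& dims,
                               const IntegerMatrix& offsets,
                               const double fit_fraction,
                               const NumericVector& spacing_um,
                               const double diameter_um) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n || intensity.size() != n)
    stop("array lengths do not match dims");
  const int m = offsets.nrow();

  std::vector<R_xlen_t> cand;
  cand.reserve(1024);
  for (R_xlen_t v = 0; v < n; ++v)
    if (mask[v]) cand.push_back(v);

  // decreasing intensity, ties by (z, y, x) lexicographic
  std::stable_sort(cand.begin(), cand.end(),
                   [&](const R_xlen_t a, const R_xlen_t b) {
    if (intensity[a] != intensity[b]) return intensity[a] > intensity[b];
    int za = (int)(a % nz), ya = (int)((a / nz) % ny),
        xa = (int)(a / ((R_xlen_t)nz * ny));
    int zb = (int)(b % nz), yb = (int)((b / nz) % ny),
        xb = (int)(b / ((R_xlen_t)nz * ny));
    if (za != zb) return za < zb;
    if (ya != yb) return ya < yb;
    return xa < xb;
  });

  std::vector<char> covered(n, 0);
  std::vector<int> acc_z, acc_y, acc_x;
  const double sz = spacing_um[0], sy = spacing_um[1], sx = spacing_um[2];
  const double d2min = diameter_um * diameter_um - 1e-9;

  for (size_t ci = 0; ci < cand.size(); ++ci) {
    const R_xlen_t v = cand[ci];
    if (covered[v]) continue;
    const int iz = (int)(v % nz);
    const int iy = (int)((v / nz) % ny);
    const int ix = (int)(v / ((R_xlen_t)nz * ny));

    int good = 0;
    for (int k = 0; k < m; ++k) {
      int z2 = iz + offsets(k, 0), y2 = iy + offsets(k, 1),
          x2 = ix + offsets(k, 2);
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      R_xlen_t w = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
      if (mask[w] && !covered[w]) ++good;
    }
    if ((double)good / (double)m < fit_fraction) continue;

    bool overlaps = false;
    for (size_t a = 0; a < acc_z.size(); ++a) {
      double ddz = (iz - acc_z[a]) * sz;
      double ddy = (iy - acc_y[a]) * sy;
      double ddx = (ix - acc_x[a]) * sx;
      if (ddz * ddz + ddy * ddy + ddx * ddx < d2min) { overlaps = true; break; }
    }
    if (overlaps) continue;

    acc_z.push_back(iz); acc_y.push_back(iy); acc_x.push_back(ix);
    for (int k = 0; k < m; ++k) {
      int z2 = iz + offsets(k, 0), y2 = iy + offsets(k, 1),
          x2 = ix + offsets(k, 2);
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      covered[z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2)] = 1;
    }
  }

  IntegerMatrix res((int)acc_z.size(), 3);
  for (int i = 0; i < (int)acc_z.size(); ++i) {
    res(i, 0) = acc_z[i] + 1;
    res(i, 1) = acc_y[i] + 1;
    res(i, 2) = acc_x[i] + 1;
  }
  return res;
}
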