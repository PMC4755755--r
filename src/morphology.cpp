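#include <Rcpp.h>
#include <array>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared), anisotropy-aware.
// Felzenszwalb & Huttenlocher lower-envelope recursion applied per axis.
// Input: fg (logical), dims (2 or 3), spacing per axis (physical units).
// Output: squared distance from each foreground voxel center to the nearest
// background voxel center; 0 on background voxels.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d, double w,
                 std::vector<int> &v, std::vector<double> &z) {
  const int n = (int)f.size();
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dim,
                         NumericVector spacing) {
  const int nd = dim.size();
  int d0 = dim[0], d1 = (nd > 1) ? dim[1] : 1, d2 = (nd > 2) ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector out(n);
  // large finite sentinel: keeps the lower-envelope recursion well-defined
  // on all-foreground scan lines (infinities would yield s = -inf)
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? INF : 0.0;

  int maxd = std::max(d0, std::max(d1, d2));
  std::vector<double> f(maxd), dbuf(maxd), z(maxd + 1);
  std::vector<int> v(maxd);

  // axis 0 (fastest varying)
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j) {
      R_xlen_t base = (R_xlen_t)k * d0 * d1 + (R_xlen_t)j * d0;
      for (int i = 0; i < d0; ++i) f[i] = out[base + i];
      f.resize(d0); dbuf.resize(d0);
      dt1d(f, dbuf, spacing[0], v, z);
      for (int i = 0; i < d0; ++i) out[base + i] = dbuf[i];
      f.resize(maxd); dbuf.resize(maxd);
    }
  // axis 1
  if (nd > 1) {
    for (int k = 0; k < d2; ++k)
      for (int i = 0; i < d0; ++i) {
        R_xlen_t base = (R_xlen_t)k * d0 * d1 + i;
        for (int j = 0; j < d1; ++j) f[j] = out[base + (R_xlen_t)j * d0];
        f.resize(d1); dbuf.resize(d1);
        dt1d(f, dbuf, spacing[1], v, z);
        for (int j = 0; j < d1; ++j) out[base + (R_xlen_t)j * d0] = dbuf[j];
        f.resize(maxd); dbuf.resize(maxd);
      }
  }
  // axis 2
  if (nd > 2) {
    R_xlen_t plane = (R_xlen_t)d0 * d1;
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        R_xlen_t base = (R_xlen_t)j * d0 + i;
        for (int k = 0; k < d2; ++k) f[k] = out[base + (R_xlen_t)k * plane];
        f.resize(d2); dbuf.resize(d2);
        dt1d(f, dbuf, spacing[2], v, z);
        for (int k = 0; k < d2; ++k) out[base + (R_xlen_t)k * plane] = dbuf[k];
        f.resize(maxd); dbuf.resize(maxd);
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving thinning (skeletonization).
// 2D: 8-connected foreground / 4-connected background.
// 3D: 26-connected foreground / 6-connected background
//     (Malandain-Bertrand simple-point characterization).
// Sequential directional border peeling; curve endpoints (<= 1 foreground
// neighbor) are preserved. Deterministic scan order.
// ---------------------------------------------------------------------------

// --- 2D helpers: patch is uint8_t[9], row-major (dy, dx) with center at 4 ---
static int fg_components_2d(const uint8_t *patch) {
  // 8-connected components of foreground among the 8 neighbors
  bool seen[9] = {false};
  int ncomp = 0;
  static const int pos[8] = {0, 1, 2, 3, 5, 6, 7, 8};
  for (int s = 0; s < 8; ++s) {
    int p = pos[s];
    if (!patch[p] || seen[p]) continue;
    ++ncomp;
    std::queue<int> q;
    q.push(p); seen[p] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cy = c / 3, cx = c % 3;
      for (int s2 = 0; s2 < 8; ++s2) {
        int p2 = pos[s2];
        if (seen[p2] || !patch[p2]) continue;
        int dy = std::abs(p2 / 3 - cy), dx = std::abs(p2 % 3 - cx);
        if (dy <= 1 && dx <= 1) { seen[p2] = true; q.push(p2); }
      }
    }
  }
  return ncomp;
}

static int bg_components_2d(const uint8_t *patch) {
  // 4-connected components of background among the 8 neighbors that are
  // 4-adjacent to the center (i.e., contain one of positions 1,3,5,7)
  bool seen[9] = {false};
  int ncomp = 0;
  static const int seeds[4] = {1, 3, 5, 7};
  static const int pos[8] = {0, 1, 2, 3, 5, 6, 7, 8};
  for (int s = 0; s < 4; ++s) {
    int p = seeds[s];
    if (patch[p] || seen[p]) continue;
    ++ncomp;
    std::queue<int> q;
    q.push(p); seen[p] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cy = c / 3, cx = c % 3;
      for (int s2 = 0; s2 < 8; ++s2) {
        int p2 = pos[s2];
        if (seen[p2] || patch[p2]) continue;
        int dy = std::abs(p2 / 3 - cy), dx = std::abs(p2 % 3 - cx);
        if (dy + dx == 1) { seen[p2] = true; q.push(p2); }
      }
    }
  }
  return ncomp;
}

static bool simple_2d(const uint8_t *patch) {
  return fg_components_2d(patch) == 1 && bg_components_2d(patch) == 1;
}

// --- 3D helpers: patch is uint8_t[27], index = (dz*3+dy)*3+dx, center 13 ---
static int fg_components_3d(const uint8_t *patch) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !patch[p] || seen[p]) continue;
    ++ncomp;
    std::queue<int> q;
    q.push(p); seen[p] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cz = c / 9, cy = (c / 3) % 3, cx = c % 3;
      for (int p2 = 0; p2 < 27; ++p2) {
        if (p2 == 13 || seen[p2] || !patch[p2]) continue;
        int dz = std::abs(p2 / 9 - cz), dy = std::abs((p2 / 3) % 3 - cy),
            dx = std::abs(p2 % 3 - cx);
        if (dz <= 1 && dy <= 1 && dx <= 1) { seen[p2] = true; q.push(p2); }
      }
    }
  }
  return ncomp;
}

static bool in_n18(int p) {
  if (p == 13) return false;
  int dz = p / 9 - 1, dy = (p / 3) % 3 - 1, dx = p % 3 - 1;
  return std::abs(dz) + std::abs(dy) + std::abs(dx) <= 2;
}

static int bg_components_3d(const uint8_t *patch) {
  // 6-connected components of background within the 18-neighborhood that
  // contain at least one of the 6 face-neighbors of the center
  static const int faces[6] = {4, 10, 12, 14, 16, 22};
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 6; ++s) {
    int p = faces[s];
    if (patch[p] || seen[p]) continue;
    ++ncomp;
    std::queue<int> q;
    q.push(p); seen[p] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cz = c / 9, cy = (c / 3) % 3, cx = c % 3;
      for (int p2 = 0; p2 < 27; ++p2) {
        if (seen[p2] || patch[p2] || !in_n18(p2)) continue;
        int dz = std::abs(p2 / 9 - cz), dy = std::abs((p2 / 3) % 3 - cy),
            dx = std::abs(p2 % 3 - cx);
        if (dz + dy + dx == 1) { seen[p2] = true; q.push(p2); }
      }
    }
  }
  return ncomp;
}

static bool simple_3d(const uint8_t *patch) {
  return fg_components_3d(patch) == 1 && bg_components_3d(patch) == 1;
}

// [[Rcpp::export(name = ".cpp_thin")]]
LogicalVector cpp_thin(LogicalVector img, IntegerVector dim) {
  const int nd = dim.size();
  int d0 = dim[0], d1 = dim[1], d2 = (nd > 2) ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  std::vector<uint8_t> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = img[i] ? 1 : 0;
  const R_xlen_t plane = (R_xlen_t)d0 * d1;
  const bool is3d = (nd > 2 && d2 > 1);

  auto at = [&](int i, int j, int k) -> uint8_t {
    if (i < 0 || i >= d0 || j < 0 || j >= d1 || k < 0 || k >= d2) return 0;
    return a[(R_xlen_t)k * plane + (R_xlen_t)j * d0 + i];
  };
  auto nb_count = [&](int i, int j, int k) -> int {
    int c = 0;
    int klo = is3d ? -1 : 0, khi = is3d ? 1 : 0;
    for (int dk = klo; dk <= khi; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          c += at(i + di, j + dj, k + dk);
        }
    return c;
  };
  auto fill_patch2 = [&](int i, int j, uint8_t *patch) {
    int t = 0;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) patch[t++] = at(i + di, j + dj, 0);
  };
  auto fill_patch3 = [&](int i, int j, int k, uint8_t *patch) {
    int t = 0;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          patch[t++] = at(i + di, j + dj, k + dk);
  };
  auto deletable = [&](int i, int j, int k) -> bool {
    int nc = nb_count(i, j, k);
    if (nc <= 1) return false;  // endpoint or isolated: preserved
    if (is3d) {
      uint8_t patch[27];
      fill_patch3(i, j, k, patch);
      return simple_3d(patch);
    } else {
      uint8_t patch[9];
      fill_patch2(i, j, patch);
      return simple_2d(patch);
    }
  };

  // face directions (di, dj, dk)
  std::vector<std::array<int, 3>> dirs;
  dirs.push_back({-1, 0, 0});
  dirs.push_back({1, 0, 0});
  dirs.push_back({0, -1, 0});
  dirs.push_back({0, 1, 0});
  if (is3d) {
    dirs.push_back({0, 0, -1});
    dirs.push_back({0, 0, 1});
  }

  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (auto &d : dirs) {
      cand.clear();
      for (int k = 0; k < d2; ++k)
        for (int j = 0; j < d1; ++j)
          for (int i = 0; i < d0; ++i) {
            R_xlen_t idx = (R_xlen_t)k * plane + (R_xlen_t)j * d0 + i;
            if (!a[idx]) continue;
            if (at(i + d[0], j + d[1], k + d[2])) continue;  // not border
            if (deletable(i, j, k)) cand.push_back(idx);
          }
      // sequential deletion with re-check preserves topology
      for (R_xlen_t idx : cand) {
        int k = (int)(idx / plane);
        int j = (int)((idx % plane) / d0);
        int i = (int)(idx % d0);
        if (deletable(i, j, k)) {
          a[idx] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis, reflect (half-sample) boundary.
// kernel must have odd length; correlation orientation (symmetric and
// even/odd kernels used pairwise, so orientation cancels where it matters).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_conv_axis")]]
NumericVector cpp_conv_axis(NumericVector arr, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nd = dim.size();
  int d0 = dim[0], d1 = (nd > 1) ? dim[1] : 1, d2 = (nd > 2) ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  const int klen = kernel.size();
  const int c = klen / 2;
  NumericVector out(n);
  out.attr("dim") = dim;

  int dlen = (axis == 0) ? d0 : (axis == 1 ? d1 : d2);
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1 ? d0 : (R_xlen_t)d0 * d1);

  auto reflect = [&](int i) -> int {
    while (i < 0 || i >= dlen) {
      if (i < 0) i = -1 - i;
      if (i >= dlen) i = 2 * dlen - 1 - i;
    }
    return i;
  };

  // iterate over all lines along `axis`
  int o1 = (axis == 0) ? d1 : d0;
  int o2 = (axis == 2) ? d1 : d2;
  R_xlen_t s1 = (axis == 0) ? (R_xlen_t)d0 : 1;
  R_xlen_t s2 = (axis == 2) ? (R_xlen_t)d0 : (R_xlen_t)d0 * d1;

  std::vector<double> line(dlen);
  for (int b2 = 0; b2 < o2; ++b2)
    for (int b1 = 0; b1 < o1; ++b1) {
      R_xlen_t base = (R_xlen_t)b2 * s2 + (R_xlen_t)b1 * s1;
      for (int i = 0; i < dlen; ++i) line[i] = arr[base + (R_xlen_t)i * stride];
      for (int i = 0; i < dlen; ++i) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k)
          acc += kernel[k] * line[reflect(i + k - c)];
        out[base + (R_xlen_t)i * stride] = acc;
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// 3x3(x3) median filter, reflect boundary (radius-1 box).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_median3")]]
NumericVector cpp_median3(NumericVector arr, IntegerVector dim) {
  const int nd = dim.size();
  int d0 = dim[0], d1 = dim[1], d2 = (nd > 2) ? dim[2] : 1;
  const bool is3d = (nd > 2 && d2 > 1);
  const R_xlen_t plane = (R_xlen_t)d0 * d1;
  const R_xlen_t n = plane * d2;
  NumericVector out(n);
  out.attr("dim") = dim;
  auto refl = [](int i, int m) { return i < 0 ? -1 - i : (i >= m ? 2 * m - 1 - i : i); };
  std::vector<double> buf(27);
  int klo = is3d ? -1 : 0, khi = is3d ? 1 : 0;
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        int t = 0;
        for (int dk = klo; dk <= khi; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int ii = refl(i + di, d0), jj = refl(j + dj, d1),
                  kk = refl(k + dk, d2);
              buf[t++] = arr[(R_xlen_t)kk * plane + (R_xlen_t)jj * d0 + ii];
            }
        std::nth_element(buf.begin(), buf.begin() + t / 2, buf.begin() + t);
        out[(R_xlen_t)k * plane + (R_xlen_t)j * d0 + i] = buf[t / 2];
      }
  return out;
}
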