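#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Voxel grids arrive as R arrays in column-major order: linear index
// l = i + nx*(j + ny*k) with 0-based (i,j,k).  All functions here keep that
// convention and return 1-based linear indices where indices are returned.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Separable interpolation kernels
// ---------------------------------------------------------------------------

// Cubic B-spline kernel applied directly (no interpolation prefilter): a
// smoothing spline with non-negative weights that sum to 1, so constants
// are reproduced exactly, values never undershoot, and the count integral
// is conserved.  The extra smoothing is the accepted trade-off of cubic
// spline resampling of emission data.
static inline void cubic_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  double u = 1.0 - t;
  w[0] = u * u * u / 6.0;
  w[1] = (3.0 * t3 - 6.0 * t2 + 4.0) / 6.0;
  w[2] = (-3.0 * t3 + 3.0 * t2 + 3.0 * t + 1.0) / 6.0;
  w[3] = t3 / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector values, IntegerVector dim_in,
                             IntegerVector dim_out, NumericVector scale,
                             NumericVector offset, int order) {
  const int nxi = dim_in[0], nyi = dim_in[1], nzi = dim_in[2];
  const int nxo = dim_out[0], nyo = dim_out[1], nzo = dim_out[2];
  NumericVector out((R_xlen_t)nxo * nyo * nzo);

  // Per-axis tap tables: base index and weights for every output index.
  int ntap = (order == 3) ? 4 : (order == 1 ? 2 : 1);
  std::vector<std::vector<int>> base(3);
  std::vector<std::vector<double>> wt(3);
  int dins[3] = {nxi, nyi, nzi};
  int douts[3] = {nxo, nyo, nzo};
  for (int a = 0; a < 3; a++) {
    base[a].resize((size_t)douts[a] * ntap);
    wt[a].resize((size_t)douts[a] * ntap);
    for (int o = 0; o < douts[a]; o++) {
      double x = offset[a] + o * scale[a];  // input voxel-index coordinate
      if (order == 0) {
        base[a][o] = clampi((int)std::floor(x + 0.5), 0, dins[a] - 1);
        wt[a][o] = 1.0;
      } else if (order == 1) {
        int i0 = (int)std::floor(x);
        double t = x - i0;
        base[a][(size_t)o * 2] = clampi(i0, 0, dins[a] - 1);
        base[a][(size_t)o * 2 + 1] = clampi(i0 + 1, 0, dins[a] - 1);
        wt[a][(size_t)o * 2] = 1.0 - t;
        wt[a][(size_t)o * 2 + 1] = t;
      } else {
        int i0 = (int)std::floor(x);
        double t = x - i0;
        double w[4];
        cubic_weights(t, w);
        for (int q = 0; q < 4; q++) {
          base[a][(size_t)o * 4 + q] = clampi(i0 - 1 + q, 0, dins[a] - 1);
          wt[a][(size_t)o * 4 + q] = w[q];
        }
      }
    }
  }

  const double *vin = values.begin();
  double *vout = out.begin();
  for (int k = 0; k < nzo; k++) {
    for (int j = 0; j < nyo; j++) {
      for (int i = 0; i < nxo; i++) {
        double acc = 0.0;
        for (int qz = 0; qz < ntap; qz++) {
          int kz = base[2][(size_t)k * ntap + qz];
          double wz = wt[2][(size_t)k * ntap + qz];
          if (wz == 0.0) continue;
          for (int qy = 0; qy < ntap; qy++) {
            int ky = base[1][(size_t)j * ntap + qy];
            double wy = wt[1][(size_t)j * ntap + qy] * wz;
            if (wy == 0.0) continue;
            const double *row = vin + (R_xlen_t)nxi * (ky + (R_xlen_t)nyi * kz);
            for (int qx = 0; qx < ntap; qx++) {
              acc += row[base[0][(size_t)i * ntap + qx]] *
                     wt[0][(size_t)i * ntap + qx] * wy;
            }
          }
        }
        vout[i + (R_xlen_t)nxo * (j + (R_xlen_t)nyo * k)] = acc;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 26-neighbourhood helpers
// ---------------------------------------------------------------------------

// Local-maximum mask: voxel > 0 and >= every in-bounds 26-neighbour.
// [[Rcpp::export]]
LogicalVector cpp_local_max_mask(NumericVector values, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(values.size());
  const double *v = values.begin();
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t l = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double val = v[l];
        if (val <= 0) { out[l] = false; continue; }
        bool ok = true;
        for (int dk = -1; dk <= 1 && ok; dk++)
          for (int dj = -1; dj <= 1 && ok; dj++)
            for (int di = -1; di <= 1; di++) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              if (v[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] > val) {
                ok = false; break;
              }
            }
        out[l] = ok;
      }
  return out;
}

// Connected components of a logical mask (26- or 6-connectivity).
// Returns integer labels (0 = background), labelled in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < mask.size(); start++) {
    if (!mask[start] || lab[start] != 0) continue;
    next++;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t l = stack.back(); stack.pop_back();
      int i = (int)(l % nx), j = (int)((l / nx) % ny), k = (int)(l / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
              continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t m = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[m] && lab[m] == 0) { lab[m] = next; stack.push_back(m); }
          }
    }
  }
  return lab;
}

// Region growing from one seed: a neighbour n of an accepted voxel c is
// accepted iff value(n) <= value(c) and value(n) > 0 (non-increasing descent
// over 26-connectivity).  Each directed edge is examined once; a voxel
// rejected from one parent may still be accepted later from another, so the
// claim set equals monotone-path reachability from the seed.
// Uses an epoch-stamped visited buffer so repeated calls do not reallocate.
static std::vector<int> grow_visited;
static int grow_epoch = 0;

// [[Rcpp::export]]
IntegerVector cpp_grow_region(NumericVector values, IntegerVector dim,
                              int seed1) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = values.begin();
  R_xlen_t n = values.size();
  if ((R_xlen_t)grow_visited.size() != n) {
    grow_visited.assign(n, 0);
    grow_epoch = 0;
  }
  grow_epoch++;
  R_xlen_t seed = seed1 - 1;
  if (v[seed] <= 0) stop("seed value must be positive");
  std::vector<R_xlen_t> queue;
  queue.push_back(seed);
  grow_visited[seed] = grow_epoch;
  size_t head = 0;
  while (head < queue.size()) {
    R_xlen_t l = queue[head++];
    double val = v[l];
    int i = (int)(l % nx), j = (int)((l / nx) % ny), k = (int)(l / ((R_xlen_t)nx * ny));
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          R_xlen_t m = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (grow_visited[m] == grow_epoch) continue;
          double w = v[m];
          if (w > 0 && w <= val) {
            grow_visited[m] = grow_epoch;
            queue.push_back(m);
          }
        }
  }
  IntegerVector out(queue.size());
  for (size_t q = 0; q < queue.size(); q++) out[q] = (int)queue[q] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Binary morphology with an explicit offset list (ball structuring element)
// ---------------------------------------------------------------------------

// offsets: 3-column integer matrix of (di, dj, dk) displacements.
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  for (R_xlen_t l = 0; l < mask.size(); l++) {
    if (!mask[l]) continue;
    int i = (int)(l % nx), j = (int)((l / nx) % ny), k = (int)(l / ((R_xlen_t)nx * ny));
    for (int o = 0; o < offsets.nrow(); o++) {
      int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      out[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] = true;
    }
  }
  return out;
}

// Erosion; displacements falling outside the grid are ignored (outside is
// treated as foreground), so closing built from this pair is extensive.
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  for (R_xlen_t l = 0; l < mask.size(); l++) {
    int i = (int)(l % nx), j = (int)((l / nx) % ny), k = (int)(l / ((R_xlen_t)nx * ny));
    bool keep = true;
    for (int o = 0; o < offsets.nrow() && keep; o++) {
      int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      if (!mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) keep = false;
    }
    out[l] = keep;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-slice hole filling (axial slices, 4-connectivity)
// ---------------------------------------------------------------------------

// Background pixels of each z-slice not 4-connected to the slice border are
// converted to foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(mask);
  std::vector<char> reach((size_t)nx * ny);
  std::vector<int> stack;
  for (int k = 0; k < nz; k++) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    R_xlen_t off = (R_xlen_t)nx * ny * k;
    for (int i = 0; i < nx; i++) {
      for (int jb = 0; jb < 2; jb++) {
        int j = jb == 0 ? 0 : ny - 1;
        if (!mask[off + i + (R_xlen_t)nx * j] && !reach[i + nx * j]) {
          reach[i + nx * j] = 1; stack.push_back(i + nx * j);
        }
      }
    }
    for (int j = 0; j < ny; j++) {
      for (int ib = 0; ib < 2; ib++) {
        int i = ib == 0 ? 0 : nx - 1;
        if (!mask[off + i + (R_xlen_t)nx * j] && !reach[i + nx * j]) {
          reach[i + nx * j] = 1; stack.push_back(i + nx * j);
        }
      }
    }
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int i = p % nx, j = p / nx;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int q = 0; q < 4; q++) {
        int ii = i + di[q], jj = j + dj[q];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        int pp = ii + nx * jj;
        if (!mask[off + pp] && !reach[pp]) { reach[pp] = 1; stack.push_back(pp); }
      }
    }
    for (int p = 0; p < nx * ny; p++)
      if (!mask[off + p] && !reach[p]) out[off + p] = true;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur (zero padding outside the grid)
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double> &v, int nx, int ny, int nz, int axis,
                      double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int q = -r; q <= r; q++) {
    ker[q + r] = std::exp(-0.5 * q * q / (sigma * sigma));
    s += ker[q + r];
  }
  for (auto &x : ker) x /= s;
  int dims[3] = {nx, ny, nz};
  int n = dims[axis];
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  std::vector<double> line(n);
  // iterate over all lines along `axis`
  int na = dims[(axis + 1) % 3], nb = dims[(axis + 2) % 3];
  R_xlen_t sa = (axis + 1) % 3 == 0 ? 1 : ((axis + 1) % 3 == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  R_xlen_t sb = (axis + 2) % 3 == 0 ? 1 : ((axis + 2) % 3 == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  for (int b = 0; b < nb; b++)
    for (int a = 0; a < na; a++) {
      R_xlen_t base = a * sa + b * sb;
      for (int q = 0; q < n; q++) line[q] = v[base + q * stride];
      for (int q = 0; q < n; q++) {
        double acc = 0;
        int lo = std::max(0, q - r), hi = std::min(n - 1, q + r);
        for (int p = lo; p <= hi; p++) acc += line[p] * ker[p - q + r];
        v[base + q * stride] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector values, IntegerVector dim,
                                NumericVector sigma_vox) {
  std::vector<double> v(values.begin(), values.end());
  for (int a = 0; a < 3; a++) blur_axis(v, dim[0], dim[1], dim[2], a, sigma_vox[a]);
  return NumericVector(v.begin(), v.end());
}

// ---------------------------------------------------------------------------
// Block averaging (grid degradation to native scanner spacing)
// ---------------------------------------------------------------------------

// Trailing partial blocks are averaged over the voxels actually available.
// [[Rcpp::export]]
NumericVector cpp_block_average(NumericVector values, IntegerVector dim,
                                IntegerVector block) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int bx = block[0], by = block[1], bz = block[2];
  const int ox = (nx + bx - 1) / bx, oy = (ny + by - 1) / by, oz = (nz + bz - 1) / bz;
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; k++)
    for (int j = 0; j < oy; j++)
      for (int i = 0; i < ox; i++) {
        double acc = 0; int cnt = 0;
        for (int dk = 0; dk < bz; dk++)
          for (int dj = 0; dj < by; dj++)
            for (int di = 0; di < bx; di++) {
              int ii = i * bx + di, jj = j * by + dj, kk = k * bz + dk;
              if (ii >= nx || jj >= ny || kk >= nz) continue;
              acc += values[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
              cnt++;
            }
        out[i + (R_xlen_t)ox * (j + (R_xlen_t)oy * k)] = acc / cnt;
      }
  out.attr("outdim") = IntegerVector::create(ox, oy, oz);
  return out;
}
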