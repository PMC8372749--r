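#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Resample a 3D volume onto an output grid. `map` is a 4x4 matrix taking
// 0-based output voxel indices (i,j,k,1) to continuous 0-based source indices.
// method: 0 = trilinear, 1 = nearest neighbour. Out-of-field -> 0.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector src_dim,
                           IntegerVector out_dim, NumericMatrix map,
                           int method) {
  const int sx = src_dim[0], sy = src_dim[1], sz = src_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double m00 = map(0,0), m01 = map(0,1), m02 = map(0,2), m03 = map(0,3);
  const double m10 = map(1,0), m11 = map(1,1), m12 = map(1,2), m13 = map(1,3);
  const double m20 = map(2,0), m21 = map(2,1), m22 = map(2,2), m23 = map(2,3);
  const double *s = src.begin();
  double *o = out.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      const double bx = m01 * j + m02 * k + m03;
      const double by = m11 * j + m12 * k + m13;
      const double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        const double x = m00 * i + bx;
        const double y = m10 * i + by;
        const double z = m20 * i + bz;
        if (method == 1) {
          const int xi = (int)std::lround(x), yi = (int)std::lround(y),
                    zi = (int)std::lround(z);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= sx || yi >= sy || zi >= sz)
            continue;
          o[idx] = s[(R_xlen_t)xi + (R_xlen_t)sx * (yi + (R_xlen_t)sy * zi)];
        } else {
          if (x < 0 || y < 0 || z < 0 || x > sx - 1 || y > sy - 1 || z > sz - 1)
            continue;
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          if (x0 == sx - 1) --x0;
          if (y0 == sy - 1) --y0;
          if (z0 == sz - 1) --z0;
          if (x0 < 0) x0 = 0;
          if (y0 < 0) y0 = 0;
          if (z0 < 0) z0 = 0;
          const double fx = x - x0, fy = y - y0, fz = z - z0;
          const R_xlen_t base =
              (R_xlen_t)x0 + (R_xlen_t)sx * (y0 + (R_xlen_t)sy * z0);
          const R_xlen_t dy = sx, dz = (R_xlen_t)sx * sy;
          const double c000 = s[base],          c100 = s[base + 1];
          const double c010 = s[base + dy],     c110 = s[base + dy + 1];
          const double c001 = s[base + dz],     c101 = s[base + dz + 1];
          const double c011 = s[base + dy + dz], c111 = s[base + dy + dz + 1];
          const double c00 = c000 + fx * (c100 - c000);
          const double c10 = c010 + fx * (c110 - c010);
          const double c01 = c001 + fx * (c101 - c001);
          const double c11 = c011 + fx * (c111 - c011);
          const double c0 = c00 + fy * (c10 - c00);
          const double c1 = c01 + fy * (c11 - c01);
          o[idx] = c0 + fz * (c1 - c0);
        }
      }
    }
  }
  return out;
}

// Label connected components of a binary mask (26- or 6-connectivity).
// Returns integer labels 1..n, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offs_i, offs_j, offs_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
          continue;
        offs_i.push_back(di);
        offs_j.push_back(dj);
        offs_k.push_back(dk);
      }
  const int noff = (int)offs_i.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      const int i = (int)(v % nx), j = (int)((v / nx) % ny),
                k = (int)(v / ((R_xlen_t)nx * ny));
      for (int t = 0; t < noff; ++t) {
        const int ii = i + offs_i[t], jj = j + offs_j[t], kk = k + offs_k[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        const R_xlen_t w = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// Voxels (within an optional mask) whose value is >= all 26 neighbours.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector x, IntegerVector dim,
                               LogicalVector mask) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const bool use_mask = mask.size() == n;
  LogicalVector out(n, false);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (use_mask && !mask[v]) continue;
    const int i = (int)(v % nx), j = (int)((v / nx) % ny),
              k = (int)(v / ((R_xlen_t)nx * ny));
    const double val = x[v];
    bool is_max = true;
    for (int dk = -1; dk <= 1 && is_max; ++dk)
      for (int dj = -1; dj <= 1 && is_max; ++dj)
        for (int di = -1; di <= 1 && is_max; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          if (x[(R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] > val)
            is_max = false;
        }
    out[v] = is_max;
  }
  return out;
}

// Binary dilation (op = 0) or erosion (op = 1) with an arbitrary structuring
// element given as an m x 3 matrix of integer voxel offsets.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets, int op) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int m = offsets.nrow();
  LogicalVector out(n, false);
  for (R_xlen_t v = 0; v < n; ++v) {
    const int i = (int)(v % nx), j = (int)((v / nx) % ny),
              k = (int)(v / ((R_xlen_t)nx * ny));
    if (op == 0) {  // dilation: any SE voxel hits the mask
      bool hit = false;
      for (int t = 0; t < m && !hit; ++t) {
        const int ii = i + offsets(t, 0), jj = j + offsets(t, 1),
                  kk = k + offsets(t, 2);
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        if (mask[(R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)])
          hit = true;
      }
      out[v] = hit;
    } else {  // erosion: all SE voxels inside the mask (outside FOV counts out)
      bool all_in = true;
      for (int t = 0; t < m && all_in; ++t) {
        const int ii = i + offsets(t, 0), jj = j + offsets(t, 1),
                  kk = k + offsets(t, 2);
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
          all_in = false;
          continue;
        }
        if (!mask[(R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)])
          all_in = false;
      }
      out[v] = all_in;
    }
  }
  return out;
}
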