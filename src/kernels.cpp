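// Low-level image kernels. Volumes are passed as numeric vectors in R array
// layout (Y fastest, then X, then Z): idx = y + ny*(x + nx*z). All filters
// use reflect (mirror) edge handling.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  // mirror without repeating the edge sample twice beyond bounds
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, int ny, int nx, int nz,
                           int radius, bool in_plane) {
  NumericVector out(vol.size());
  int rz = in_plane ? 0 : radius;
  int wmax = (2 * radius + 1) * (2 * radius + 1) * (2 * rz + 1);
  std::vector<double> buf(wmax);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int k = 0;
        for (int dz = -rz; dz <= rz; ++dz) {
          int zz = reflect(z + dz, nz);
          for (int dx = -radius; dx <= radius; ++dx) {
            int xx = reflect(x + dx, nx);
            for (int dy = -radius; dy <= radius; ++dy) {
              int yy = reflect(y + dy, ny);
              buf[k++] = vol[yy + (size_t)ny * (xx + (size_t)nx * zz)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
        out[y + (size_t)ny * (x + (size_t)nx * z)] = buf[k / 2];
      }
  return out;
}

// Contrast-limited adaptive histogram equalization of one 2D slice.
// Tiles of `block` x `block`, 256 bins spanning the slice range, clip limit
// expressed as a fraction of tile pixel count; bilinear blending of tile
// mappings. Output in [0, 1]. A constant slice maps to all zeros.
// [[Rcpp::export]]
NumericVector cpp_clahe2d(NumericVector img, int ny, int nx, int block,
                          double clip) {
  const int nbin = 256;
  NumericVector out(img.size());
  double lo = R_PosInf, hi = R_NegInf;
  for (R_xlen_t i = 0; i < img.size(); ++i) {
    if (img[i] < lo) lo = img[i];
    if (img[i] > hi) hi = img[i];
  }
  if (!(hi > lo)) return out;  // constant slice
  double scale = (nbin - 1) / (hi - lo);
  int nty = (ny + block - 1) / block, ntx = (nx + block - 1) / block;
  // per-tile clipped-CDF mapping
  std::vector<double> map((size_t)nty * ntx * nbin);
  for (int tx = 0; tx < ntx; ++tx)
    for (int ty = 0; ty < nty; ++ty) {
      int y0 = ty * block, y1 = std::min(ny, y0 + block);
      int x0 = tx * block, x1 = std::min(nx, x0 + block);
      double npix = (double)(y1 - y0) * (x1 - x0);
      std::vector<double> hist(nbin, 0.0);
      for (int x = x0; x < x1; ++x)
        for (int y = y0; y < y1; ++y) {
          int b = (int)std::floor((img[y + (size_t)ny * x] - lo) * scale + 0.5);
          hist[b]++;
        }
      double limit = std::max(1.0, clip * npix);
      double excess = 0.0;
      for (int b = 0; b < nbin; ++b)
        if (hist[b] > limit) { excess += hist[b] - limit; hist[b] = limit; }
      double add = excess / nbin;
      double cum = 0.0;
      size_t off = ((size_t)ty + (size_t)nty * tx) * nbin;
      for (int b = 0; b < nbin; ++b) {
        cum += hist[b] + add;
        map[off + b] = cum / npix;
      }
    }
  // bilinear interpolation between tile centers
  for (int x = 0; x < nx; ++x) {
    double gx = (x - block / 2.0) / block;
    int tx0 = (int)std::floor(gx);
    double fx = gx - tx0;
    int txa = std::min(std::max(tx0, 0), ntx - 1);
    int txb = std::min(std::max(tx0 + 1, 0), ntx - 1);
    for (int y = 0; y < ny; ++y) {
      double gy = (y - block / 2.0) / block;
      int ty0 = (int)std::floor(gy);
      double fy = gy - ty0;
      int tya = std::min(std::max(ty0, 0), nty - 1);
      int tyb = std::min(std::max(ty0 + 1, 0), nty - 1);
      int b = (int)std::floor((img[y + (size_t)ny * x] - lo) * scale + 0.5);
      double v00 = map[((size_t)tya + (size_t)nty * txa) * nbin + b];
      double v01 = map[((size_t)tya + (size_t)nty * txb) * nbin + b];
      double v10 = map[((size_t)tyb + (size_t)nty * txa) * nbin + b];
      double v11 = map[((size_t)tyb + (size_t)nty * txb) * nbin + b];
      double v = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                 fy * ((1 - fx) * v10 + fx * v11);
      out[y + (size_t)ny * x] = std::min(1.0, std::max(0.0, v));
    }
  }
  return out;
}

// Separable Gaussian blur, sigma per axis in voxels (0 skips an axis).
static void gauss1d(std::vector<double> &line, double sigma,
                    std::vector<double> &tmp) {
  int n = (int)line.size();
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &v : k) v /= s;
  tmp.resize(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0;
    for (int j = -r; j <= r; ++j) acc += k[j + r] * line[reflect(i + j, n)];
    tmp[i] = acc;
  }
  line.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, int ny, int nx, int nz,
                          double sy, double sx, double sz) {
  NumericVector out = clone(vol);
  std::vector<double> line, tmp;
  if (sy > 0) {
    line.resize(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        size_t off = (size_t)ny * (x + (size_t)nx * z);
        for (int y = 0; y < ny; ++y) line[y] = out[off + y];
        gauss1d(line, sy, tmp);
        for (int y = 0; y < ny; ++y) out[off + y] = line[y];
      }
  }
  if (sx > 0) {
    line.resize(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x)
          line[x] = out[y + (size_t)ny * (x + (size_t)nx * z)];
        gauss1d(line, sx, tmp);
        for (int x = 0; x < nx; ++x)
          out[y + (size_t)ny * (x + (size_t)nx * z)] = line[x];
      }
  }
  if (sz > 0 && nz > 1) {
    line.resize(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z)
          line[z] = out[y + (size_t)ny * (x + (size_t)nx * z)];
        gauss1d(line, sz, tmp);
        for (int z = 0; z < nz; ++z)
          out[y + (size_t)ny * (x + (size_t)nx * z)] = line[z];
      }
  }
  return out;
}

static void neighbor_offsets(int conn, int ny, int nx, int nz,
                             std::vector<std::array<int, 3>> &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int m = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (conn == 6 && m != 1) continue;
        if (nz == 1 && dz != 0) continue;
        off.push_back({dy, dx, dz});
      }
}

// Connected components of a mask, 6- or 26-connectivity (4/8 when nz == 1).
// Labels are 1..K in scan order of the first voxel met.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int ny, int nx, int nz, int conn) {
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(conn, ny, nx, nz, off);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < (size_t)mask.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int z = (int)(p / ((size_t)ny * nx));
      int rem = (int)(p % ((size_t)ny * nx));
      int x = rem / ny, y = rem % ny;
      for (auto &d : off) {
        int yy = y + d[0], xx = x + d[1], zz = z + d[2];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        size_t q = yy + (size_t)ny * (xx + (size_t)nx * zz);
        if (mask[q] && !lab[q]) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Exact Euclidean distance transform (Felzenszwalb-Huttenlocher), anisotropic
// voxel spacing; returns distance in physical units from each foreground
// voxel to the nearest background voxel.
static void dt1d(std::vector<double> &f, double d) {
  int n = (int)f.size();
  std::vector<double> out(n);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = R_NegInf;
  zb[1] = R_PosInf;
  double d2 = d * d;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + d2 * q * q) - (f[v[k]] + d2 * v[k] * v[k])) /
          (2.0 * d2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    out[q] = d2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
  f.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, int ny, int nx, int nz,
                        double dy, double dx, double dz) {
  size_t n = mask.size();
  NumericVector out(n);
  const double INF = 1e30;
  for (size_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;
  std::vector<double> line;
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t off = (size_t)ny * (x + (size_t)nx * z);
      for (int y = 0; y < ny; ++y) line[y] = out[off + y];
      dt1d(line, dy);
      for (int y = 0; y < ny; ++y) out[off + y] = line[y];
    }
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x)
        line[x] = out[y + (size_t)ny * (x + (size_t)nx * z)];
      dt1d(line, dx);
      for (int x = 0; x < nx; ++x)
        out[y + (size_t)ny * (x + (size_t)nx * z)] = line[x];
    }
  if (nz > 1) {
    line.resize(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z)
          line[z] = out[y + (size_t)ny * (x + (size_t)nx * z)];
        dt1d(line, dz);
        for (int z = 0; z < nz; ++z)
          out[y + (size_t)ny * (x + (size_t)nx * z)] = line[z];
      }
  }
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// Seeded watershed by priority flood: voxels inside `mask` are flooded from
// the seed labels in ascending order of `prio` (pass -distance to grow from
// distance maxima). FIFO tie-break makes the result deterministic.
struct PQItem {
  double v;
  unsigned long long order;
  size_t idx;
};
struct PQCmp {
  bool operator()(const PQItem &a, const PQItem &b) const {
    if (a.v != b.v) return a.v > b.v;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector prio, IntegerVector seeds,
                              LogicalVector mask, int ny, int nx, int nz,
                              int conn) {
  IntegerVector lab = clone(seeds);
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(conn, ny, nx, nz, off);
  std::priority_queue<PQItem, std::vector<PQItem>, PQCmp> pq;
  unsigned long long order = 0;
  for (size_t i = 0; i < (size_t)lab.size(); ++i)
    if (lab[i] > 0 && mask[i]) pq.push({prio[i], order++, i});
  while (!pq.empty()) {
    PQItem it = pq.top();
    pq.pop();
    size_t p = it.idx;
    int z = (int)(p / ((size_t)ny * nx));
    int rem = (int)(p % ((size_t)ny * nx));
    int x = rem / ny, y = rem % ny;
    for (auto &d : off) {
      int yy = y + d[0], xx = x + d[1], zz = z + d[2];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      size_t q = yy + (size_t)ny * (xx + (size_t)nx * zz);
      if (mask[q] && lab[q] == 0) {
        lab[q] = lab[p];
        pq.push({prio[q], order++, q});
      }
    }
  }
  return lab;
}

// Morphological reconstruction by erosion of `marker` above `ref`
// (marker >= ref everywhere); sequential raster scans until stable.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_erosion(NumericVector marker, NumericVector ref,
                                      int ny, int nx, int nz, int conn) {
  NumericVector g = clone(marker);
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(conn, ny, nx, nz, off);
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 1000) {
    changed = false;
    for (int dir = 0; dir < 2; ++dir) {
      for (size_t s = 0; s < (size_t)g.size(); ++s) {
        size_t p = dir == 0 ? s : (size_t)g.size() - 1 - s;
        int z = (int)(p / ((size_t)ny * nx));
        int rem = (int)(p % ((size_t)ny * nx));
        int x = rem / ny, y = rem % ny;
        double m = g[p];
        for (auto &d : off) {
          int yy = y + d[0], xx = x + d[1], zz = z + d[2];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
            continue;
          size_t q = yy + (size_t)ny * (xx + (size_t)nx * zz);
          if (g[q] < m) m = g[q];
        }
        double v = std::max(m, ref[p]);
        if (v < g[p]) {
          g[p] = v;
          changed = true;
        }
      }
    }
  }
  return g;
}

// Regional minima: connected plateaus with no lower neighbor.
// [[Rcpp::export]]
LogicalVector cpp_regional_minima(NumericVector vol, int ny, int nx, int nz,
                                  int conn) {
  size_t n = vol.size();
  LogicalVector out(n, false);
  std::vector<char> state(n, 0);  // 0 unknown, 1 visited
  std::vector<std::array<int, 3>> off;
  neighbor_offsets(conn, ny, nx, nz, off);
  std::vector<size_t> plateau, stack;
  for (size_t i = 0; i < n; ++i) {
    if (state[i]) continue;
    double v = vol[i];
    bool is_min = true;
    plateau.clear();
    stack.clear();
    stack.push_back(i);
    state[i] = 1;
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      plateau.push_back(p);
      int z = (int)(p / ((size_t)ny * nx));
      int rem = (int)(p % ((size_t)ny * nx));
      int x = rem / ny, y = rem % ny;
      for (auto &d : off) {
        int yy = y + d[0], xx = x + d[1], zz = z + d[2];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        size_t q = yy + (size_t)ny * (xx + (size_t)nx * zz);
        if (vol[q] < v) is_min = false;
        else if (vol[q] == v && !state[q]) {
          state[q] = 1;
          stack.push_back(q);
        }
      }
    }
    if (is_min)
      for (size_t p : plateau) out[p] = true;
  }
  return out;
}

// Local maxima within a (2r+1)^3 window (2D window when nz == 1), optionally
// restricted to mask and above a floor value. Plateau maxima all flagged.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector vol, int ny, int nx, int nz,
                               int r, double floor_val, LogicalVector mask) {
  size_t n = vol.size();
  LogicalVector out(n, false);
  bool use_mask = mask.size() == (R_xlen_t)n;
  int rz = nz == 1 ? 0 : r;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        size_t p = y + (size_t)ny * (x + (size_t)nx * z);
        if (use_mask && !mask[p]) continue;
        double v = vol[p];
        if (v <= floor_val) continue;
        bool is_max = true;
        for (int dz = -rz; dz <= rz && is_max; ++dz)
          for (int dx = -r; dx <= r && is_max; ++dx)
            for (int dy = -r; dy <= r && is_max; ++dy) {
              if (!dy && !dx && !dz) continue;
              int yy = y + dy, xx = x + dx, zz = z + dz;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 ||
                  zz >= nz)
                continue;
              if (vol[yy + (size_t)ny * (xx + (size_t)nx * zz)] > v)
                is_max = false;
            }
        if (is_max) out[p] = true;
      }
  return out;
}
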