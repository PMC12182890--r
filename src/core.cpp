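#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Volumes are R arrays stored [y, x, z]: linear index iy + ny*(ix + nx*iz).
// All physical spacings arrive as (sy, sx, sz) matching that order.

static inline R_xlen_t lin(int iy, int ix, int iz, int ny, int nx) {
  return (R_xlen_t)iy + (R_xlen_t)ny * ((R_xlen_t)ix + (R_xlen_t)nx * (R_xlen_t)iz);
}

static const double EDT_INF = 1e20;

// 1D squared distance transform of a sampled function (Felzenszwalb-Huttenlocher)
static void dt1d(const double* f, double* d, int* v, double* z, int n, double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF; z[1] = EDT_INF;
  for (int q = 1; q < n; q++) {
    double xq = q * w, s = 0.0;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (k > 0 && s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q; z[k] = s; z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * w;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Euclidean distance (in physical units) from every foreground voxel to the
// nearest background voxel. Background voxels get 0.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? EDT_INF : 0.0;
  int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along y
  for (int iz = 0; iz < nz; iz++)
    for (int ix = 0; ix < nx; ix++) {
      R_xlen_t base = lin(0, ix, iz, ny, nx);
      for (int iy = 0; iy < ny; iy++) f[iy] = out[base + iy];
      dt1d(f.data(), d.data(), v.data(), z.data(), ny, spacing[0]);
      for (int iy = 0; iy < ny; iy++) out[base + iy] = d[iy];
    }
  // pass along x
  for (int iz = 0; iz < nz; iz++)
    for (int iy = 0; iy < ny; iy++) {
      for (int ix = 0; ix < nx; ix++) f[ix] = out[lin(iy, ix, iz, ny, nx)];
      dt1d(f.data(), d.data(), v.data(), z.data(), nx, spacing[1]);
      for (int ix = 0; ix < nx; ix++) out[lin(iy, ix, iz, ny, nx)] = d[ix];
    }
  // pass along z
  for (int ix = 0; ix < nx; ix++)
    for (int iy = 0; iy < ny; iy++) {
      for (int iz = 0; iz < nz; iz++) f[iz] = out[lin(iy, ix, iz, ny, nx)];
      dt1d(f.data(), d.data(), v.data(), z.data(), nz, spacing[2]);
      for (int iz = 0; iz < nz; iz++) out[lin(iy, ix, iz, ny, nx)] = d[iz];
    }
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(out[i]);
  return out;
}

// Separable Gaussian blur, sigma in voxels per axis (sy, sx, sz), reflecting
// boundary. sigma <= 0 on an axis skips that axis.
// [[Rcpp::export(name = ".gauss_blur3d")]]
NumericVector gauss_blur3d(NumericVector img, IntegerVector dims, NumericVector sigma) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector cur = clone(img);
  NumericVector tmp(n);
  for (int axis = 0; axis < 3; axis++) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; i++) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + r]; }
    for (int i = 0; i <= 2 * r; i++) k[i] /= ksum;
    int len = (axis == 0) ? ny : (axis == 1) ? nx : nz;
    R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)ny : (R_xlen_t)ny * nx;
    // iterate over all lines along `axis`
    int d1 = (axis == 0) ? nx : ny;
    int d2 = (axis == 2) ? nx : nz;
    for (int b = 0; b < d2; b++)
      for (int a = 0; a < d1; a++) {
        R_xlen_t base;
        if (axis == 0)      base = lin(0, a, b, ny, nx);
        else if (axis == 1) base = lin(a, 0, b, ny, nx);
        else                base = lin(a, b, 0, ny, nx);
        for (int p = 0; p < len; p++) {
          double acc = 0;
          for (int i = -r; i <= r; i++) {
            int q = p + i;
            if (q < 0) q = -q - 1;               // reflect
            if (q >= len) q = 2 * len - q - 1;
            if (q < 0) q = 0;                    // tiny axes
            if (q >= len) q = len - 1;
            acc += k[i + r] * cur[base + (R_xlen_t)q * stride];
          }
          tmp[base + (R_xlen_t)p * stride] = acc;
        }
      }
    std::swap(cur, tmp);
  }
  return cur;
}

static int neighbor_offsets(int conn, int ny, int nx,
                            std::vector<R_xlen_t>& off,
                            std::vector<int>& dy, std::vector<int>& dx, std::vector<int>& dz) {
  off.clear(); dy.clear(); dx.clear(); dz.clear();
  for (int z = -1; z <= 1; z++)
    for (int x = -1; x <= 1; x++)
      for (int y = -1; y <= 1; y++) {
        int m = std::abs(y) + std::abs(x) + std::abs(z);
        if (m == 0) continue;
        if (conn == 6 && m != 1) continue;
        off.push_back(lin(y, x, z, ny, nx) - lin(0, 0, 0, ny, nx));
        dy.push_back(y); dx.push_back(x); dz.push_back(z);
      }
  return (int)off.size();
}

// Connected-component labelling of a boolean mask, 6- or 26-connectivity.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims, int conn) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> off; std::vector<int> dy, dx, dz;
  int m = neighbor_offsets(conn, ny, nx, off, dy, dx, dz);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int iz = (int)(cur / ((R_xlen_t)ny * nx));
      int rem = (int)(cur - (R_xlen_t)iz * ny * nx);
      int ix = rem / ny, iy = rem % ny;
      for (int j = 0; j < m; j++) {
        int yy = iy + dy[j], xx = ix + dx[j], zz = iz + dz[j];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
        R_xlen_t q = cur + off[j];
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Morphological reconstruction by dilation of `marker` under `ceiling`
// (marker <= ceiling everywhere), 26-connectivity. Vincent's hybrid algorithm.
// [[Rcpp::export(name = ".reconstruct_dilation")]]
NumericVector reconstruct_dilation(NumericVector marker, NumericVector ceiling,
                                   IntegerVector dims) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  NumericVector J = clone(marker);
  std::vector<R_xlen_t> off; std::vector<int> dy, dx, dz;
  int m = neighbor_offsets(26, ny, nx, off, dy, dx, dz);
  // raster and anti-raster scans
  for (int pass = 0; pass < 2; pass++) {
    bool fwd = (pass == 0);
    for (int iz = fwd ? 0 : nz - 1; fwd ? iz < nz : iz >= 0; iz += fwd ? 1 : -1)
      for (int ix = fwd ? 0 : nx - 1; fwd ? ix < nx : ix >= 0; ix += fwd ? 1 : -1)
        for (int iy = fwd ? 0 : ny - 1; fwd ? iy < ny : iy >= 0; iy += fwd ? 1 : -1) {
          R_xlen_t i = lin(iy, ix, iz, ny, nx);
          double best = J[i];
          for (int j = 0; j < m; j++) {
            // scan-causal neighbours only
            int ord = dz[j] * 9 + dx[j] * 3 + dy[j];
            if (fwd ? (ord >= 0) : (ord <= 0)) continue;
            int yy = iy + dy[j], xx = ix + dx[j], zz = iz + dz[j];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
            best = std::max(best, J[i + off[j]]);
          }
          J[i] = std::min(best, ceiling[i]);
        }
  }
  // queue phase
  std::queue<R_xlen_t> fifo;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  for (R_xlen_t i = 0; i < n; i++) {
    int iz = (int)(i / ((R_xlen_t)ny * nx));
    int rem = (int)(i - (R_xlen_t)iz * ny * nx);
    int ix = rem / ny, iy = rem % ny;
    for (int j = 0; j < m; j++) {
      int yy = iy + dy[j], xx = ix + dx[j], zz = iz + dz[j];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      R_xlen_t q = i + off[j];
      if (J[q] < J[i] && J[q] < ceiling[q]) { fifo.push(i); break; }
    }
  }
  while (!fifo.empty()) {
    R_xlen_t i = fifo.front(); fifo.pop();
    int iz = (int)(i / ((R_xlen_t)ny * nx));
    int rem = (int)(i - (R_xlen_t)iz * ny * nx);
    int ix = rem / ny, iy = rem % ny;
    for (int j = 0; j < m; j++) {
      int yy = iy + dy[j], xx = ix + dx[j], zz = iz + dz[j];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      R_xlen_t q = i + off[j];
      if (J[q] < J[i] && ceiling[q] != J[q]) {
        J[q] = std::min(J[i], ceiling[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

// Regional maxima (plateau-aware, 26-connectivity) of `img` restricted to mask.
// [[Rcpp::export(name = ".regional_maxima")]]
LogicalVector regional_maxima(NumericVector img, LogicalVector mask, IntegerVector dims) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<R_xlen_t> off; std::vector<int> dy, dx, dz;
  int m = neighbor_offsets(26, ny, nx, off, dy, dx, dz);
  LogicalVector out(n);
  std::vector<uint8_t> state(n, 0); // 0 unvisited, 1 in-plateau, 2 resolved
  std::vector<R_xlen_t> plateau, stack;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || state[i] != 0) continue;
    double v = img[i];
    bool is_max = true;
    plateau.clear(); stack.clear();
    stack.push_back(i); state[i] = 1; plateau.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int iz = (int)(cur / ((R_xlen_t)ny * nx));
      int rem = (int)(cur - (R_xlen_t)iz * ny * nx);
      int ix = rem / ny, iy = rem % ny;
      for (int j = 0; j < m; j++) {
        int yy = iy + dy[j], xx = ix + dx[j], zz = iz + dz[j];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
        R_xlen_t q = cur + off[j];
        if (!mask[q]) continue;
        if (img[q] > v) { is_max = false; continue; }
        if (img[q] == v && state[q] == 0) {
          state[q] = 1; plateau.push_back(q); stack.push_back(q);
        }
      }
    }
    for (R_xlen_t p : plateau) { state[p] = 2; out[p] = is_max; }
  }
  return out;
}

// Seeded watershed: flood `mask` from labelled `seeds` in order of decreasing
// `priority` (6-connectivity). Every mask voxel connected to a seed gets the
// label of the highest-priority front reaching it first; ties broken by
// insertion order (deterministic).
// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerVector watershed_seeded(NumericVector priority, IntegerVector seeds,
                               LogicalVector mask, IntegerVector dims) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> off; std::vector<int> dy, dx, dz;
  int m = neighbor_offsets(6, ny, nx, off, dy, dx, dz);
  struct Node { double pr; int64_t ord; R_xlen_t idx; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.pr != b.pr) return a.pr < b.pr;      // max-heap on priority
      return a.ord > b.ord;                      // FIFO on ties
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  int64_t ord = 0;
  for (R_xlen_t i = 0; i < n; i++)
    if (seeds[i] > 0 && mask[i]) { lab[i] = seeds[i]; pq.push({priority[i], ord++, i}); }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    R_xlen_t i = nd.idx;
    int iz = (int)(i / ((R_xlen_t)ny * nx));
    int rem = (int)(i - (R_xlen_t)iz * ny * nx);
    int ix = rem / ny, iy = rem % ny;
    for (int j = 0; j < m; j++) {
      int yy = iy + dy[j], xx = ix + dx[j], zz = iz + dz[j];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      R_xlen_t q = i + off[j];
      if (mask[q] && lab[q] == 0) {
        lab[q] = lab[i];
        pq.push({priority[q], ord++, q});
      }
    }
  }
  return lab;
}

// Rasterize spheres into an integer label grid. Centers/radii in physical µm,
// voxel center of index (iy,ix,iz) at (ix*sx, iy*sy, iz*sz). Later spheres
// never overwrite earlier labels (packing guarantees disjointness anyway).
// [[Rcpp::export(name = ".raster_spheres")]]
IntegerVector raster_spheres(IntegerVector dims, NumericVector spacing,
                             NumericMatrix centers_xyz, NumericVector radii) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  double sy = spacing[0], sx = spacing[1], sz = spacing[2];
  IntegerVector lab((R_xlen_t)ny * nx * nz);
  for (int c = 0; c < centers_xyz.nrow(); c++) {
    double cx = centers_xyz(c, 0), cy = centers_xyz(c, 1), cz = centers_xyz(c, 2);
    double r = radii[c], r2 = r * r;
    int y0 = std::max(0, (int)std::ceil((cy - r) / sy));
    int y1 = std::min(ny - 1, (int)std::floor((cy + r) / sy));
    int x0 = std::max(0, (int)std::ceil((cx - r) / sx));
    int x1 = std::min(nx - 1, (int)std::floor((cx + r) / sx));
    int z0 = std::max(0, (int)std::ceil((cz - r) / sz));
    int z1 = std::min(nz - 1, (int)std::floor((cz + r) / sz));
    for (int iz = z0; iz <= z1; iz++) {
      double ddz = iz * sz - cz;
      for (int ix = x0; ix <= x1; ix++) {
        double ddx = ix * sx - cx;
        for (int iy = y0; iy <= y1; iy++) {
          double ddy = iy * sy - cy;
          if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) {
            R_xlen_t i = lin(iy, ix, iz, ny, nx);
            if (lab[i] == 0) lab[i] = c + 1;
          }
        }
      }
    }
  }
  return lab;
}

// Per-label voxel count, centroid sums (physical µm) and bounding box
// (0-based voxel indices). Returns a K x 11 matrix:
// count, sum_x, sum_y, sum_z, y0, y1, x0, x1, z0, z1, touches_border.
// [[Rcpp::export(name = ".label_stats")]]
NumericMatrix label_stats(IntegerVector lab, IntegerVector dims, NumericVector spacing,
                          int nlab) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  double sy = spacing[0], sx = spacing[1], sz = spacing[2];
  NumericMatrix out(nlab, 11);
  for (int k = 0; k < nlab; k++) {
    out(k, 4) = ny; out(k, 5) = -1; out(k, 6) = nx; out(k, 7) = -1;
    out(k, 8) = nz; out(k, 9) = -1;
  }
  R_xlen_t i = 0;
  for (int iz = 0; iz < nz; iz++)
    for (int ix = 0; ix < nx; ix++)
      for (int iy = 0; iy < ny; iy++, i++) {
        int l = lab[i];
        if (l <= 0 || l > nlab) continue;
        int k = l - 1;
        out(k, 0) += 1;
        out(k, 1) += ix * sx;
        out(k, 2) += iy * sy;
        out(k, 3) += iz * sz;
        if (iy < out(k, 4)) out(k, 4) = iy;
        if (iy > out(k, 5)) out(k, 5) = iy;
        if (ix < out(k, 6)) out(k, 6) = ix;
        if (ix > out(k, 7)) out(k, 7) = ix;
        if (iz < out(k, 8)) out(k, 8) = iz;
        if (iz > out(k, 9)) out(k, 9) = iz;
        if (iy == 0 || iy == ny - 1 || ix == 0 || ix == nx - 1 || iz == 0 || iz == nz - 1)
          out(k, 10) = 1;
      }
  return out;
}

// Generalized squared distance transform: given per-voxel parabola offsets f
// (use a large value, e.g. 1e20, for non-sites), returns
// min_c ( ||x - c||^2 + f(c) ) in physical units.
// [[Rcpp::export(name = ".sq_dt3d")]]
NumericVector sq_dt3d(NumericVector f0, IntegerVector dims, NumericVector spacing) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out = clone(f0);
  int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int iz = 0; iz < nz; iz++)
    for (int ix = 0; ix < nx; ix++) {
      R_xlen_t base = lin(0, ix, iz, ny, nx);
      for (int iy = 0; iy < ny; iy++) f[iy] = out[base + iy];
      dt1d(f.data(), d.data(), v.data(), z.data(), ny, spacing[0]);
      for (int iy = 0; iy < ny; iy++) out[base + iy] = d[iy];
    }
  for (int iz = 0; iz < nz; iz++)
    for (int iy = 0; iy < ny; iy++) {
      for (int ix = 0; ix < nx; ix++) f[ix] = out[lin(iy, ix, iz, ny, nx)];
      dt1d(f.data(), d.data(), v.data(), z.data(), nx, spacing[1]);
      for (int ix = 0; ix < nx; ix++) out[lin(iy, ix, iz, ny, nx)] = d[ix];
    }
  for (int ix = 0; ix < nx; ix++)
    for (int iy = 0; iy < ny; iy++) {
      for (int iz = 0; iz < nz; iz++) f[iz] = out[lin(iy, ix, iz, ny, nx)];
      dt1d(f.data(), d.data(), v.data(), z.data(), nz, spacing[2]);
      for (int iz = 0; iz < nz; iz++) out[lin(iy, ix, iz, ny, nx)] = d[iz];
    }
  return out;
}
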