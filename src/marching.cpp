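#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Isosurface area by marching tetrahedra: each grid cell is split into six
// tetrahedra sharing the 0-6 cube diagonal (face diagonals consistent between
// neighbouring cells, so the surface is watertight). Vertices are linearly
// interpolated on tet edges at `level`. Returns total triangle area in
// physical units; spacing is (sy, sx, sz) matching the [y, x, z] array order.

static inline void interp_pt(double level, const double* p1, const double* p2,
                             double v1, double v2, double* out) {
  double denom = v2 - v1;
  double t = (std::fabs(denom) < 1e-300) ? 0.5 : (level - v1) / denom;
  if (t < 0) t = 0; if (t > 1) t = 1;
  for (int k = 0; k < 3; k++) out[k] = p1[k] + t * (p2[k] - p1[k]);
}

static inline double tri_area(const double* a, const double* b, const double* c) {
  double u[3], v[3];
  for (int k = 0; k < 3; k++) { u[k] = b[k] - a[k]; v[k] = c[k] - a[k]; }
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static double tet_area(double level, const double pts[4][3], const double val[4]) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; i++) { in[i] = val[i] > level; if (in[i]) nin++; }
  if (nin == 0 || nin == 4) return 0.0;
  int a[4], b[4], na = 0, nb = 0;
  for (int i = 0; i < 4; i++) { if (in[i]) a[na++] = i; else b[nb++] = i; }
  double q[4][3];
  if (nin == 1 || nin == 3) {
    int apex = (nin == 1) ? a[0] : b[0];
    int* other = (nin == 1) ? b : a;
    for (int j = 0; j < 3; j++)
      interp_pt(level, pts[apex], pts[other[j]], val[apex], val[other[j]], q[j]);
    return tri_area(q[0], q[1], q[2]);
  }
  // 2-2 case: quad ac, ad, bd, bc with a=a[0], b=a[1], c=b[0], d=b[1]
  interp_pt(level, pts[a[0]], pts[b[0]], val[a[0]], val[b[0]], q[0]);
  interp_pt(level, pts[a[0]], pts[b[1]], val[a[0]], val[b[1]], q[1]);
  interp_pt(level, pts[a[1]], pts[b[1]], val[a[1]], val[b[1]], q[2]);
  interp_pt(level, pts[a[1]], pts[b[0]], val[a[1]], val[b[0]], q[3]);
  return tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
}

// [[Rcpp::export(name = ".isosurface_area")]]
double isosurface_area(NumericVector vol, IntegerVector dims, double level,
                       NumericVector spacing) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  double sy = spacing[0], sx = spacing[1], sz = spacing[2];
  // cube corner offsets (dx, dy, dz) in Bourke order; 0-6 is the main diagonal
  static const int C[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
  };
  static const int TETS[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
  };
  double total = 0.0;
  double cval[8], cpos[8][3];
  for (int iz = 0; iz < nz - 1; iz++)
    for (int ix = 0; ix < nx - 1; ix++)
      for (int iy = 0; iy < ny - 1; iy++) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int xx = ix + C[c][0], yy = iy + C[c][1], zz = iz + C[c][2];
          double v = vol[(R_xlen_t)yy + (R_xlen_t)ny * ((R_xlen_t)xx + (R_xlen_t)nx * zz)];
          cval[c] = v;
          cpos[c][0] = xx * sx; cpos[c][1] = yy * sy; cpos[c][2] = zz * sz;
          if (v > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          double pts[4][3], val[4];
          for (int i = 0; i < 4; i++) {
            int c = TETS[t][i];
            val[i] = cval[c];
            for (int k = 0; k < 3; k++) pts[i][k] = cpos[c][k];
          }
          total += tet_area(level, pts, val);
        }
      }
  return total;
}
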