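#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable 3D Gaussian blur on an array with dim (ny, nx, nz).
// sigma_vox gives the kernel sigma per axis in voxel units; axes with
// sigma < 0.05 are skipped. Boundaries are handled by reflection.
static void blur_axis(std::vector<double> &v, int ny, int nx, int nz,
                      int axis, double sigma) {
  if (sigma < 0.05) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &w : k) w /= s;

  int n[3] = {ny, nx, nz};
  long stride[3] = {1, (long)ny, (long)ny * nx};
  int len = n[axis];
  long st = stride[axis];
  std::vector<double> line(len);

  // iterate over all lines along `axis`
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  for (int j2 = 0; j2 < n[a2]; ++j2) {
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      long base = (long)j1 * stride[a1] + (long)j2 * stride[a2];
      for (int i = 0; i < len; ++i) line[i] = v[base + i * st];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int d = -r; d <= r; ++d) {
          int idx = i + d;
          if (idx < 0) idx = -idx - 1;           // reflect
          if (idx >= len) idx = 2 * len - idx - 1;
          if (idx < 0) idx = 0;                  // very short lines
          if (idx >= len) idx = len - 1;
          acc += k[d + r] * line[idx];
        }
        v[base + i * st] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector blur3d_cpp(NumericVector vol, IntegerVector dims,
                         NumericVector sigma_vox) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, ny, nx, nz, 0, sigma_vox[0]);
  blur_axis(v, ny, nx, nz, 1, sigma_vox[1]);
  blur_axis(v, ny, nx, nz, 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// 3D connected-component labeling of a logical mask, 6- or 26-connectivity.
// Returns integer labels (0 = background), dim (ny, nx, nz).
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  long n = (long)ny * nx * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;

  std::vector<long> offs;
  std::vector<int> doy, dox, doz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manhattan = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        doy.push_back(dy); dox.push_back(dx); doz.push_back(dz);
        offs.push_back((long)dy + (long)dx * ny + (long)dz * ny * nx);
      }
  int nn = (int)offs.size();

  std::vector<long> stack;
  int cur = 0;
  for (long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      long p = stack.back();
      stack.pop_back();
      int py = (int)(p % ny);
      int px = (int)((p / ny) % nx);
      int pz = (int)(p / ((long)ny * nx));
      for (int q = 0; q < nn; ++q) {
        int yy = py + doy[q], xx = px + dox[q], zz = pz + doz[q];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        long pp = p + offs[q];
        if (mask[pp] && lab[pp] == 0) {
          lab[pp] = cur;
          stack.push_back(pp);
        }
      }
    }
  }
  return lab;
}

// Trilinear interpolation of a (ny, nx, nz) array at physical points.
// pts is an m x 3 matrix of (y, x, z) in voxel-index units (1-based,
// voxel centers at integers, matching R indexing).
// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  int m = pts.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double y = pts(i, 0) - 1.0, x = pts(i, 1) - 1.0, z = pts(i, 2) - 1.0;
    // clamp to the valid interpolation domain
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int y0 = (int)std::floor(y), x0 = (int)std::floor(x), z0 = (int)std::floor(z);
    int y1 = std::min(y0 + 1, ny - 1), x1 = std::min(x0 + 1, nx - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double fy = y - y0, fx = x - x0, fz = z - z0;
    auto at = [&](int yy, int xx, int zz) {
      return vol[(long)yy + (long)xx * ny + (long)zz * ny * nx];
    };
    double c00 = at(y0, x0, z0) * (1 - fy) + at(y1, x0, z0) * fy;
    double c10 = at(y0, x1, z0) * (1 - fy) + at(y1, x1, z0) * fy;
    double c01 = at(y0, x0, z1) * (1 - fy) + at(y1, x0, z1) * fy;
    double c11 = at(y0, x1, z1) * (1 - fy) + at(y1, x1, z1) * fy;
    double c0 = c00 * (1 - fx) + c10 * fx;
    double c1 = c01 * (1 - fx) + c11 * fx;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Surface area of the `level` isosurface of a (ny, nx, nz) scalar field
// with anisotropic voxel spacing, by marching tetrahedra: each cell is
// split into 6 tetrahedra sharing the main diagonal; the linear
// interpolant's level set within each tetrahedron is one or two
// triangles whose areas are accumulated.
// [[Rcpp::export]]
double isosurface_area_cpp(NumericVector vol, IntegerVector dims,
                           NumericVector spacing, double level) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  double sy = spacing[0], sx = spacing[1], sz = spacing[2];
  auto at = [&](int y, int x, int z) {
    return vol[(long)y + (long)x * ny + (long)z * ny * nx];
  };
  // cube corner offsets (y, x, z)
  static const int co[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // 6 tetrahedra around the 0-7 diagonal
  static const int tets[6][4] = {
    {0,5,1,7},{0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7}};

  double area = 0.0;
  double P[8][3], F[8];
  for (int z = 0; z < nz - 1; ++z)
    for (int x = 0; x < nx - 1; ++x)
      for (int y = 0; y < ny - 1; ++y) {
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          F[c] = at(y + co[c][0], x + co[c][1], z + co[c][2]);
          P[c][0] = (y + co[c][0]) * sy;
          P[c][1] = (x + co[c][1]) * sx;
          P[c][2] = (z + co[c][2]) * sz;
          if (F[c] > level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int hi[4], nhi = 0, lo[4], nlo = 0;
          for (int v = 0; v < 4; ++v) {
            if (F[T[v]] > level) hi[nhi++] = T[v];
            else lo[nlo++] = T[v];
          }
          if (nhi == 0 || nhi == 4) continue;
          auto interp = [&](int a, int b, double *out) {
            double tt = (level - F[a]) / (F[b] - F[a]);
            for (int d = 0; d < 3; ++d)
              out[d] = P[a][d] + tt * (P[b][d] - P[a][d]);
          };
          auto tri_area = [](double *a, double *b, double *c) {
            double u[3], v[3], w[3];
            for (int d = 0; d < 3; ++d) { u[d] = b[d] - a[d]; v[d] = c[d] - a[d]; }
            w[0] = u[1] * v[2] - u[2] * v[1];
            w[1] = u[2] * v[0] - u[0] * v[2];
            w[2] = u[0] * v[1] - u[1] * v[0];
            return 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
          };
          double q[4][3];
          if (nhi == 1 || nhi == 3) {
            int apex = (nhi == 1) ? hi[0] : lo[0];
            int *others = (nhi == 1) ? lo : hi;
            for (int v = 0; v < 3; ++v) interp(apex, others[v], q[v]);
            area += tri_area(q[0], q[1], q[2]);
          } else { // 2-2: quad split into two triangles
            interp(hi[0], lo[0], q[0]);
            interp(hi[0], lo[1], q[1]);
            interp(hi[1], lo[1], q[2]);
            interp(hi[1], lo[0], q[3]);
            area += tri_area(q[0], q[1], q[2]);
            area += tri_area(q[0], q[2], q[3]);
          }
        }
      }
  return area;
}
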