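// Low-level array kernels for 3D volumes.
// Conventions: volumes are column-major arrays of dim (nx,ny,nz);
// voxel coordinates are 0-based; displacement fields are N x 3 matrices
// in *voxel units* of the grid they live on (R wrappers convert mm).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double sample_clamp(const double* vol, int nx, int ny, int nz,
                                  double x, double y, double z) {
  // trilinear with edge clamp
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = clampi(x0 + 1, 0, nx - 1), y1 = clampi(y0 + 1, 0, ny - 1), z1 = clampi(z0 + 1, 0, nz - 1);
  x0 = clampi(x0, 0, nx - 1); y0 = clampi(y0, 0, ny - 1); z0 = clampi(z0, 0, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  size_t sxy = (size_t)nx * ny;
  #define V(i,j,k) vol[(size_t)(i) + (size_t)nx*(j) + sxy*(k)]
  double c00 = V(x0,y0,z0)*(1-fx) + V(x1,y0,z0)*fx;
  double c10 = V(x0,y1,z0)*(1-fx) + V(x1,y1,z0)*fx;
  double c01 = V(x0,y0,z1)*(1-fx) + V(x1,y0,z1)*fx;
  double c11 = V(x0,y1,z1)*(1-fx) + V(x1,y1,z1)*fx;
  #undef V
  double c0 = c00*(1-fy) + c10*fy;
  double c1 = c01*(1-fy) + c11*fy;
  return c0*(1-fz) + c1*fz;
}

// [[Rcpp::export]]
NumericVector cpp_interp_at_points(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts, double background,
                                   bool clamp_border) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int i = 0; i < n; ++i) {
    double x = pts(i,0), y = pts(i,1), z = pts(i,2);
    if (!clamp_border && (x < 0 || y < 0 || z < 0 ||
                          x > nx - 1 || y > ny - 1 || z > nz - 1)) {
      out[i] = background;
    } else {
      out[i] = sample_clamp(v, nx, ny, nz, x, y, z);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_warp_by_field(NumericVector vol, IntegerVector dim,
                                NumericMatrix field, double background,
                                bool clamp_border) {
  // out(x) = vol(x + u(x)); pull-back convention
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)n);
  const double* v = vol.begin();
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double px = x + field(i,0), py = y + field(i,1), pz = z + field(i,2);
        if (!clamp_border && (px < 0 || py < 0 || pz < 0 ||
                              px > nx - 1 || py > ny - 1 || pz > nz - 1)) {
          out[i] = background;
        } else {
          out[i] = sample_clamp(v, nx, ny, nz, px, py, pz);
        }
      }
  return out;
}

static void smooth_axis(std::vector<double>& a, std::vector<double>& tmp,
                        int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (auto& w : k) w /= s;
  size_t sxy = (size_t)nx * ny;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nx : sxy);
  // iterate over all lines along `axis`
  for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
    for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
      for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
        size_t base = (size_t)x + (size_t)nx * y + sxy * z;
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int j = -r; j <= r; ++j) {
            int idx = i + j;
            // reflect
            if (idx < 0) idx = -idx - 1;
            if (idx >= len) idx = 2 * len - idx - 1;
            if (idx < 0) idx = 0; if (idx >= len) idx = len - 1;
            acc += k[j + r] * a[base + stride * idx];
          }
          tmp[i] = acc;
        }
        for (int i = 0; i < len; ++i) a[base + stride * i] = tmp[i];
      }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> tmp((size_t)std::max(nx, std::max(ny, nz)));
  smooth_axis(a, tmp, nx, ny, nz, 0, sigma[0]);
  smooth_axis(a, tmp, nx, ny, nz, 1, sigma[1]);
  smooth_axis(a, tmp, nx, ny, nz, 2, sigma[2]);
  NumericVector out(vol.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gradient(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sxy = (size_t)nx * ny, n = sxy * nz;
  NumericMatrix g((R_xlen_t)n, 3);
  const double* v = vol.begin();
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        int xp = clampi(x + 1, 0, nx - 1), xm = clampi(x - 1, 0, nx - 1);
        int yp = clampi(y + 1, 0, ny - 1), ym = clampi(y - 1, 0, ny - 1);
        int zp = clampi(z + 1, 0, nz - 1), zm = clampi(z - 1, 0, nz - 1);
        g(i,0) = 0.5 * (v[(size_t)xp + (size_t)nx*y + sxy*z] - v[(size_t)xm + (size_t)nx*y + sxy*z]);
        g(i,1) = 0.5 * (v[(size_t)x + (size_t)nx*yp + sxy*z] - v[(size_t)x + (size_t)nx*ym + sxy*z]);
        g(i,2) = 0.5 * (v[(size_t)x + (size_t)nx*y + sxy*zp] - v[(size_t)x + (size_t)nx*y + sxy*zm]);
      }
  return g;
}

// Felzenszwalb & Huttenlocher 1D lower-envelope squared distance transform
static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& zbuf,
                   int n, double w2) {
  // w2 = squared spacing along this axis
  int k = 0;
  v[0] = 0;
  zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector mask, IntegerVector dim,
                         NumericVector spacing) {
  // squared Euclidean distance (in spacing units) to nearest mask>0 voxel
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sxy = (size_t)nx * ny, n = sxy * nz;
  const double BIG = 1e30;
  std::vector<double> d(n);
  for (size_t i = 0; i < n; ++i) d[i] = mask[i] > 0 ? 0.0 : BIG;
  int maxn = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxn), dd(maxn), zbuf(maxn + 1);
  std::vector<int> v(maxn);
  // x axis
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nx * y + sxy * z;
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      edt_1d(f, dd, v, zbuf, nx, spacing[0] * spacing[0]);
      for (int x = 0; x < nx; ++x) d[base + x] = dd[x];
    }
  // y axis
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)x + sxy * z;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (size_t)nx * y];
      edt_1d(f, dd, v, zbuf, ny, spacing[1] * spacing[1]);
      for (int y = 0; y < ny; ++y) d[base + (size_t)nx * y] = dd[y];
    }
  // z axis
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)x + (size_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = d[base + sxy * z];
      edt_1d(f, dd, v, zbuf, nz, spacing[2] * spacing[2]);
      for (int z = 0; z < nz; ++z) d[base + sxy * z] = dd[z];
    }
  NumericVector out((R_xlen_t)n);
  std::copy(d.begin(), d.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

static inline void sample_field(const NumericMatrix& field, int nx, int ny, int nz,
                                double x, double y, double z, double* out3) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = clampi(x0 + 1, 0, nx - 1), y1 = clampi(y0 + 1, 0, ny - 1), z1 = clampi(z0 + 1, 0, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  size_t sxy = (size_t)nx * ny;
  size_t i000 = (size_t)x0 + (size_t)nx*y0 + sxy*z0;
  size_t i100 = (size_t)x1 + (size_t)nx*y0 + sxy*z0;
  size_t i010 = (size_t)x0 + (size_t)nx*y1 + sxy*z0;
  size_t i110 = (size_t)x1 + (size_t)nx*y1 + sxy*z0;
  size_t i001 = (size_t)x0 + (size_t)nx*y0 + sxy*z1;
  size_t i101 = (size_t)x1 + (size_t)nx*y0 + sxy*z1;
  size_t i011 = (size_t)x0 + (size_t)nx*y1 + sxy*z1;
  size_t i111 = (size_t)x1 + (size_t)nx*y1 + sxy*z1;
  double w000 = (1-fx)*(1-fy)*(1-fz), w100 = fx*(1-fy)*(1-fz);
  double w010 = (1-fx)*fy*(1-fz),     w110 = fx*fy*(1-fz);
  double w001 = (1-fx)*(1-fy)*fz,     w101 = fx*(1-fy)*fz;
  double w011 = (1-fx)*fy*fz,         w111 = fx*fy*fz;
  for (int c = 0; c < 3; ++c) {
    out3[c] = w000*field(i000,c) + w100*field(i100,c) + w010*field(i010,c) +
              w110*field(i110,c) + w001*field(i001,c) + w101*field(i101,c) +
              w011*field(i011,c) + w111*field(i111,c);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_invert_field(NumericMatrix field, IntegerVector dim,
                               int n_iter) {
  // fixed-point: v(x) = -u(x + v(x))
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericMatrix v((R_xlen_t)n, 3);
  double u3[3];
  for (int it = 0; it < n_iter; ++it) {
    size_t i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++i) {
          sample_field(field, nx, ny, nz,
                       x + v(i,0), y + v(i,1), z + v(i,2), u3);
          v(i,0) = -u3[0]; v(i,1) = -u3[1]; v(i,2) = -u3[2];
        }
  }
  return v;
}

// [[Rcpp::export]]
NumericMatrix cpp_compose_fields(NumericMatrix u, NumericMatrix v,
                                 IntegerVector dim) {
  // w = v + u(x + v(x)) : the displacement of (id+u) o (id+v)
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericMatrix w((R_xlen_t)n, 3);
  double u3[3];
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        sample_field(u, nx, ny, nz, x + v(i,0), y + v(i,1), z + v(i,2), u3);
        w(i,0) = v(i,0) + u3[0];
        w(i,1) = v(i,1) + u3[1];
        w(i,2) = v(i,2) + u3[2];
      }
  return w;
}

// [[Rcpp::export]]
NumericMatrix cpp_field_at_points(NumericMatrix field, IntegerVector dim,
                                  NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double u3[3];
  for (int i = 0; i < n; ++i) {
    sample_field(field, nx, ny, nz, pts(i,0), pts(i,1), pts(i,2), u3);
    out(i,0) = u3[0]; out(i,1) = u3[1]; out(i,2) = u3[2];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_warp_labels(IntegerVector labels, IntegerVector dim,
                              NumericMatrix field, int n_labels) {
  // per-label indicator trilinear interpolation then argmax;
  // ties -> background, then lowest label index; outside -> background
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sxy = (size_t)nx * ny, n = sxy * nz;
  IntegerVector out((R_xlen_t)n);
  std::vector<double> acc(n_labels + 1);
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double px = x + field(i,0), py = y + field(i,1), pz = z + field(i,2);
        if (px < 0 || py < 0 || pz < 0 ||
            px > nx - 1 || py > ny - 1 || pz > nz - 1) { out[i] = 0; continue; }
        int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
        int x1 = clampi(x0+1,0,nx-1), y1 = clampi(y0+1,0,ny-1), z1 = clampi(z0+1,0,nz-1);
        x0 = clampi(x0,0,nx-1); y0 = clampi(y0,0,ny-1); z0 = clampi(z0,0,nz-1);
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        std::fill(acc.begin(), acc.end(), 0.0);
        const int cx[2] = {x0, x1}; const double wx[2] = {1-fx, fx};
        const int cy[2] = {y0, y1}; const double wy[2] = {1-fy, fy};
        const int cz[2] = {z0, z1}; const double wz[2] = {1-fz, fz};
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b)
            for (int c = 0; c < 2; ++c) {
              double w = wx[a]*wy[b]*wz[c];
              if (w <= 0) continue;
              int lab = labels[(size_t)cx[a] + (size_t)nx*cy[b] + sxy*cz[c]];
              if (lab >= 0 && lab <= n_labels) acc[lab] += w;
            }
        int best = 0; double bw = acc[0];
        for (int l = 1; l <= n_labels; ++l) {
          if (acc[l] > bw + 1e-12) { best = l; bw = acc[l]; }
        }
        out[i] = best;
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
List cpp_downsample2(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = (nx + 1) / 2, my = (ny + 1) / 2, mz = (nz + 1) / 2;
  NumericVector out((R_xlen_t)mx * my * mz);
  size_t sxy = (size_t)nx * ny;
  size_t o = 0;
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x, ++o) {
        double s = 0; int cnt = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              int xx = 2*x+dx, yy = 2*y+dy, zz = 2*z+dz;
              if (xx < nx && yy < ny && zz < nz) {
                s += vol[(size_t)xx + (size_t)nx*yy + sxy*zz]; ++cnt;
              }
            }
        out[o] = s / cnt;
      }
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return List::create(_["data"] = out,
                      _["dim"] = IntegerVector::create(mx, my, mz));
}

// [[Rcpp::export]]
NumericMatrix cpp_resample_field(NumericMatrix field, IntegerVector dim_in,
                                 IntegerVector dim_out, double value_scale) {
  // resample each component onto dim_out, aligning voxel centers of the
  // block-mean pyramid: coarse = (fine + 0.5) * (nIn/nOut) - 0.5
  int nxo = dim_out[0], nyo = dim_out[1], nzo = dim_out[2];
  int nxi = dim_in[0], nyi = dim_in[1], nzi = dim_in[2];
  double rx = (double)nxi / nxo, ry = (double)nyi / nyo, rz = (double)nzi / nzo;
  size_t n = (size_t)nxo * nyo * nzo;
  NumericMatrix out((R_xlen_t)n, 3);
  double u3[3];
  size_t i = 0;
  for (int z = 0; z < nzo; ++z)
    for (int y = 0; y < nyo; ++y)
      for (int x = 0; x < nxo; ++x, ++i) {
        double px = (x + 0.5) * rx - 0.5;
        double py = (y + 0.5) * ry - 0.5;
        double pz = (z + 0.5) * rz - 0.5;
        sample_field(field, nxi, nyi, nzi, px, py, pz, u3);
        out(i,0) = u3[0] * value_scale;
        out(i,1) = u3[1] * value_scale;
        out(i,2) = u3[2] * value_scale;
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericMatrix field, IntegerVector dim) {
  // determinant of Jacobian of (id + u), central differences
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sxy = (size_t)nx * ny, n = sxy * nz;
  NumericVector out((R_xlen_t)n);
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        int xp = clampi(x+1,0,nx-1), xm = clampi(x-1,0,nx-1);
        int yp = clampi(y+1,0,ny-1), ym = clampi(y-1,0,ny-1);
        int zp = clampi(z+1,0,nz-1), zm = clampi(z-1,0,nz-1);
        double hx = 0.5 * (xp - xm); if (hx == 0) hx = 1;
        double hy = 0.5 * (yp - ym); if (hy == 0) hy = 1;
        double hz = 0.5 * (zp - zm); if (hz == 0) hz = 1;
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          size_t ixp = (size_t)xp + (size_t)nx*y + sxy*z, ixm = (size_t)xm + (size_t)nx*y + sxy*z;
          size_t iyp = (size_t)x + (size_t)nx*yp + sxy*z, iym = (size_t)x + (size_t)nx*ym + sxy*z;
          size_t izp = (size_t)x + (size_t)nx*y + sxy*zp, izm = (size_t)x + (size_t)nx*y + sxy*zm;
          J[c][0] = (field(ixp,c) - field(ixm,c)) / (2.0*hx);
          J[c][1] = (field(iyp,c) - field(iym,c)) / (2.0*hy);
          J[c][2] = (field(izp,c) - field(izm,c)) / (2.0*hz);
        }
        J[0][0] += 1; J[1][1] += 1; J[2][2] += 1;
        out[i] = J[0][0]*(J[1][1]*J[2][2]-J[1][2]*J[2][1])
               - J[0][1]*(J[1][0]*J[2][2]-J[1][2]*J[2][0])
               + J[0][2]*(J[1][0]*J[2][1]-J[1][1]*J[2][0]);
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
List cpp_demons_level(NumericVector fixed, NumericVector moving,
                      IntegerVector dim, NumericMatrix u0, int n_iter,
                      double sig_update, double sig_field,
                      double max_step, double tol) {
  // symmetric-force demons at one pyramid level; returns the best field
  // (lowest MSE) and the MSE trace
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double* f = fixed.begin();
  const double* m = moving.begin();
  std::vector<double> u1(n), u2(n), u3(n);
  for (size_t i = 0; i < n; ++i) {
    u1[i] = u0(i,0); u2[i] = u0(i,1); u3[i] = u0(i,2);
  }
  // fixed-image gradient, computed once
  std::vector<double> gfx(n), gfy(n), gfz(n);
  {
    size_t sxy = (size_t)nx * ny, i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++i) {
          int xp = clampi(x+1,0,nx-1), xm = clampi(x-1,0,nx-1);
          int yp = clampi(y+1,0,ny-1), ym = clampi(y-1,0,ny-1);
          int zp = clampi(z+1,0,nz-1), zm = clampi(z-1,0,nz-1);
          gfx[i] = 0.5*(f[(size_t)xp+(size_t)nx*y+sxy*z]-f[(size_t)xm+(size_t)nx*y+sxy*z]);
          gfy[i] = 0.5*(f[(size_t)x+(size_t)nx*yp+sxy*z]-f[(size_t)x+(size_t)nx*ym+sxy*z]);
          gfz[i] = 0.5*(f[(size_t)x+(size_t)nx*y+sxy*zp]-f[(size_t)x+(size_t)nx*y+sxy*zm]);
        }
  }
  std::vector<double> w(n), ux(n), uy(n), uz(n);
  std::vector<double> b1(u1), b2(u2), b3(u3);
  std::vector<double> tmp((size_t)std::max(nx, std::max(ny, nz)));
  std::vector<double> metric;
  double best = std::numeric_limits<double>::infinity();
  int stall = 0;
  size_t sxy = (size_t)nx * ny;
  for (int it = 0; it < n_iter; ++it) {
    // warp moving by current field
    double mse = 0;
    size_t i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++i)
          w[i] = sample_clamp(m, nx, ny, nz, x+u1[i], y+u2[i], z+u3[i]);
    // symmetric demons force
    i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++i) {
          int xp = clampi(x+1,0,nx-1), xm = clampi(x-1,0,nx-1);
          int yp = clampi(y+1,0,ny-1), ym = clampi(y-1,0,ny-1);
          int zp = clampi(z+1,0,nz-1), zm = clampi(z-1,0,nz-1);
          double gx = 0.25*(w[(size_t)xp+(size_t)nx*y+sxy*z]-w[(size_t)xm+(size_t)nx*y+sxy*z]) + 0.5*gfx[i];
          double gy = 0.25*(w[(size_t)x+(size_t)nx*yp+sxy*z]-w[(size_t)x+(size_t)nx*ym+sxy*z]) + 0.5*gfy[i];
          double gz = 0.25*(w[(size_t)x+(size_t)nx*y+sxy*zp]-w[(size_t)x+(size_t)nx*y+sxy*zm]) + 0.5*gfz[i];
          double diff = w[i] - f[i];
          mse += diff * diff;
          double g2 = gx*gx + gy*gy + gz*gz;
          double denom = g2 + diff*diff;
          double s = denom > 1e-9 ? -diff / denom : 0.0;
          double vx = gx*s, vy = gy*s, vz = gz*s;
          double mag2 = vx*vx + vy*vy + vz*vz;
          if (mag2 > max_step*max_step) {
            double sc = max_step / std::sqrt(mag2);
            vx *= sc; vy *= sc; vz *= sc;
          }
          ux[i] = vx; uy[i] = vy; uz[i] = vz;
        }
    mse /= n;
    if (!std::isfinite(mse)) stop("demons: non-finite metric");
    metric.push_back(mse);
    if (sig_update > 0) {
      smooth_axis(ux, tmp, nx, ny, nz, 0, sig_update);
      smooth_axis(ux, tmp, nx, ny, nz, 1, sig_update);
      smooth_axis(ux, tmp, nx, ny, nz, 2, sig_update);
      smooth_axis(uy, tmp, nx, ny, nz, 0, sig_update);
      smooth_axis(uy, tmp, nx, ny, nz, 1, sig_update);
      smooth_axis(uy, tmp, nx, ny, nz, 2, sig_update);
      smooth_axis(uz, tmp, nx, ny, nz, 0, sig_update);
      smooth_axis(uz, tmp, nx, ny, nz, 1, sig_update);
      smooth_axis(uz, tmp, nx, ny, nz, 2, sig_update);
    }
    for (size_t j = 0; j < n; ++j) { u1[j] += ux[j]; u2[j] += uy[j]; u3[j] += uz[j]; }
    if (sig_field > 0) {
      smooth_axis(u1, tmp, nx, ny, nz, 0, sig_field);
      smooth_axis(u1, tmp, nx, ny, nz, 1, sig_field);
      smooth_axis(u1, tmp, nx, ny, nz, 2, sig_field);
      smooth_axis(u2, tmp, nx, ny, nz, 0, sig_field);
      smooth_axis(u2, tmp, nx, ny, nz, 1, sig_field);
      smooth_axis(u2, tmp, nx, ny, nz, 2, sig_field);
      smooth_axis(u3, tmp, nx, ny, nz, 0, sig_field);
      smooth_axis(u3, tmp, nx, ny, nz, 1, sig_field);
      smooth_axis(u3, tmp, nx, ny, nz, 2, sig_field);
    }
    if (mse < best - 1e-15) {
      best = mse; b1 = u1; b2 = u2; b3 = u3; stall = 0;
    } else ++stall;
    int nm = metric.size();
    if (nm > 5 && std::fabs(metric[nm-1] - metric[nm-6]) <
        tol * std::max(metric[nm-1], 1e-12)) break;
    if (stall >= 10) break;
  }
  NumericMatrix u((R_xlen_t)n, 3);
  for (size_t j = 0; j < n; ++j) { u(j,0) = b1[j]; u(j,1) = b2[j]; u(j,2) = b3[j]; }
  return List::create(_["u"] = u, _["metric"] = wrap(metric));
}
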