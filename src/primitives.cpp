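#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// 3D image primitives shared by the resampling, distance-map and demons code.
// All arrays are column-major (R layout), voxel indices are 0-based here;
// the R wrappers translate to the package's 1-based convention.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// --- 1D squared distance transform (Felzenszwalb & Huttenlocher) ----------
// f: input squared distances at sample points spaced `step` apart.
static void dt1d(const double *f, double *d, int n, double step,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
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
    double dq = (q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from every voxel to the nearest voxel where
// mask != 0, honouring anisotropic spacing (mm). Voxels with no seed at all
// return Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(const IntegerVector mask, const IntegerVector dims,
                         const NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel: Inf would give Inf - Inf = NaN in dt1d on scan
  // lines without any seed
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] != 0 ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double *col = &out[(R_xlen_t)j * nx + (R_xlen_t)k * nx * ny];
      for (int i = 0; i < nx; ++i) f[i] = col[i];
      dt1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) col[i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) out[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = out[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) out[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny] = d[k];
    }
  return out;
}

// --- separable Gaussian smoothing -----------------------------------------
static void gauss1d_axis(std::vector<double> &buf, const double *src,
                         double *dst, int n, const std::vector<double> &ker) {
  const int r = (int)(ker.size() / 2);
  for (int q = 0; q < n; ++q) {
    double acc = 0.0;
    for (int t = -r; t <= r; ++t) {
      int p = clampi(q + t, 0, n - 1); // replicate boundary
      acc += src[p] * ker[t + r];
    }
    dst[q] = acc;
  }
  (void)buf;
}

static std::vector<double> make_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * (t / sigma) * (t / sigma));
    s += k[t + r];
  }
  for (auto &x : k) x /= s;
  return k;
}

// Gaussian smoothing with per-axis sigma in voxel units; sigma <= 0 skips
// that axis. Replicate (edge-clamp) boundary handling.
// [[Rcpp::export]]
NumericVector cpp_gauss3(const NumericVector arr, const IntegerVector dims,
                         const NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(arr);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), res(nmax), buf;

  if (sigma[0] > 0) {
    auto ker = make_kernel(sigma[0]);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        double *col = &out[(R_xlen_t)j * nx + (R_xlen_t)k * nx * ny];
        for (int i = 0; i < nx; ++i) line[i] = col[i];
        gauss1d_axis(buf, line.data(), res.data(), nx, ker);
        for (int i = 0; i < nx; ++i) col[i] = res[i];
      }
  }
  if (sigma[1] > 0) {
    auto ker = make_kernel(sigma[1]);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) line[j] = out[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny];
        gauss1d_axis(buf, line.data(), res.data(), ny, ker);
        for (int j = 0; j < ny; ++j) out[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny] = res[j];
      }
  }
  if (sigma[2] > 0) {
    auto ker = make_kernel(sigma[2]);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) line[k] = out[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny];
        gauss1d_axis(buf, line.data(), res.data(), nz, ker);
        for (int k = 0; k < nz; ++k) out[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny] = res[k];
      }
  }
  (void)n;
  return out;
}

// --- interpolation ---------------------------------------------------------
static inline double sample_one(const double *a, int nx, int ny, int nz,
                                double x, double y, double z, bool linear,
                                bool clamp, double fill) {
  if (clamp) {
    x = x < 0 ? 0 : (x > nx - 1 ? nx - 1 : x);
    y = y < 0 ? 0 : (y > ny - 1 ? ny - 1 : y);
    z = z < 0 ? 0 : (z > nz - 1 ? nz - 1 : z);
  } else if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    return fill;
  }
  if (!linear) {
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    i = clampi(i, 0, nx - 1); j = clampi(j, 0, ny - 1); k = clampi(k, 0, nz - 1);
    return a[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny];
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  i0 = clampi(i0, 0, nx - 2); j0 = clampi(j0, 0, ny - 2); k0 = clampi(k0, 0, nz - 2);
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  fx = fx < 0 ? 0 : (fx > 1 ? 1 : fx);
  fy = fy < 0 ? 0 : (fy > 1 ? 1 : fy);
  fz = fz < 0 ? 0 : (fz > 1 ? 1 : fz);
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
  #define A(I, J, K) a[(I) + (R_xlen_t)(J) * nx + (R_xlen_t)(K) * nx * ny]
  double c00 = A(i0, j0, k0) * (1 - fx) + A(i1, j0, k0) * fx;
  double c10 = A(i0, j1, k0) * (1 - fx) + A(i1, j1, k0) * fx;
  double c01 = A(i0, j0, k1) * (1 - fx) + A(i1, j0, k1) * fx;
  double c11 = A(i0, j1, k1) * (1 - fx) + A(i1, j1, k1) * fx;
  #undef A
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Sample `arr` at continuous 0-based voxel coordinates (rows of `coords`).
// [[Rcpp::export]]
NumericVector cpp_sample3(const NumericVector arr, const IntegerVector dims,
                          const NumericMatrix coords, bool linear, bool clamp,
                          double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t m = coords.nrow();
  NumericVector out(m);
  const double *a = &arr[0];
  for (R_xlen_t q = 0; q < m; ++q)
    out[q] = sample_one(a, nx, ny, nz, coords(q, 0), coords(q, 1), coords(q, 2),
                        linear, clamp, fill);
  return out;
}

// Warp an image by a dense displacement field in voxel units:
// out(x) = arr(x + d(x)).
// [[Rcpp::export]]
NumericVector cpp_warp3(const NumericVector arr, const IntegerVector dims,
                        const NumericVector dx, const NumericVector dy,
                        const NumericVector dz, bool linear, bool clamp,
                        double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double *a = &arr[0];
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q)
        out[q] = sample_one(a, nx, ny, nz, i + dx[q], j + dy[q], k + dz[q],
                            linear, clamp, fill);
  return out;
}

// Compose displacement fields (voxel units): result of applying phi2 then
// phi1, i.e. out(x) = d2(x) + d1(x + d2(x)).
// [[Rcpp::export]]
List cpp_compose_field(const NumericVector d1x, const NumericVector d1y,
                       const NumericVector d1z, const NumericVector d2x,
                       const NumericVector d2y, const NumericVector d2z,
                       const IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector ox(n), oy(n), oz(n);
  const double *ax = &d1x[0], *ay = &d1y[0], *az = &d1z[0];
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        double x = i + d2x[q], y = j + d2y[q], z = k + d2z[q];
        ox[q] = d2x[q] + sample_one(ax, nx, ny, nz, x, y, z, true, true, 0.0);
        oy[q] = d2y[q] + sample_one(ay, nx, ny, nz, x, y, z, true, true, 0.0);
        oz[q] = d2z[q] + sample_one(az, nx, ny, nz, x, y, z, true, true, 0.0);
      }
  return List::create(ox, oy, oz);
}

// Exponentiate a stationary velocity field by scaling and squaring, giving
// the displacement of exp(v). Velocity and displacement are in voxel units.
// [[Rcpp::export]]
List cpp_exp_field(const NumericVector vx, const NumericVector vy,
                   const NumericVector vz, const IntegerVector dims,
                   int nsteps) {
  const R_xlen_t n = vx.size();
  const double s = std::pow(2.0, -nsteps);
  NumericVector dx(n), dy(n), dz(n);
  for (R_xlen_t q = 0; q < n; ++q) {
    dx[q] = vx[q] * s; dy[q] = vy[q] * s; dz[q] = vz[q] * s;
  }
  for (int it = 0; it < nsteps; ++it) {
    List r = cpp_compose_field(dx, dy, dz, dx, dy, dz, dims);
    dx = r[0]; dy = r[1]; dz = r[2];
  }
  return List::create(dx, dy, dz);
}

// Central-difference gradient divided by spacing (mm^-1 units when arr is
// dimensionless); one-sided at the borders.
// [[Rcpp::export]]
List cpp_grad3(const NumericVector arr, const IntegerVector dims,
               const NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector gx(n), gy(n), gz(n);
  const double *a = &arr[0];
  #define A(I, J, K) a[(I) + (R_xlen_t)(J) * nx + (R_xlen_t)(K) * nx * ny]
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        gx[q] = (A(ip, j, k) - A(im, j, k)) / ((ip - im) * spacing[0]);
        gy[q] = (A(i, jp, k) - A(i, jm, k)) / ((jp - jm) * spacing[1]);
        gz[q] = (A(i, j, kp) - A(i, j, km)) / ((kp - km) * spacing[2]);
      }
  #undef A
  return List::create(gx, gy, gz);
}
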