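// Low-level array kernels for 3D image volumes and displacement fields.
// All arrays are R column-major; voxel coordinates are 0-based.
// Displacement fields are 4D arrays [nx, ny, nz, 3] holding world-mm
// displacements sampled on the fixed grid; `spacing` converts mm -> voxels.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear sample of vol at continuous voxel coords (x,y,z).
// mode 0: outside -> fill; mode 1: clamp to edge.
static double sample_linear(const double* v, int nx, int ny, int nz,
                            double x, double y, double z, int mode, double fill) {
  if (mode == 1) {
    x = clampd(x, 0.0, nx - 1.0);
    y = clampd(y, 0.0, ny - 1.0);
    z = clampd(z, 0.0, nz - 1.0);
  } else if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    return fill;
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  i0 = i0 < 0 ? 0 : (i0 > nx - 2 ? (nx > 1 ? nx - 2 : 0) : i0);
  j0 = j0 < 0 ? 0 : (j0 > ny - 2 ? (ny > 1 ? ny - 2 : 0) : j0);
  k0 = k0 < 0 ? 0 : (k0 > nz - 2 ? (nz > 1 ? nz - 2 : 0) : k0);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = nx == 1 ? 0 : i0 + 1, j1 = ny == 1 ? 0 : j0 + 1, k1 = nz == 1 ? 0 : k0 + 1;
  double c000 = v[idx3(i0, j0, k0, nx, ny)], c100 = v[idx3(i1, j0, k0, nx, ny)];
  double c010 = v[idx3(i0, j1, k0, nx, ny)], c110 = v[idx3(i1, j1, k0, nx, ny)];
  double c001 = v[idx3(i0, j0, k1, nx, ny)], c101 = v[idx3(i1, j0, k1, nx, ny)];
  double c011 = v[idx3(i0, j1, k1, nx, ny)], c111 = v[idx3(i1, j1, k1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static double sample_nearest(const double* v, int nx, int ny, int nz,
                             double x, double y, double z, int mode, double fill) {
  int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5), k = (int)std::floor(z + 0.5);
  if (mode == 1) {
    i = i < 0 ? 0 : (i > nx - 1 ? nx - 1 : i);
    j = j < 0 ? 0 : (j > ny - 1 ? ny - 1 : j);
    k = k < 0 ? 0 : (k > nz - 1 ? nz - 1 : k);
  } else if (i < 0 || j < 0 || k < 0 || i > nx - 1 || j > ny - 1 || k > nz - 1) {
    return fill;
  }
  return v[idx3(i, j, k, nx, ny)];
}

// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector vol, NumericVector xs, NumericVector ys,
                         NumericVector zs, bool nearest, int mode, double fill) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = xs.size();
  NumericVector out(n);
  const double* v = vol.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    out[t] = nearest ? sample_nearest(v, nx, ny, nz, xs[t], ys[t], zs[t], mode, fill)
                     : sample_linear(v, nx, ny, nz, xs[t], ys[t], zs[t], mode, fill);
  }
  return out;
}

// Warp a 3D volume by a displacement field (mm): out(x) = vol(x + u(x)/spacing).
// [[Rcpp::export]]
NumericVector cpp_warp_disp(NumericVector vol, NumericVector u, NumericVector spacing,
                            bool nearest, double fill) {
  IntegerVector d = u.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  IntegerVector dv = vol.attr("dim");
  int vx = dv[0], vy = dv[1], vz = dv[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* up = u.begin();
  const double* vp = vol.begin();
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        double px = i + up[t] / sx;
        double py = j + up[t + nvox] / sy;
        double pz = k + up[t + 2 * nvox] / sz;
        out[t] = nearest ? sample_nearest(vp, vx, vy, vz, px, py, pz, 0, fill)
                         : sample_linear(vp, vx, vy, vz, px, py, pz, 0, fill);
      }
  return out;
}

// Composition phi_f(phi_g(x)): u(x) = u_g(x) + u_f(x + u_g(x)/spacing).
// u_f is sampled linearly with edge clamping (fields extend smoothly).
// [[Rcpp::export]]
NumericVector cpp_compose_disp(NumericVector uf, NumericVector ug, NumericVector spacing) {
  IntegerVector d = ug.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double* gf = ug.begin();
  const double* ff = uf.begin();
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        double px = clampd(i + gf[t] / sx, 0.0, nx - 1.0);
        double py = clampd(j + gf[t + nvox] / sy, 0.0, ny - 1.0);
        double pz = clampd(k + gf[t + 2 * nvox] / sz, 0.0, nz - 1.0);
        int i0 = (int)px, j0 = (int)py, k0 = (int)pz;
        if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
        if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
        if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
        double fx = px - i0, fy = py - j0, fz = pz - k0;
        int i1 = nx == 1 ? 0 : i0 + 1, j1 = ny == 1 ? 0 : j0 + 1,
            k1 = nz == 1 ? 0 : k0 + 1;
        R_xlen_t t000 = idx3(i0, j0, k0, nx, ny), t100 = idx3(i1, j0, k0, nx, ny);
        R_xlen_t t010 = idx3(i0, j1, k0, nx, ny), t110 = idx3(i1, j1, k0, nx, ny);
        R_xlen_t t001 = idx3(i0, j0, k1, nx, ny), t101 = idx3(i1, j0, k1, nx, ny);
        R_xlen_t t011 = idx3(i0, j1, k1, nx, ny), t111 = idx3(i1, j1, k1, nx, ny);
        double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
        double w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz);
        double w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz;
        double w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
        for (int c = 0; c < 3; ++c) {
          const double* fc = ff + (R_xlen_t)c * nvox;
          out[t + c * nvox] = gf[t + c * nvox] +
            w000 * fc[t000] + w100 * fc[t100] + w010 * fc[t010] + w110 * fc[t110] +
            w001 * fc[t001] + w101 * fc[t101] + w011 * fc[t011] + w111 * fc[t111];
        }
      }
  return out;
}

// Exponential of a stationary velocity field by scaling and squaring.
// [[Rcpp::export]]
NumericVector cpp_exp_disp(NumericVector v, NumericVector spacing, int n_squarings) {
  NumericVector u = clone(v);
  double scale = std::pow(2.0, -n_squarings);
  for (R_xlen_t t = 0; t < u.size(); ++t) u[t] *= scale;
  u.attr("dim") = v.attr("dim");
  for (int s = 0; s < n_squarings; ++s) u = cpp_compose_disp(u, u, spacing);
  return u;
}

// Separable Gaussian smoothing, truncated kernel renormalised at edges.
static void smooth_axis(std::vector<double>& a, std::vector<double>& b,
                        int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> ker(2 * r + 1);
  for (int t = -r; t <= r; ++t) ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
  // per-position kernel mass for edge renormalisation (1D along the axis)
  std::vector<double> wsum(len, 0.0);
  for (int pos = 0; pos < len; ++pos) {
    int lo = pos - r < 0 ? -pos : -r;
    int hi = pos + r > len - 1 ? len - 1 - pos : r;
    for (int t = lo; t <= hi; ++t) wsum[pos] += ker[t + r];
  }
  std::fill(b.begin(), b.end(), 0.0);
  // tap-outer accumulation over contiguous spans
  for (int t = -r; t <= r; ++t) {
    double wk = ker[t + r];
    int p0 = t < 0 ? -t : 0;           // valid axis positions [p0, p1]
    int p1 = t > 0 ? len - 1 - t : len - 1;
    if (p0 > p1) continue;
    if (axis == 2) {
      R_xlen_t start = (R_xlen_t)p0 * nx * ny;
      R_xlen_t count = (R_xlen_t)(p1 - p0 + 1) * nx * ny;
      const double* src = a.data() + start + (R_xlen_t)t * stride;
      double* dst = b.data() + start;
      for (R_xlen_t q = 0; q < count; ++q) dst[q] += wk * src[q];
    } else if (axis == 1) {
      for (int k = 0; k < nz; ++k) {
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)p0 * nx;
        R_xlen_t count = (R_xlen_t)(p1 - p0 + 1) * nx;
        const double* src = a.data() + base + (R_xlen_t)t * stride;
        double* dst = b.data() + base;
        for (R_xlen_t q = 0; q < count; ++q) dst[q] += wk * src[q];
      }
    } else {
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          R_xlen_t base = idx3(p0, j, k, nx, ny);
          const double* src = a.data() + base + t;
          double* dst = b.data() + base;
          int count = p1 - p0 + 1;
          for (int q = 0; q < count; ++q) dst[q] += wk * src[q];
        }
    }
  }
  // renormalise by per-position kernel mass
  if (axis == 2) {
    for (int k = 0; k < nz; ++k) {
      double inv = 1.0 / wsum[k];
      double* dst = b.data() + (R_xlen_t)k * nx * ny;
      for (R_xlen_t q = 0; q < (R_xlen_t)nx * ny; ++q) dst[q] *= inv;
    }
  } else if (axis == 1) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        double inv = 1.0 / wsum[j];
        double* dst = b.data() + idx3(0, j, k, nx, ny);
        for (int q = 0; q < nx; ++q) dst[q] *= inv;
      }
  } else {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        double* dst = b.data() + idx3(0, j, k, nx, ny);
        for (int q = 0; q < nx; ++q) dst[q] *= 1.0 / wsum[q];
      }
  }
  std::swap(a, b);
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, NumericVector sigma_vox) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  int ncomp = vol.size() / nvox;
  NumericVector out(vol.size());
  out.attr("dim") = vol.attr("dim");
  std::vector<double> a(nvox), b(nvox);
  for (int c = 0; c < ncomp; ++c) {
    std::copy(vol.begin() + c * nvox, vol.begin() + (c + 1) * nvox, a.begin());
    for (int axis = 0; axis < 3; ++axis)
      smooth_axis(a, b, nx, ny, nz, axis, sigma_vox[axis]);
    std::copy(a.begin(), a.end(), out.begin() + c * nvox);
  }
  return out;
}

// Uniform box sum of radius r along one axis, dividing by the in-range
// count (for mean patch distances near edges).
static void box_mean_axis(std::vector<double>& a, std::vector<double>& b,
                          int nx, int ny, int nz, int axis, int r) {
  int n3[3] = {nx, ny, nz};
  int len = n3[axis];
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int pos = axis == 0 ? i : (axis == 1 ? j : k);
        R_xlen_t t0 = idx3(i, j, k, nx, ny);
        int lo = pos - r < 0 ? -pos : -r;
        int hi = pos + r > len - 1 ? len - 1 - pos : r;
        double acc = 0.0;
        for (int t = lo; t <= hi; ++t) acc += a[t0 + t * stride];
        b[t0] = acc / (hi - lo + 1);
      }
  std::swap(a, b);
}

// Non-local-means denoising: patch radius pr, search radius sr, bandwidth h.
// Offset-loop formulation: for each search offset, the mean squared patch
// difference is a box-filtered squared shift difference.
// [[Rcpp::export]]
NumericVector cpp_nlm(NumericVector vol, double h, int pr, int sr) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double* v = vol.begin();
  double h2 = h * h;
  std::vector<double> acc(nvox, 0.0), wsum(nvox, 0.0);
  std::vector<double> diff2(nvox), tmp(nvox);
  for (int ok = -sr; ok <= sr; ++ok)
    for (int oj = -sr; oj <= sr; ++oj)
      for (int oi = -sr; oi <= sr; ++oi) {
        if (oi * oi + oj * oj + ok * ok > sr * sr) continue;  // spherical window
        // squared difference to the offset image (edge-clamped shift)
        for (int k = 0; k < nz; ++k) {
          int ck = k + ok; ck = ck < 0 ? 0 : (ck >= nz ? nz - 1 : ck);
          for (int j = 0; j < ny; ++j) {
            int cj = j + oj; cj = cj < 0 ? 0 : (cj >= ny ? ny - 1 : cj);
            R_xlen_t row = idx3(0, j, k, nx, ny);
            R_xlen_t crow = idx3(0, cj, ck, nx, ny);
            for (int i = 0; i < nx; ++i) {
              int ci = i + oi; ci = ci < 0 ? 0 : (ci >= nx ? nx - 1 : ci);
              double df = v[row + i] - v[crow + ci];
              diff2[row + i] = df * df;
            }
          }
        }
        for (int ax = 0; ax < 3; ++ax) box_mean_axis(diff2, tmp, nx, ny, nz, ax, pr);
        // accumulate the weighted offset image
        for (int k = 0; k < nz; ++k) {
          int ck = k + ok; ck = ck < 0 ? 0 : (ck >= nz ? nz - 1 : ck);
          for (int j = 0; j < ny; ++j) {
            int cj = j + oj; cj = cj < 0 ? 0 : (cj >= ny ? ny - 1 : cj);
            R_xlen_t row = idx3(0, j, k, nx, ny);
            R_xlen_t crow = idx3(0, cj, ck, nx, ny);
            for (int i = 0; i < nx; ++i) {
              int ci = i + oi; ci = ci < 0 ? 0 : (ci >= nx ? nx - 1 : ci);
              double w = std::exp(-diff2[row + i] / h2);
              acc[row + i] += w * v[crow + ci];
              wsum[row + i] += w;
            }
          }
        }
      }
  NumericVector out(nvox);
  out.attr("dim") = vol.attr("dim");
  for (R_xlen_t t = 0; t < nvox; ++t) out[t] = acc[t] / wsum[t];
  return out;
}

// Connected components of a binary mask; connectivity 6, 18 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox);
  lab.attr("dim") = mask.attr("dim");
  std::vector<int> offs_i, offs_j, offs_k;
  for (int ok = -1; ok <= 1; ++ok)
    for (int oj = -1; oj <= 1; ++oj)
      for (int oi = -1; oi <= 1; ++oi) {
        int s = std::abs(oi) + std::abs(oj) + std::abs(ok);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        offs_i.push_back(oi); offs_j.push_back(oj); offs_k.push_back(ok);
      }
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t t0 = 0; t0 < nvox; ++t0) {
    if (!mask[t0] || lab[t0] != 0) continue;
    ++cur;
    lab[t0] = cur;
    stack.clear();
    stack.push_back(t0);
    while (!stack.empty()) {
      R_xlen_t t = stack.back(); stack.pop_back();
      int i = t % nx, j = (t / nx) % ny, k = t / ((R_xlen_t)nx * ny);
      for (size_t m = 0; m < offs_i.size(); ++m) {
        int ci = i + offs_i[m], cj = j + offs_j[m], ck = k + offs_k[m];
        if (ci < 0 || cj < 0 || ck < 0 || ci >= nx || cj >= ny || ck >= nz) continue;
        R_xlen_t tn = idx3(ci, cj, ck, nx, ny);
        if (mask[tn] && lab[tn] == 0) { lab[tn] = cur; stack.push_back(tn); }
      }
    }
  }
  return lab;
}

// Spatial gradient of phi = x + u w.r.t. world mm; returns det(grad phi).
// Central differences in the interior, one-sided at the boundary.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector u, NumericVector spacing) {
  IntegerVector d = u.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* up = u.begin();
  double s[3] = {spacing[0], spacing[1], spacing[2]};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double J[3][3];
        int pos[3] = {i, j, k};
        int n[3] = {nx, ny, nz};
        for (int c = 0; c < 3; ++c) {
          const double* uc = up + (R_xlen_t)c * nvox;
          for (int ax = 0; ax < 3; ++ax) {
            int lo = pos[ax] > 0 ? pos[ax] - 1 : pos[ax];
            int hi = pos[ax] < n[ax] - 1 ? pos[ax] + 1 : pos[ax];
            int q[3] = {i, j, k};
            q[ax] = hi;
            double vhi = uc[idx3(q[0], q[1], q[2], nx, ny)];
            q[ax] = lo;
            double vlo = uc[idx3(q[0], q[1], q[2], nx, ny)];
            double denom = (hi - lo) * s[ax];
            J[c][ax] = (denom > 0 ? (vhi - vlo) / denom : 0.0) + (c == ax ? 1.0 : 0.0);
          }
        }
        out[idx3(i, j, k, nx, ny)] =
          J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
          J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
          J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}

// Catmull-Rom (Keys, a = -0.5) cubic kernel weight.
static inline double keys_w(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// Warp a 3D volume by a displacement field with cubic (Keys) interpolation:
// sharper than trilinear for template averaging. Outside -> fill.
// [[Rcpp::export]]
NumericVector cpp_warp_disp_cubic(NumericVector vol, NumericVector u,
                                  NumericVector spacing, double fill) {
  IntegerVector d = u.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* up = u.begin();
  const double* vp = vol.begin();
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        double px = i + up[t] / sx;
        double py = j + up[t + nvox] / sy;
        double pz = k + up[t + 2 * nvox] / sz;
        if (px < 0 || py < 0 || pz < 0 || px > nx - 1 || py > ny - 1 || pz > nz - 1) {
          out[t] = fill;
          continue;
        }
        int i0 = (int)std::floor(px), j0 = (int)std::floor(py), k0 = (int)std::floor(pz);
        double wx[4], wy[4], wz[4];
        for (int m = 0; m < 4; ++m) {
          wx[m] = keys_w(px - (i0 - 1 + m));
          wy[m] = keys_w(py - (j0 - 1 + m));
          wz[m] = keys_w(pz - (k0 - 1 + m));
        }
        double acc = 0.0;
        for (int mk2 = 0; mk2 < 4; ++mk2) {
          int ck = k0 - 1 + mk2;
          ck = ck < 0 ? 0 : (ck > nz - 1 ? nz - 1 : ck);
          for (int mj = 0; mj < 4; ++mj) {
            int cj = j0 - 1 + mj;
            cj = cj < 0 ? 0 : (cj > ny - 1 ? ny - 1 : cj);
            double wjk = wy[mj] * wz[mk2];
            if (wjk == 0.0) continue;
            for (int mi = 0; mi < 4; ++mi) {
              int ci = i0 - 1 + mi;
              ci = ci < 0 ? 0 : (ci > nx - 1 ? nx - 1 : ci);
              acc += wx[mi] * wjk * vp[idx3(ci, cj, ck, nx, ny)];
            }
          }
        }
        out[t] = acc;
      }
  return out;
}

// One demons force evaluation: central-difference gradient of `warped`,
// Thirion normalisation, small-difference floor, magnitude cap. Returns
// the 4D force (mm) with attribute "msd" = masked mean squared difference.
// [[Rcpp::export]]
NumericVector cpp_demons_force(NumericVector fixed, NumericVector warped,
                               LogicalVector mask, NumericVector spacing,
                               double K2, double cap, double floor_abs) {
  IntegerVector d = fixed.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector force(nvox * 3);
  force.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double* f = fixed.begin();
  const double* w = warped.begin();
  double s[3] = {spacing[0], spacing[1], spacing[2]};
  double acc = 0.0; R_xlen_t nmask = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        double diff = f[t] - w[t];
        if (mask[t]) { acc += diff * diff; ++nmask; }
        if (std::fabs(diff) < floor_abs) continue;
        double g[3];
        int pos[3] = {i, j, k};
        int n[3] = {nx, ny, nz};
        for (int ax = 0; ax < 3; ++ax) {
          int lo = pos[ax] > 0 ? pos[ax] - 1 : pos[ax];
          int hi = pos[ax] < n[ax] - 1 ? pos[ax] + 1 : pos[ax];
          int q[3] = {i, j, k};
          q[ax] = hi;
          double vhi = w[idx3(q[0], q[1], q[2], nx, ny)];
          q[ax] = lo;
          double vlo = w[idx3(q[0], q[1], q[2], nx, ny)];
          g[ax] = (vhi - vlo) / ((hi - lo) * s[ax]);
        }
        double den = g[0] * g[0] + g[1] * g[1] + g[2] * g[2] + diff * diff / K2;
        if (den < 1e-12) continue;
        double fx = diff * g[0] / den, fy = diff * g[1] / den, fz = diff * g[2] / den;
        double mag = std::sqrt(fx * fx + fy * fy + fz * fz);
        if (mag > cap) { fx *= cap / mag; fy *= cap / mag; fz *= cap / mag; }
        force[t] = fx; force[t + nvox] = fy; force[t + 2 * nvox] = fz;
      }
  force.attr("msd") = nmask > 0 ? acc / nmask : 0.0;
  return force;
}

// Block-average downsampling by 2 along each axis (odd tails averaged short).
// [[Rcpp::export]]
NumericVector cpp_downsample2(NumericVector vol) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int mx = (nx + 1) / 2, my = (ny + 1) / 2, mz = (nz + 1) / 2;
  NumericVector out((R_xlen_t)mx * my * mz);
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  const double* v = vol.begin();
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double acc = 0.0; int cnt = 0;
        for (int ok = 0; ok < 2; ++ok)
          for (int oj = 0; oj < 2; ++oj)
            for (int oi = 0; oi < 2; ++oi) {
              int ci = 2 * i + oi, cj = 2 * j + oj, ck = 2 * k + ok;
              if (ci >= nx || cj >= ny || ck >= nz) continue;
              acc += v[idx3(ci, cj, ck, nx, ny)];
              ++cnt;
            }
        out[idx3(i, j, k, mx, my)] = acc / cnt;
      }
  return out;
}
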