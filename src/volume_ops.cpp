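// Low-level 3D kernels: regularized Heaviside/Dirac, integral-image localized
// region forces, mean curvature, explicit diffusion, exact Euclidean distance
// transform, separable Gaussian blur, trilinear affine resampling.
// All arrays are column-major (R layout), 0-based indices internally.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// C2 polynomial (quintic smoothstep) profile with compact support [-eps, eps].
// H is the INTERIOR weight: H = 1 for phi <= -eps, H = 0 for phi >= eps,
// H(0) = 0.5. dirac = -dH/dphi >= 0, symmetric, integrates to 1.
static inline double hside(double p, double eps) {
  if (p <= -eps) return 1.0;
  if (p >= eps) return 0.0;
  double s = 0.5 * (1.0 - p / eps);
  return ((6.0 * s - 15.0) * s + 10.0) * s * s * s;
}
static inline double dirac_(double p, double eps) {
  if (p <= -eps || p >= eps) return 0.0;
  double s = 0.5 * (1.0 - p / eps);
  double t = s * (1.0 - s);
  return 15.0 * t * t / eps;
}

// [[Rcpp::export(name = ".heaviside_cpp")]]
NumericVector heaviside_cpp(NumericVector phi, double eps) {
  NumericVector out(phi.size());
  for (R_xlen_t i = 0; i < phi.size(); ++i) out[i] = hside(phi[i], eps);
  return out;
}

// [[Rcpp::export(name = ".dirac_cpp")]]
NumericVector dirac_cpp(NumericVector phi, double eps) {
  NumericVector out(phi.size());
  for (R_xlen_t i = 0; i < phi.size(); ++i) out[i] = dirac_(phi[i], eps);
  return out;
}

// Padded 3D prefix sums: P has dims (nx+1, ny+1, nz+1), P(0,.,.) = 0,
// P(i+1,j+1,k+1) = sum of a over the box [0..i]x[0..j]x[0..k].
static void cumsum3(const double* a, int nx, int ny, int nz, std::vector<double>& P) {
  int px = nx + 1, py = ny + 1, pz = nz + 1;
  P.assign((size_t)px * py * pz, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        P[(size_t)(x + 1) + (size_t)px * ((y + 1) + (size_t)py * (z + 1))] =
          a[idx3(x, y, z, nx, ny)];
  // cumulative along x, then y, then z (within the padded array)
  for (int z = 1; z < pz; ++z)
    for (int y = 1; y < py; ++y) {
      double* row = &P[(size_t)px * (y + (size_t)py * z)];
      for (int x = 1; x < px; ++x) row[x] += row[x - 1];
    }
  for (int z = 1; z < pz; ++z)
    for (int y = 2; y < py; ++y) {
      double* row = &P[(size_t)px * (y + (size_t)py * z)];
      double* prev = &P[(size_t)px * ((y - 1) + (size_t)py * z)];
      for (int x = 1; x < px; ++x) row[x] += prev[x];
    }
  for (int z = 2; z < pz; ++z)
    for (int y = 1; y < py; ++y) {
      double* row = &P[(size_t)px * (y + (size_t)py * z)];
      double* prev = &P[(size_t)px * (y + (size_t)py * (z - 1))];
      for (int x = 1; x < px; ++x) row[x] += prev[x];
    }
}

static inline double boxsum(const std::vector<double>& P, int px, int py,
                            int x0, int x1, int y0, int y1, int z0, int z1) {
  // inclusive box [x0..x1] etc., 0-based
  const double* p = P.data();
  size_t sxy = (size_t)px * py;
  ++x1; ++y1; ++z1;
  return p[x1 + px * y1 + sxy * z1] - p[x0 + px * y1 + sxy * z1]
       - p[x1 + px * y0 + sxy * z1] - p[x1 + px * y1 + sxy * z0]
       + p[x0 + px * y0 + sxy * z1] + p[x0 + px * y1 + sxy * z0]
       + p[x1 + px * y0 + sxy * z0] - p[x0 + px * y0 + sxy * z0];
}

// [[Rcpp::export(name = ".integral_image_cpp")]]
NumericVector integral_image_cpp(NumericVector a, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> P;
  cumsum3(REAL(a), nx, ny, nz, P);
  NumericVector out(P.begin(), P.end());
  out.attr("dim") = IntegerVector::create(nx + 1, ny + 1, nz + 1);
  return out;
}

// Localized region force field of the banded UM / MS models.
//   speed(x) = dirac(phi(x)) * sum_{y in B(x)} dirac(phi(y)) *
//              [ l1 (I(y)-u_x)^2 (/A_in) - l2 (I(y)-v_x)^2 (/A_out) ]
// u_x, v_x are the Heaviside-weighted interior/exterior means of the window;
// model: 0 = UM (no area normalization), 1 = MS (divide by A_in / A_out).
// csI/csI2 are padded prefix sums of I and I^2 (cached across iterations).
// Also returns the banded localized energy and the degenerate-window count.
// [[Rcpp::export(name = ".force_field_cpp")]]
List force_field_cpp(NumericVector vol, NumericVector phi, IntegerVector dim,
                     int rad, double lam1, double lam2, double eps, int model,
                     NumericVector csI, NumericVector csI2) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double* I = REAL(vol);
  const double* ph = REAL(phi);
  int px = nx + 1, py = ny + 1;

  std::vector<double> H(n), D(n), HI(n), HI2(n), DI(n), DI2(n);
  for (size_t i = 0; i < n; ++i) {
    double h = hside(ph[i], eps), d = dirac_(ph[i], eps);
    H[i] = h; D[i] = d;
    HI[i] = h * I[i]; HI2[i] = h * I[i] * I[i];
    DI[i] = d * I[i]; DI2[i] = d * I[i] * I[i];
  }
  std::vector<double> PH, PHI, PHI2, PD, PDI, PDI2;
  cumsum3(H.data(), nx, ny, nz, PH);
  cumsum3(HI.data(), nx, ny, nz, PHI);
  cumsum3(HI2.data(), nx, ny, nz, PHI2);
  cumsum3(D.data(), nx, ny, nz, PD);
  cumsum3(DI.data(), nx, ny, nz, PDI);
  cumsum3(DI2.data(), nx, ny, nz, PDI2);
  std::vector<double> PI(REAL(csI), REAL(csI) + (size_t)px * py * (nz + 1));
  std::vector<double> PI2(REAL(csI2), REAL(csI2) + (size_t)px * py * (nz + 1));

  NumericVector speed(vol.size());
  speed.attr("dim") = dim;
  double energy = 0.0;
  int degenerate = 0;
  const double tol = 1e-9;

  for (int z = 0; z < nz; ++z) {
    int z0 = std::max(0, z - rad), z1 = std::min(nz - 1, z + rad);
    for (int y = 0; y < ny; ++y) {
      int y0 = std::max(0, y - rad), y1 = std::min(ny - 1, y + rad);
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)idx3(x, y, z, nx, ny);
        double dc = D[i];
        if (dc <= 0.0) continue;
        int x0 = std::max(0, x - rad), x1 = std::min(nx - 1, x + rad);
        double N = (double)(x1 - x0 + 1) * (y1 - y0 + 1) * (z1 - z0 + 1);
        double sH  = boxsum(PH,  px, py, x0, x1, y0, y1, z0, z1);
        double sHI = boxsum(PHI, px, py, x0, x1, y0, y1, z0, z1);
        double sHI2= boxsum(PHI2,px, py, x0, x1, y0, y1, z0, z1);
        double sI  = boxsum(PI,  px, py, x0, x1, y0, y1, z0, z1);
        double sI2 = boxsum(PI2, px, py, x0, x1, y0, y1, z0, z1);
        double Ain = sH, Aout = N - sH;
        double full = sI / N;
        double u, v;
        bool degen = false;
        if (Ain > tol) u = sHI / Ain; else { u = full; degen = true; }
        if (Aout > tol) v = (sI - sHI) / Aout; else { v = full; degen = true; }
        if (degen) ++degenerate;
        double sD   = boxsum(PD,   px, py, x0, x1, y0, y1, z0, z1);
        double sDI  = boxsum(PDI,  px, py, x0, x1, y0, y1, z0, z1);
        double sDI2 = boxsum(PDI2, px, py, x0, x1, y0, y1, z0, z1);
        double su = sDI2 - 2.0 * u * sDI + u * u * sD; // sum dirac*(I-u)^2
        double sv = sDI2 - 2.0 * v * sDI + v * v * sD;
        double nin = 1.0, nout = 1.0;
        if (model == 1) {
          nin = (Ain > tol) ? Ain : N;
          nout = (Aout > tol) ? Aout : N;
        }
        speed[i] = dc * (lam1 * su / nin - lam2 * sv / nout);
        // localized energy: interior/exterior misfit of the window
        double ein = sHI2 - 2.0 * u * sHI + u * u * sH;
        double eout = (sI2 - sHI2) - 2.0 * v * (sI - sHI) + v * v * Aout;
        energy += dc * (lam1 * ein / nin + lam2 * eout / nout);
      }
    }
  }
  return List::create(_["speed"] = speed, _["energy"] = energy,
                      _["degenerate"] = degenerate);
}

// mu * dirac(phi) * mean curvature (div of normalized gradient), central
// differences, evaluated only where dirac > 0; gradient-magnitude floor.
// [[Rcpp::export(name = ".curvature_cpp")]]
NumericVector curvature_cpp(NumericVector phi, IntegerVector dim, double mu,
                            double eps, double grad_floor) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(phi.size());
  out.attr("dim") = dim;
  if (mu == 0.0) return out;
  const double* p = REAL(phi);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)idx3(x, y, z, nx, ny);
        double d = dirac_(p[i], eps);
        if (d <= 0.0) continue;
        int xm = std::max(0, x - 1), xp = std::min(nx - 1, x + 1);
        int ym = std::max(0, y - 1), yp = std::min(ny - 1, y + 1);
        int zm = std::max(0, z - 1), zp = std::min(nz - 1, z + 1);
        double pxp = p[idx3(xp, y, z, nx, ny)], pxm = p[idx3(xm, y, z, nx, ny)];
        double pyp = p[idx3(x, yp, z, nx, ny)], pym = p[idx3(x, ym, z, nx, ny)];
        double pzp = p[idx3(x, y, zp, nx, ny)], pzm = p[idx3(x, y, zm, nx, ny)];
        double fx = 0.5 * (pxp - pxm);
        double fy = 0.5 * (pyp - pym);
        double fz = 0.5 * (pzp - pzm);
        double fxx = pxp - 2.0 * p[i] + pxm;
        double fyy = pyp - 2.0 * p[i] + pym;
        double fzz = pzp - 2.0 * p[i] + pzm;
        double fxy = 0.25 * (p[idx3(xp, yp, z, nx, ny)] - p[idx3(xm, yp, z, nx, ny)]
                           - p[idx3(xp, ym, z, nx, ny)] + p[idx3(xm, ym, z, nx, ny)]);
        double fxz = 0.25 * (p[idx3(xp, y, zp, nx, ny)] - p[idx3(xm, y, zp, nx, ny)]
                           - p[idx3(xp, y, zm, nx, ny)] + p[idx3(xm, y, zm, nx, ny)]);
        double fyz = 0.25 * (p[idx3(x, yp, zp, nx, ny)] - p[idx3(x, ym, zp, nx, ny)]
                           - p[idx3(x, yp, zm, nx, ny)] + p[idx3(x, ym, zm, nx, ny)]);
        double g2 = fx * fx + fy * fy + fz * fz;
        double g = std::sqrt(g2);
        if (g < grad_floor) continue;
        double k = (fx * fx * (fyy + fzz) + fy * fy * (fxx + fzz) + fz * fz * (fxx + fyy)
                  - 2.0 * (fx * fy * fxy + fx * fz * fxz + fy * fz * fyz)) / (g2 * g);
        out[i] = mu * d * k;
      }
  return out;
}

// Explicit diffusion sub-steps with zero-flux boundaries:
// phi <- phi + dtau * nu * laplacian(phi). Stability checked by the caller.
// [[Rcpp::export(name = ".diffuse_cpp")]]
NumericVector diffuse_cpp(NumericVector phi, IntegerVector dim, double nu,
                          double dtau, int substeps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(REAL(phi), REAL(phi) + n), b(n);
  for (int s = 0; s < substeps; ++s) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t i = (size_t)idx3(x, y, z, nx, ny);
          double c = a[i], lap = 0.0;
          if (x > 0) lap += a[i - 1] - c;
          if (x < nx - 1) lap += a[i + 1] - c;
          if (y > 0) lap += a[i - nx] - c;
          if (y < ny - 1) lap += a[i + nx] - c;
          if (z > 0) lap += a[i - (size_t)nx * ny] - c;
          if (z < nz - 1) lap += a[i + (size_t)nx * ny] - c;
          b[i] = c + dtau * nu * lap;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Felzenszwalb & Huttenlocher exact squared EDT, one axis.
static void dt1d(std::vector<double>& f, int n, double w2,
                 std::vector<int>& v, std::vector<double>& zbuf,
                 std::vector<double>& d) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
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
    d[q] = f[v[k]] + w2 * (q - v[k]) * (q - v[k]);
  }
}

// Distance (physical units per `spacing`) from every voxel to the nearest
// seed voxel. Exact Euclidean, anisotropic.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector seed, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double BIG = 1e20;
  std::vector<double> D(n);
  for (size_t i = 0; i < n; ++i) D[i] = seed[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // x axis
  double w2 = spacing[0] * spacing[0];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = D[idx3(x, y, z, nx, ny)];
      dt1d(f, nx, w2, v, zbuf, d);
      for (int x = 0; x < nx; ++x) D[idx3(x, y, z, nx, ny)] = d[x];
    }
  // y axis
  w2 = spacing[1] * spacing[1];
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = D[idx3(x, y, z, nx, ny)];
      dt1d(f, ny, w2, v, zbuf, d);
      for (int y = 0; y < ny; ++y) D[idx3(x, y, z, nx, ny)] = d[y];
    }
  // z axis
  w2 = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = D[idx3(x, y, z, nx, ny)];
      dt1d(f, nz, w2, v, zbuf, d);
      for (int z = 0; z < nz; ++z) D[idx3(x, y, z, nx, ny)] = d[z];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(D[i]);
  out.attr("dim") = dim;
  return out;
}

// Mask voxels with at least one 6-connected non-mask neighbour (grid borders
// do not count as background).
// [[Rcpp::export(name = ".border_voxels_cpp")]]
LogicalVector border_voxels_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  out.attr("dim") = dim;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        bool b = false;
        if (x > 0 && !mask[i - 1]) b = true;
        else if (x < nx - 1 && !mask[i + 1]) b = true;
        else if (y > 0 && !mask[i - nx]) b = true;
        else if (y < ny - 1 && !mask[i + nx]) b = true;
        else if (z > 0 && !mask[i - (size_t)nx * ny]) b = true;
        else if (z < nz - 1 && !mask[i + (size_t)nx * ny]) b = true;
        out[i] = b;
      }
  return out;
}

// Interior voxels (phi < 0) adjacent (6-connectivity) to a voxel with
// phi >= 0: the discrete zero-level-set shell.
// [[Rcpp::export(name = ".contour_voxels_cpp")]]
LogicalVector contour_voxels_cpp(NumericVector phi, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* p = REAL(phi);
  LogicalVector out(phi.size());
  out.attr("dim") = dim;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)idx3(x, y, z, nx, ny);
        if (p[i] >= 0) continue;
        bool b = false;
        if (x > 0 && p[i - 1] >= 0) b = true;
        else if (x < nx - 1 && p[i + 1] >= 0) b = true;
        else if (y > 0 && p[i - nx] >= 0) b = true;
        else if (y < ny - 1 && p[i + nx] >= 0) b = true;
        else if (z > 0 && p[i - (size_t)nx * ny] >= 0) b = true;
        else if (z < nz - 1 && p[i + (size_t)nx * ny] >= 0) b = true;
        out[i] = b;
      }
  return out;
}

// Separable Gaussian blur, kernel truncated at 3 sigma, replicate borders.
// [[Rcpp::export(name = ".gaussian_blur3d_cpp")]]
NumericVector gaussian_blur3d_cpp(NumericVector a, IntegerVector dim,
                                  NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> cur(REAL(a), REAL(a) + n), nxt(n);
  int dims[3] = {nx, ny, nz};
  size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int hw = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * hw + 1);
    double ksum = 0;
    for (int j = -hw; j <= hw; ++j) {
      k[j + hw] = std::exp(-0.5 * j * j / (s * s));
      ksum += k[j + hw];
    }
    for (double& kv : k) kv /= ksum;
    int nax = dims[ax];
    size_t st = strides[ax];
    for (size_t i = 0; i < n; ++i) {
      // position along axis
      int pos;
      if (ax == 0) pos = (int)(i % nx);
      else if (ax == 1) pos = (int)((i / nx) % ny);
      else pos = (int)(i / ((size_t)nx * ny));
      double acc = 0;
      for (int j = -hw; j <= hw; ++j) {
        int q = pos + j;
        if (q < 0) q = 0;
        if (q >= nax) q = nax - 1;
        acc += k[j + hw] * cur[i + (size_t)(q - pos) * st];
      }
      nxt[i] = acc;
    }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// Trilinear resampling under an affine map: for each output voxel with
// 0-based index o, source coordinate s = A %*% o + t (0-based, voxel units of
// the source grid), clamped to the grid. A is 3x3 column-major.
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  IntegerVector odim, NumericVector A,
                                  NumericVector t) {
  int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  const double* S = REAL(src);
  NumericVector out((size_t)ox * oy * oz);
  out.attr("dim") = odim;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double cx = A[0] * x + A[3] * y + A[6] * z + t[0];
        double cy = A[1] * x + A[4] * y + A[7] * z + t[1];
        double cz = A[2] * x + A[5] * y + A[8] * z + t[2];
        if (cx < 0) cx = 0; if (cx > sx - 1) cx = sx - 1;
        if (cy < 0) cy = 0; if (cy > sy - 1) cy = sy - 1;
        if (cz < 0) cz = 0; if (cz > sz - 1) cz = sz - 1;
        int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
        int x1 = std::min(x0 + 1, sx - 1), y1 = std::min(y0 + 1, sy - 1),
            z1 = std::min(z0 + 1, sz - 1);
        double fx = cx - x0, fy = cy - y0, fz = cz - z0;
        double c00 = S[idx3(x0, y0, z0, sx, sy)] * (1 - fx) + S[idx3(x1, y0, z0, sx, sy)] * fx;
        double c10 = S[idx3(x0, y1, z0, sx, sy)] * (1 - fx) + S[idx3(x1, y1, z0, sx, sy)] * fx;
        double c01 = S[idx3(x0, y0, z1, sx, sy)] * (1 - fx) + S[idx3(x1, y0, z1, sx, sy)] * fx;
        double c11 = S[idx3(x0, y1, z1, sx, sy)] * (1 - fx) + S[idx3(x1, y1, z1, sx, sy)] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[idx3(x, y, z, ox, oy)] = c0 * (1 - fz) + c1 * fz;
      }
  return out;
}

// One fused evolution step: banded localized force (+ curvature), CFL-style
// explicit update of phi IN PLACE, reaction-diffusion sub-steps, clamping of
// phi to the bounded transition layer [-cap, cap], and trace statistics
// (localized energy, interior volume, optional DICE against a mask).
// lam_in weights the interior-misfit term, lam_out the exterior one.
// [[Rcpp::export(name = ".ls_step_cpp")]]
List ls_step_cpp(NumericVector vol, NumericVector phi, IntegerVector dim,
                 int rad, double lam_in, double lam_out, double eps, int model,
                 double mu, double grad_floor, double cfl, double dt_fixed,
                 double rd_nu, double rd_dtau, int rd_substeps, double cap,
                 double rd_gain, NumericVector csI, NumericVector csI2,
                 LogicalVector gt) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double* I = REAL(vol);
  double* ph = REAL(phi);
  int px = nx + 1, py = ny + 1;

  std::vector<double> H(n), D(n), HI(n), HI2(n), DI(n), DI2(n);
  for (size_t i = 0; i < n; ++i) {
    double h = hside(ph[i], eps), d = dirac_(ph[i], eps);
    H[i] = h; D[i] = d;
    HI[i] = h * I[i]; HI2[i] = h * I[i] * I[i];
    DI[i] = d * I[i]; DI2[i] = d * I[i] * I[i];
  }
  std::vector<double> PH, PHI, PHI2, PD, PDI, PDI2;
  cumsum3(H.data(), nx, ny, nz, PH);
  cumsum3(HI.data(), nx, ny, nz, PHI);
  cumsum3(HI2.data(), nx, ny, nz, PHI2);
  cumsum3(D.data(), nx, ny, nz, PD);
  cumsum3(DI.data(), nx, ny, nz, PDI);
  cumsum3(DI2.data(), nx, ny, nz, PDI2);
  std::vector<double> PI(REAL(csI), REAL(csI) + (size_t)px * py * (nz + 1));
  std::vector<double> PI2(REAL(csI2), REAL(csI2) + (size_t)px * py * (nz + 1));

  std::vector<size_t> bidx;
  std::vector<double> bspeed;
  bidx.reserve(16384); bspeed.reserve(16384);
  double energy = 0.0, maxabs = 0.0;
  int degenerate = 0;
  const double tol = 1e-9;

  for (int z = 0; z < nz; ++z) {
    int z0 = std::max(0, z - rad), z1 = std::min(nz - 1, z + rad);
    for (int y = 0; y < ny; ++y) {
      int y0 = std::max(0, y - rad), y1 = std::min(ny - 1, y + rad);
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)idx3(x, y, z, nx, ny);
        double dc = D[i];
        if (dc <= 0.0) continue;
        int x0 = std::max(0, x - rad), x1 = std::min(nx - 1, x + rad);
        double N = (double)(x1 - x0 + 1) * (y1 - y0 + 1) * (z1 - z0 + 1);
        double sH  = boxsum(PH,  px, py, x0, x1, y0, y1, z0, z1);
        double sHI = boxsum(PHI, px, py, x0, x1, y0, y1, z0, z1);
        double sHI2= boxsum(PHI2,px, py, x0, x1, y0, y1, z0, z1);
        double sI  = boxsum(PI,  px, py, x0, x1, y0, y1, z0, z1);
        double sI2 = boxsum(PI2, px, py, x0, x1, y0, y1, z0, z1);
        double Ain = sH, Aout = N - sH;
        double full = sI / N;
        double u, v;
        bool degen = false;
        if (Ain > tol) u = sHI / Ain; else { u = full; degen = true; }
        if (Aout > tol) v = (sI - sHI) / Aout; else { v = full; degen = true; }
        if (degen) ++degenerate;
        double sD   = boxsum(PD,   px, py, x0, x1, y0, y1, z0, z1);
        double sDI  = boxsum(PDI,  px, py, x0, x1, y0, y1, z0, z1);
        double sDI2 = boxsum(PDI2, px, py, x0, x1, y0, y1, z0, z1);
        double su = sDI2 - 2.0 * u * sDI + u * u * sD;
        double sv = sDI2 - 2.0 * v * sDI + v * v * sD;
        double nin = 1.0, nout = 1.0;
        if (model == 1) {
          nin = (Ain > tol) ? Ain : N;
          nout = (Aout > tol) ? Aout : N;
        }
        double spd = dc * (lam_in * su / nin - lam_out * sv / nout);
        // curvature term inline (central differences, replicate borders)
        if (mu > 0) {
          int xm = std::max(0, x - 1), xp = std::min(nx - 1, x + 1);
          int ym = std::max(0, y - 1), yp = std::min(ny - 1, y + 1);
          int zm = std::max(0, z - 1), zp = std::min(nz - 1, z + 1);
          double pxp = ph[idx3(xp, y, z, nx, ny)], pxm = ph[idx3(xm, y, z, nx, ny)];
          double pyp = ph[idx3(x, yp, z, nx, ny)], pym = ph[idx3(x, ym, z, nx, ny)];
          double pzp = ph[idx3(x, y, zp, nx, ny)], pzm = ph[idx3(x, y, zm, nx, ny)];
          double fx = 0.5 * (pxp - pxm), fy = 0.5 * (pyp - pym), fz = 0.5 * (pzp - pzm);
          double g2 = fx * fx + fy * fy + fz * fz;
          double g = std::sqrt(g2);
          if (g >= grad_floor) {
            double fxx = pxp - 2.0 * ph[i] + pxm;
            double fyy = pyp - 2.0 * ph[i] + pym;
            double fzz = pzp - 2.0 * ph[i] + pzm;
            double fxy = 0.25 * (ph[idx3(xp, yp, z, nx, ny)] - ph[idx3(xm, yp, z, nx, ny)]
                               - ph[idx3(xp, ym, z, nx, ny)] + ph[idx3(xm, ym, z, nx, ny)]);
            double fxz = 0.25 * (ph[idx3(xp, y, zp, nx, ny)] - ph[idx3(xm, y, zp, nx, ny)]
                               - ph[idx3(xp, y, zm, nx, ny)] + ph[idx3(xm, y, zm, nx, ny)]);
            double fyz = 0.25 * (ph[idx3(x, yp, zp, nx, ny)] - ph[idx3(x, ym, zp, nx, ny)]
                               - ph[idx3(x, yp, zm, nx, ny)] + ph[idx3(x, ym, zm, nx, ny)]);
            double k = (fx * fx * (fyy + fzz) + fy * fy * (fxx + fzz) + fz * fz * (fxx + fyy)
                      - 2.0 * (fx * fy * fxy + fx * fz * fxz + fy * fz * fyz)) / (g2 * g);
            spd += mu * dc * k;
          }
        }
        double ein = sHI2 - 2.0 * u * sHI + u * u * sH;
        double eout = (sI2 - sHI2) - 2.0 * v * (sI - sHI) + v * v * Aout;
        energy += dc * (lam_in * ein / nin + lam_out * eout / nout);
        bidx.push_back(i);
        bspeed.push_back(spd);
        double a = std::fabs(spd);
        if (a > maxabs) maxabs = a;
      }
    }
  }
  double dt = (dt_fixed > 0) ? dt_fixed : ((maxabs > 0) ? cfl / maxabs : 0.0);
  for (size_t k = 0; k < bidx.size(); ++k) ph[bidx[k]] += dt * bspeed[k];
  // reaction step: pull phi toward the +-cap wells (multiplicative
  // sharpening balanced against the diffusion below, so the transition
  // layer keeps a steady width instead of smearing over long runs)
  if (cap > 0 && rd_gain > 0) {
    double g = 1.0 + rd_gain;
    for (size_t i = 0; i < n; ++i) {
      double v2 = ph[i] * g;
      if (v2 > cap) v2 = cap;
      else if (v2 < -cap) v2 = -cap;
      ph[i] = v2;
    }
  }
  // diffusion sub-steps + clamp
  if (rd_nu > 0 && rd_substeps > 0) {
    std::vector<double> buf(n);
    for (int s = 0; s < rd_substeps; ++s) {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t i = (size_t)idx3(x, y, z, nx, ny);
            double c = ph[i], lap = 0.0;
            if (x > 0) lap += ph[i - 1] - c;
            if (x < nx - 1) lap += ph[i + 1] - c;
            if (y > 0) lap += ph[i - nx] - c;
            if (y < ny - 1) lap += ph[i + nx] - c;
            if (z > 0) lap += ph[i - (size_t)nx * ny] - c;
            if (z < nz - 1) lap += ph[i + (size_t)nx * ny] - c;
            buf[i] = c + rd_dtau * rd_nu * lap;
          }
      std::copy(buf.begin(), buf.end(), ph);
    }
  }
  size_t n_in = 0, inter = 0, ngt = 0;
  bool has_gt = gt.size() == (R_xlen_t)n;
  for (size_t i = 0; i < n; ++i) {
    if (cap > 0) {
      if (ph[i] > cap) ph[i] = cap;
      else if (ph[i] < -cap) ph[i] = -cap;
    }
    bool in = ph[i] < 0;
    if (in) ++n_in;
    if (has_gt) {
      if (gt[i]) { ++ngt; if (in) ++inter; }
    }
  }
  double dice = has_gt ? 2.0 * inter / (double)(n_in + ngt) : NA_REAL;
  return List::create(_["energy"] = energy, _["degenerate"] = degenerate,
                      _["n_in"] = (double)n_in, _["dice"] = dice,
                      _["max_speed"] = maxabs, _["dt"] = dt);
}
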