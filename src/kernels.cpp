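#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D array at continuous 0-based voxel indices.
// Points outside the grid (no full 8-neighbourhood) yield NA.
// [[Rcpp::export]]
NumericVector interp_trilinear_cpp(NumericVector vol, IntegerVector dim,
                                   NumericMatrix idx) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = idx.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  const double eps = 1e-9; // tolerate rounding at the exact grid boundary
  for (int p = 0; p < n; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!(x >= -eps && y >= -eps && z >= -eps &&
          x <= nx - 1 + eps && y <= ny - 1 + eps && z <= nz - 1 + eps)) {
      out[p] = NA_REAL;
      continue;
    }
    if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1; if (y > ny - 1) y = ny - 1; if (z > nz - 1) z = nz - 1;
    int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    const double *b = v + (size_t)i0 + (size_t)nx * (j0 + (size_t)ny * k0);
    const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
    double c00 = b[0] * (1 - fx) + b[sx] * fx;
    double c10 = b[sy] * (1 - fx) + b[sy + sx] * fx;
    double c01 = b[sz] * (1 - fx) + b[sz + sx] * fx;
    double c11 = b[sy + sz] * (1 - fx) + b[sy + sz + sx] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Separable Gaussian smoothing, sigma given in voxels per axis (0 = skip axis).
// [[Rcpp::export]]
NumericVector gauss_smooth3d_cpp(NumericVector vol, IntegerVector dim,
                                 NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + r]; }
    for (auto &w : k) w /= ksum;
    const size_t st = stride[ax];
    const int len = n[ax];
    // iterate over all lines along axis ax
    for (int k2 = 0; k2 < (ax == 2 ? 1 : nz); ++k2)
      for (int j2 = 0; j2 < (ax == 1 ? 1 : ny); ++j2)
        for (int i2 = 0; i2 < (ax == 0 ? 1 : nx); ++i2) {
          size_t base = (size_t)i2 + (size_t)nx * (j2 + (size_t)ny * k2);
          for (int t = 0; t < len; ++t) {
            double acc = 0, wsum = 0;
            int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
            for (int u = lo; u <= hi; ++u) { acc += k[u - t + r] * a[base + st * u]; wsum += k[u - t + r]; }
            b[base + st * t] = acc / wsum;
          }
        }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

static inline void bspline_basis(double u, double w[4]) {
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  w[1] = (4 - 6 * u2 + 3 * u3) / 6.0;
  w[2] = (1 + 3 * u + 3 * u2 - 3 * u3) / 6.0;
  w[3] = u3 / 6.0;
}

// Cubic B-spline FFD displacement at grid-parameter coordinates t (N x 3),
// t = (x - grid_origin)/grid_spacing. disp is (ngx*ngy*ngz) x 3 column-major
// over the control grid. Points without full 4^3 support get NA rows.
// [[Rcpp::export]]
NumericMatrix bspline_disp_cpp(NumericMatrix t, NumericMatrix disp,
                               IntegerVector ng) {
  const int ngx = ng[0], ngy = ng[1], ngz = ng[2];
  const int n = t.nrow();
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; ++p) {
    double tx = t(p, 0), ty = t(p, 1), tz = t(p, 2);
    int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
    // upper support boundary: treat t == n-2 (within eps) as inside
    if (ix == ngx - 2 && tx - (ngx - 2) < 1e-9) ix = ngx - 3;
    if (iy == ngy - 2 && ty - (ngy - 2) < 1e-9) iy = ngy - 3;
    if (iz == ngz - 2 && tz - (ngz - 2) < 1e-9) iz = ngz - 3;
    if (ix < 1 || iy < 1 || iz < 1 || ix > ngx - 3 || iy > ngy - 3 || iz > ngz - 3) {
      out(p, 0) = NA_REAL; out(p, 1) = NA_REAL; out(p, 2) = NA_REAL;
      continue;
    }
    double wx[4], wy[4], wz[4];
    bspline_basis(tx - ix, wx); bspline_basis(ty - iy, wy); bspline_basis(tz - iz, wz);
    double dx = 0, dy = 0, dz = 0;
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b) {
        double wbc = wy[b] * wz[c];
        size_t row0 = (size_t)(ix - 1) + (size_t)ngx * ((iy - 1 + b) + (size_t)ngy * (iz - 1 + c));
        for (int a = 0; a < 4; ++a) {
          double w = wx[a] * wbc;
          size_t row = row0 + a;
          dx += w * disp(row, 0); dy += w * disp(row, 1); dz += w * disp(row, 2);
        }
      }
    out(p, 0) = dx; out(p, 1) = dy; out(p, 2) = dz;
  }
  return out;
}

// NCC and its gradient w.r.t. B-spline control displacements.
// q: N x 3 world points (after the affine part of the chain); F: fixed atlas
// intensities at the originating sample points. The moving value is the
// target interpolated at q + D(q). w2i maps world -> continuous target voxel
// index: idx = A * world + b (A 3x3 row-major, b length 3). t0/ts give the
// grid parameterisation t = (world - t0)/ts. Points mapped outside the
// target (or outside spline support) are excluded from both vectors.
// Returns list(ncc, grad (nctrl x 3), n_used).
// [[Rcpp::export]]
List bspline_ncc_grad_cpp(NumericMatrix q, NumericVector F,
                          NumericVector vol, IntegerVector dim,
                          NumericMatrix A, NumericVector bvec,
                          NumericVector t0, NumericVector ts,
                          NumericMatrix disp, IntegerVector ng,
                          bool want_grad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ngx = ng[0], ngy = ng[1], ngz = ng[2];
  const int n = q.nrow();
  const double *v = vol.begin();
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  std::vector<double> M(n), Fv(n);
  std::vector<int> used; used.reserve(n);
  // per-point cached quantities for the gradient pass
  std::vector<double> gW(want_grad ? (size_t)n * 3 : 0);   // dM/dworld
  std::vector<double> wxs(want_grad ? (size_t)n * 12 : 0); // basis weights
  std::vector<int> cell(want_grad ? (size_t)n * 3 : 0);
  int m = 0;
  double sumF = 0, sumM = 0;
  for (int p = 0; p < n; ++p) {
    double wx_[3] = {q(p, 0), q(p, 1), q(p, 2)};
    double tx = (wx_[0] - t0[0]) / ts[0], ty = (wx_[1] - t0[1]) / ts[1],
           tz = (wx_[2] - t0[2]) / ts[2];
    int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
    if (ix == ngx - 2 && tx - (ngx - 2) < 1e-9) ix = ngx - 3;
    if (iy == ngy - 2 && ty - (ngy - 2) < 1e-9) iy = ngy - 3;
    if (iz == ngz - 2 && tz - (ngz - 2) < 1e-9) iz = ngz - 3;
    if (ix < 1 || iy < 1 || iz < 1 || ix > ngx - 3 || iy > ngy - 3 || iz > ngz - 3)
      continue;
    double wxb[4], wyb[4], wzb[4];
    bspline_basis(tx - ix, wxb); bspline_basis(ty - iy, wyb); bspline_basis(tz - iz, wzb);
    double dx = 0, dy = 0, dz = 0;
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b) {
        double wbc = wyb[b] * wzb[c];
        size_t row0 = (size_t)(ix - 1) + (size_t)ngx * ((iy - 1 + b) + (size_t)ngy * (iz - 1 + c));
        for (int a = 0; a < 4; ++a) {
          double w = wxb[a] * wbc;
          dx += w * disp(row0 + a, 0); dy += w * disp(row0 + a, 1); dz += w * disp(row0 + a, 2);
        }
      }
    double wx2 = wx_[0] + dx, wy2 = wx_[1] + dy, wz2 = wx_[2] + dz;
    // world -> target index
    double X = A(0, 0) * wx2 + A(0, 1) * wy2 + A(0, 2) * wz2 + bvec[0];
    double Y = A(1, 0) * wx2 + A(1, 1) * wy2 + A(1, 2) * wz2 + bvec[1];
    double Z = A(2, 0) * wx2 + A(2, 1) * wy2 + A(2, 2) * wz2 + bvec[2];
    if (!(X >= 0 && Y >= 0 && Z >= 0 && X <= nx - 1 && Y <= ny - 1 && Z <= nz - 1))
      continue;
    int i0 = std::min(std::max((int)std::floor(X), 0), nx - 2);
    int j0 = std::min(std::max((int)std::floor(Y), 0), ny - 2);
    int k0 = std::min(std::max((int)std::floor(Z), 0), nz - 2);
    double fx = X - i0, fy = Y - j0, fz = Z - k0;
    const double *bb = v + (size_t)i0 + sy * j0 + sz * k0;
    double c000 = bb[0], c100 = bb[sx], c010 = bb[sy], c110 = bb[sy + sx];
    double c001 = bb[sz], c101 = bb[sz + sx], c011 = bb[sz + sy], c111 = bb[sz + sy + sx];
    double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
    double val = c0 * (1 - fz) + c1 * fz;
    M[m] = val; Fv[m] = F[p];
    sumF += F[p]; sumM += val;
    if (want_grad) {
      // dM/d(index)
      double gx = ((c100 - c000) * (1 - fy) + (c110 - c010) * fy) * (1 - fz) +
                  ((c101 - c001) * (1 - fy) + (c111 - c011) * fy) * fz;
      double gy = (c10 - c00) * (1 - fz) + (c11 - c01) * fz;
      double gz = c1 - c0;
      // dM/d(world) = A^T * dM/d(index)
      gW[(size_t)m * 3 + 0] = A(0, 0) * gx + A(1, 0) * gy + A(2, 0) * gz;
      gW[(size_t)m * 3 + 1] = A(0, 1) * gx + A(1, 1) * gy + A(2, 1) * gz;
      gW[(size_t)m * 3 + 2] = A(0, 2) * gx + A(1, 2) * gy + A(2, 2) * gz;
      for (int a = 0; a < 4; ++a) {
        wxs[(size_t)m * 12 + a] = wxb[a];
        wxs[(size_t)m * 12 + 4 + a] = wyb[a];
        wxs[(size_t)m * 12 + 8 + a] = wzb[a];
      }
      cell[(size_t)m * 3] = ix; cell[(size_t)m * 3 + 1] = iy; cell[(size_t)m * 3 + 2] = iz;
    }
    ++m;
  }
  if (m < 2) return List::create(_["ncc"] = NA_REAL, _["grad"] = R_NilValue, _["n_used"] = m);
  double mF = sumF / m, mM = sumM / m;
  double sFF = 0, sMM = 0, sFM = 0;
  for (int p = 0; p < m; ++p) {
    double a = Fv[p] - mF, b = M[p] - mM;
    sFF += a * a; sMM += b * b; sFM += a * b;
  }
  if (sFF <= 0 || sMM <= 0)
    return List::create(_["ncc"] = NA_REAL, _["grad"] = R_NilValue, _["n_used"] = m);
  double ncc = sFM / std::sqrt(sFF * sMM);
  if (!want_grad)
    return List::create(_["ncc"] = ncc, _["grad"] = R_NilValue, _["n_used"] = m);
  // dNCC/dM_p = (F_p - mF)/sqrt(sFF*sMM) - ncc*(M_p - mM)/sMM
  NumericMatrix grad((size_t)ngx * ngy * ngz, 3);
  std::fill(grad.begin(), grad.end(), 0.0);
  double inv = 1.0 / std::sqrt(sFF * sMM);
  for (int p = 0; p < m; ++p) {
    double dNdM = (Fv[p] - mF) * inv - ncc * (M[p] - mM) / sMM;
    double ax = dNdM * gW[(size_t)p * 3], ay = dNdM * gW[(size_t)p * 3 + 1],
           az = dNdM * gW[(size_t)p * 3 + 2];
    int ix = cell[(size_t)p * 3], iy = cell[(size_t)p * 3 + 1], iz = cell[(size_t)p * 3 + 2];
    const double *wp = &wxs[(size_t)p * 12];
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b) {
        double wbc = wp[4 + b] * wp[8 + c];
        size_t row0 = (size_t)(ix - 1) + (size_t)ngx * ((iy - 1 + b) + (size_t)ngy * (iz - 1 + c));
        for (int a = 0; a < 4; ++a) {
          double w = wp[a] * wbc;
          grad(row0 + a, 0) += w * ax; grad(row0 + a, 1) += w * ay; grad(row0 + a, 2) += w * az;
        }
      }
  }
  return List::create(_["ncc"] = ncc, _["grad"] = grad, _["n_used"] = m);
}

// Rasterise a tube around a polyline: returns the min distance from each
// voxel centre to the sampled curve, computed only within rmax of the curve
// (Inf elsewhere). Grid is axis-aligned: world = origin + spacing * index.
// [[Rcpp::export]]
NumericVector tube_distance_cpp(IntegerVector dim, NumericVector spacing,
                                NumericVector origin, NumericMatrix curve,
                                double rmax) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz, R_PosInf);
  const int k = curve.nrow();
  for (int s = 0; s < k; ++s) {
    double cx = curve(s, 0), cy = curve(s, 1), cz = curve(s, 2);
    int ilo = std::max(0, (int)std::ceil((cx - rmax - origin[0]) / spacing[0]));
    int ihi = std::min(nx - 1, (int)std::floor((cx + rmax - origin[0]) / spacing[0]));
    int jlo = std::max(0, (int)std::ceil((cy - rmax - origin[1]) / spacing[1]));
    int jhi = std::min(ny - 1, (int)std::floor((cy + rmax - origin[1]) / spacing[1]));
    int klo = std::max(0, (int)std::ceil((cz - rmax - origin[2]) / spacing[2]));
    int khi = std::min(nz - 1, (int)std::floor((cz + rmax - origin[2]) / spacing[2]));
    for (int kk = klo; kk <= khi; ++kk) {
      double dz = origin[2] + spacing[2] * kk - cz;
      for (int jj = jlo; jj <= jhi; ++jj) {
        double dy = origin[1] + spacing[1] * jj - cy;
        double dyz = dy * dy + dz * dz;
        size_t base = (size_t)nx * (jj + (size_t)ny * kk);
        for (int ii = ilo; ii <= ihi; ++ii) {
          double dx = origin[0] + spacing[0] * ii - cx;
          double d2 = dx * dx + dyz;
          double d = std::sqrt(d2);
          if (d < out[base + ii]) out[base + ii] = d;
        }
      }
    }
  }
  return out;
}
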