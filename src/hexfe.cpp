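// Structured-grid voxel finite elements and image morphology kernels.
//
// The mesh is implicit: dims = (nx, ny, nz) elements, each a cube of edge h
// (mm).  Nodes live on the (nx+1) x (ny+1) x (nz+1) lattice; node index
// n = ix + (nx+1) * (iy + (ny+1) * iz), dof index 3*n + c with c in {0,1,2}
// for (x, y, z).  All elements share one reference stiffness matrix K0
// (24 x 24, unit cube, unit modulus) scaled per element by E_e * h.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static inline void element_node_offsets(int nx, int ny, int noff[8]) {
  int k = 0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx)
        noff[k++] = dx + (nx + 1) * (dy + (ny + 1) * dz);
}

// y = K x with K = sum_e E_e * h * K0 (no constraints applied here)
static void matvec(const double* x, double* y,
                   const double* E, const int* dims,
                   const double* K0, double h, int ndof) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int noff[8];
  element_node_offsets(nx, ny, noff);
  std::fill(y, y + ndof, 0.0);
  double xe[24], ye[24];
  long e = 0;
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      long rowbase = (long)(nx + 1) * (iy + (long)(ny + 1) * iz);
      for (int ix = 0; ix < nx; ++ix, ++e) {
        double s = E[e] * h;
        if (s == 0.0) continue;
        long nb = ix + rowbase;
        for (int l = 0; l < 8; ++l) {
          long d = 3 * (nb + noff[l]);
          xe[3 * l]     = x[d];
          xe[3 * l + 1] = x[d + 1];
          xe[3 * l + 2] = x[d + 2];
        }
        for (int i = 0; i < 24; ++i) {
          const double* K0i = K0 + (long)i * 24;  // K0 symmetric
          double acc = 0.0;
          for (int j = 0; j < 24; ++j) acc += K0i[j] * xe[j];
          ye[i] = s * acc;
        }
        for (int l = 0; l < 8; ++l) {
          long d = 3 * (nb + noff[l]);
          y[d]     += ye[3 * l];
          y[d + 1] += ye[3 * l + 1];
          y[d + 2] += ye[3 * l + 2];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".fe_matvec_cpp")]]
NumericVector fe_matvec_cpp(NumericVector x, NumericVector E,
                            IntegerVector dims, NumericMatrix K0, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  long ndof = 3L * (nx + 1) * (ny + 1) * (nz + 1);
  if ((long)x.size() != ndof) stop("x has wrong length");
  NumericVector y(ndof);
  int d[3] = {nx, ny, nz};
  matvec(REAL(x), REAL(y), REAL(E), d, REAL(K0), h, (int)ndof);
  return y;
}

// [[Rcpp::export(name = ".fe_diag_cpp")]]
NumericVector fe_diag_cpp(NumericVector E, IntegerVector dims,
                          NumericMatrix K0, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  long ndof = 3L * (nx + 1) * (ny + 1) * (nz + 1);
  NumericVector dg(ndof);
  double* d = REAL(dg);
  const double* K0p = REAL(K0);
  int noff[8];
  element_node_offsets(nx, ny, noff);
  long e = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      long rowbase = (long)(nx + 1) * (iy + (long)(ny + 1) * iz);
      for (int ix = 0; ix < nx; ++ix, ++e) {
        double s = REAL(E)[e] * h;
        long nb = ix + rowbase;
        for (int l = 0; l < 8; ++l) {
          long dof = 3 * (nb + noff[l]);
          for (int c = 0; c < 3; ++c) {
            int i = 3 * l + c;
            d[dof + c] += s * K0p[(long)i * 24 + i];
          }
        }
      }
    }
  return dg;
}

// Jacobi-preconditioned conjugate gradients on the free dofs.
// dir_idx: 0-based dof indices with prescribed values dir_val.
// [[Rcpp::export(name = ".fe_pcg_cpp")]]
List fe_pcg_cpp(NumericVector E, IntegerVector dims, NumericMatrix K0,
                double h, IntegerVector dir_idx, NumericVector dir_val,
                double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long ndof = 3L * (nx + 1) * (ny + 1) * (nz + 1);
  int dd[3] = {nx, ny, nz};
  const double* K0p = REAL(K0);

  std::vector<char> fixed(ndof, 0);
  std::vector<double> u(ndof, 0.0);
  for (int k = 0; k < dir_idx.size(); ++k) {
    long i = dir_idx[k];
    fixed[i] = 1;
    u[i] = dir_val[k];
  }

  // b = -K u0 restricted to free dofs
  std::vector<double> b(ndof), r(ndof), z(ndof), p(ndof), q(ndof), x(ndof, 0.0);
  matvec(u.data(), b.data(), REAL(E), dd, K0p, h, (int)ndof);
  double bb = 0.0;
  for (long i = 0; i < ndof; ++i) {
    b[i] = fixed[i] ? 0.0 : -b[i];
    bb += b[i] * b[i];
  }
  NumericVector hist;
  if (bb == 0.0) {
    return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                        _["iterations"] = 0, _["relres"] = 0.0,
                        _["converged"] = true, _["history"] = hist);
  }
  std::vector<double> dg(ndof);
  {
    NumericVector dgv = fe_diag_cpp(E, dims, K0, h);
    std::copy(dgv.begin(), dgv.end(), dg.begin());
  }
  const double bnorm = std::sqrt(bb);
  r = b;
  double rz = 0.0;
  for (long i = 0; i < ndof; ++i) {
    z[i] = fixed[i] ? 0.0 : r[i] / dg[i];
    rz += r[i] * z[i];
  }
  p = z;
  std::vector<double> history;
  history.reserve(256);
  double relres = 1.0;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    matvec(p.data(), q.data(), REAL(E), dd, K0p, h, (int)ndof);
    double pq = 0.0;
    for (long i = 0; i < ndof; ++i) {
      if (fixed[i]) q[i] = 0.0;
      pq += p[i] * q[i];
    }
    if (pq <= 0.0) break;  // indefinite/singular: give up
    double alpha = rz / pq;
    double rr = 0.0;
    for (long i = 0; i < ndof; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * q[i];
      rr += r[i] * r[i];
    }
    relres = std::sqrt(rr) / bnorm;
    history.push_back(relres);
    if (relres <= tol) { converged = true; break; }
    double rznew = 0.0;
    for (long i = 0; i < ndof; ++i) {
      z[i] = fixed[i] ? 0.0 : r[i] / dg[i];
      rznew += r[i] * z[i];
    }
    double beta = rznew / rz;
    rz = rznew;
    for (long i = 0; i < ndof; ++i) p[i] = z[i] + beta * p[i];
  }
  for (long i = 0; i < ndof; ++i) u[i] += x[i];
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["iterations"] = it > maxit ? maxit : it,
                      _["relres"] = relres, _["converged"] = converged,
                      _["history"] = NumericVector(history.begin(), history.end()));
}

// Strain components at element centroids: (exx, eyy, ezz, gxy, gyz, gxz).
// For trilinear hexahedra the centroid strain equals the mean over the
// 2x2x2 Gauss points (shape-function gradients are multilinear).
// [[Rcpp::export(name = ".fe_centroid_strain_cpp")]]
NumericMatrix fe_centroid_strain_cpp(NumericVector u, IntegerVector dims,
                                     double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long ne = (long)nx * ny * nz;
  NumericMatrix eps(ne, 6);
  const double* up = REAL(u);
  int noff[8];
  element_node_offsets(nx, ny, noff);
  int sgx[8], sgy[8], sgz[8];
  for (int l = 0; l < 8; ++l) {
    sgx[l] = (l & 1) ? 1 : -1;
    sgy[l] = (l & 2) ? 1 : -1;
    sgz[l] = (l & 4) ? 1 : -1;
  }
  const double c = 1.0 / (4.0 * h);
  long e = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      long rowbase = (long)(nx + 1) * (iy + (long)(ny + 1) * iz);
      for (int ix = 0; ix < nx; ++ix, ++e) {
        long nb = ix + rowbase;
        double exx = 0, eyy = 0, ezz = 0, gxy = 0, gyz = 0, gxz = 0;
        for (int l = 0; l < 8; ++l) {
          long d = 3 * (nb + noff[l]);
          double ux = up[d], uy = up[d + 1], uz = up[d + 2];
          exx += sgx[l] * ux;
          eyy += sgy[l] * uy;
          ezz += sgz[l] * uz;
          gxy += sgy[l] * ux + sgx[l] * uy;
          gyz += sgz[l] * uy + sgy[l] * uz;
          gxz += sgz[l] * ux + sgx[l] * uz;
        }
        eps(e, 0) = c * exx; eps(e, 1) = c * eyy; eps(e, 2) = c * ezz;
        eps(e, 3) = c * gxy; eps(e, 4) = c * gyz; eps(e, 5) = c * gxz;
      }
    }
  return eps;
}

// 3D connected-component labelling (6- or 26-connectivity), BFS.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  if ((long)mask.size() != n) stop("mask has wrong length");
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dx, dy, dz});
      }
  std::vector<long> stack;
  int cur = 0;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      long v = stack.back();
      stack.pop_back();
      int ix = v % nx, iy = (v / nx) % ny, iz = v / ((long)nx * ny);
      for (size_t k = 0; k < nb.size(); ++k) {
        int jx = ix + nb[k][0], jy = iy + nb[k][1], jz = iz + nb[k][2];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        long w = jx + (long)nx * (jy + (long)ny * jz);
        if (mask[w] && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// Chebyshev (L-inf) dilation by integer radius, separable max filter.
// [[Rcpp::export(name = ".dilate_chebyshev_cpp")]]
LogicalVector dilate_chebyshev_cpp(LogicalVector mask, IntegerVector dims,
                                   int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  std::vector<char> a(n), b(n);
  for (long i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  // pass along x
  for (long iz = 0; iz < nz; ++iz)
    for (long iy = 0; iy < ny; ++iy) {
      long base = nx * (iy + (long)ny * iz);
      for (int ix = 0; ix < nx; ++ix) {
        char v = 0;
        int lo = std::max(0, ix - radius), hi = std::min(nx - 1, ix + radius);
        for (int j = lo; j <= hi && !v; ++j) v = a[base + j];
        b[base + ix] = v;
      }
    }
  // pass along y
  for (long iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      long base = ix + (long)nx * ny * iz;
      for (int iy = 0; iy < ny; ++iy) {
        char v = 0;
        int lo = std::max(0, iy - radius), hi = std::min(ny - 1, iy + radius);
        for (int j = lo; j <= hi && !v; ++j) v = b[base + (long)nx * j];
        a[base + (long)nx * iy] = v;
      }
    }
  // pass along z
  LogicalVector out(n);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      long base = ix + (long)nx * iy;
      for (int iz = 0; iz < nz; ++iz) {
        char v = 0;
        int lo = std::max(0, iz - radius), hi = std::min(nz - 1, iz + radius);
        for (int j = lo; j <= hi && !v; ++j) v = a[base + (long)nx * ny * j];
        out[base + (long)nx * ny * iz] = v != 0;
      }
    }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const double* f, double* d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Euclidean distance (in pixels) to the nearest TRUE pixel of a 2D mask.
// [[Rcpp::export(name = ".edt2d_cpp")]]
NumericMatrix edt2d_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e20;
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) g(i, j) = mask(i, j) ? 0.0 : BIG;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {  // transform along rows (index i)
    for (int i = 0; i < nr; ++i) f[i] = g(i, j);
    dt1d(f.data(), d.data(), nr);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) {  // then along columns (index j)
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    dt1d(f.data(), d.data(), nc);
    for (int j = 0; j < nc; ++j) g(i, j) = std::sqrt(d[j]);
  }
  return g;
}
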