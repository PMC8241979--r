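#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Matrix-free voxel FE operator: every voxel is one 8-node hexahedral element
// sharing a reference stiffness Kref (unit Young's modulus), scaled per
// element by Ee. Node (i,j,k) on the (nx+1)(ny+1)(nz+1) grid has dofs
// 3*id..3*id+2 with id = i + (nx+1)*(j + (ny+1)*k). Corner order is
// lexicographic (x fastest), matching the R-side element stiffness.

struct VoxelOp {
  int nx, ny, nz, nnx, nny, nnz;
  std::size_t ndof;
  const double* Kr;   // 24x24, symmetric, column-major
  const double* Ee;   // element moduli, length nx*ny*nz
  int noff[8];

  VoxelOp(int nx_, int ny_, int nz_, const double* Kr_, const double* Ee_)
      : nx(nx_), ny(ny_), nz(nz_), nnx(nx_ + 1), nny(ny_ + 1), nnz(nz_ + 1),
        Kr(Kr_), Ee(Ee_) {
    ndof = 3 * (std::size_t)nnx * nny * nnz;
    int c = 0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx)
          noff[c++] = dx + nnx * (dy + nny * dz);
  }

  // y = K x over all dofs (no boundary conditions applied)
  void matvec(const double* x, double* y) const {
    std::fill(y, y + ndof, 0.0);
    std::size_t e = 0;
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        std::size_t nrow = (std::size_t)j * nnx + (std::size_t)k * nnx * nny;
        for (int i = 0; i < nx; ++i, ++e) {
          const double E = Ee[e];
          std::size_t n0 = nrow + i;
          std::size_t idx[24];
          for (int a = 0; a < 8; ++a) {
            std::size_t base = 3 * (n0 + noff[a]);
            idx[3 * a] = base; idx[3 * a + 1] = base + 1; idx[3 * a + 2] = base + 2;
          }
          double ul[24];
          for (int a = 0; a < 24; ++a) ul[a] = x[idx[a]];
          for (int a = 0; a < 24; ++a) {
            const double* col = Kr + 24 * a;  // symmetric: col == row
            double s = 0.0;
            for (int b = 0; b < 24; ++b) s += col[b] * ul[b];
            y[idx[a]] += E * s;
          }
        }
      }
    }
  }

  // per-element strain energy W_e = 0.5 * u' K_e u
  void energies(const double* u, double* w) const {
    std::size_t e = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        std::size_t nrow = (std::size_t)j * nnx + (std::size_t)k * nnx * nny;
        for (int i = 0; i < nx; ++i, ++e) {
          std::size_t n0 = nrow + i;
          double ul[24];
          for (int a = 0; a < 8; ++a) {
            std::size_t base = 3 * (n0 + noff[a]);
            ul[3 * a] = u[base]; ul[3 * a + 1] = u[base + 1]; ul[3 * a + 2] = u[base + 2];
          }
          double q = 0.0;
          for (int a = 0; a < 24; ++a) {
            const double* col = Kr + 24 * a;
            double s = 0.0;
            for (int b = 0; b < 24; ++b) s += col[b] * ul[b];
            q += ul[a] * s;
          }
          w[e] = 0.5 * Ee[e] * q;
        }
      }
  }

  void diagonal(double* d) const {
    std::fill(d, d + ndof, 0.0);
    std::size_t e = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        std::size_t nrow = (std::size_t)j * nnx + (std::size_t)k * nnx * nny;
        for (int i = 0; i < nx; ++i, ++e) {
          const double E = Ee[e];
          std::size_t n0 = nrow + i;
          for (int a = 0; a < 8; ++a) {
            std::size_t base = 3 * (n0 + noff[a]);
            d[base]     += E * Kr[25 * (3 * a)];
            d[base + 1] += E * Kr[25 * (3 * a + 1)];
            d[base + 2] += E * Kr[25 * (3 * a + 2)];
          }
        }
      }
  }
};

// Jacobi-preconditioned conjugate gradients on the free dofs of the
// displacement-constrained voxel problem. `fixed` marks Dirichlet dofs whose
// values are already set in `u`; the reduced right-hand side is -K_fc u_c.
// [[Rcpp::export(name = ".cg_solve_voxel")]]
List cg_solve_voxel(NumericVector Ee, IntegerVector nel, NumericMatrix Kref,
                    LogicalVector fixed, NumericVector u_init,
                    double tol, int maxit) {
  const int nx = nel[0], ny = nel[1], nz = nel[2];
  if ((std::size_t)nx * ny * nz != (std::size_t)Ee.size())
    stop("element modulus vector does not match the grid");
  VoxelOp op(nx, ny, nz, REAL(Kref), REAL(Ee));
  const std::size_t n = op.ndof;
  if ((std::size_t)fixed.size() != n || (std::size_t)u_init.size() != n)
    stop("boundary-condition vectors do not match the grid");

  std::vector<double> u(u_init.begin(), u_init.end());
  std::vector<double> r(n), z(n), p(n), q(n), diag(n);
  op.diagonal(diag.data());
  for (std::size_t i = 0; i < n; ++i)
    if (diag[i] <= 0.0) diag[i] = 1.0;  // isolated node guard

  // residual of the reduced system at the initial guess
  op.matvec(u.data(), r.data());
  double bnorm2 = 0.0;
  {
    // reference norm: rhs of the reduced system, -(K u_c) on free dofs
    std::vector<double> uc(n, 0.0), t(n);
    for (std::size_t i = 0; i < n; ++i) if (fixed[i]) uc[i] = u[i];
    op.matvec(uc.data(), t.data());
    for (std::size_t i = 0; i < n; ++i)
      if (!fixed[i]) bnorm2 += t[i] * t[i];
  }
  for (std::size_t i = 0; i < n; ++i) r[i] = fixed[i] ? 0.0 : -r[i];

  const double bnorm = std::sqrt(bnorm2);
  std::vector<double> history;
  double rnorm2 = 0.0;
  for (std::size_t i = 0; i < n; ++i) rnorm2 += r[i] * r[i];
  double relres = bnorm > 0 ? std::sqrt(rnorm2) / bnorm : 0.0;
  history.push_back(relres);

  int it = 0;
  bool converged = relres <= tol;
  double rz = 0.0;
  while (!converged && it < maxit) {
    for (std::size_t i = 0; i < n; ++i) z[i] = fixed[i] ? 0.0 : r[i] / diag[i];
    double rz_new = 0.0;
    for (std::size_t i = 0; i < n; ++i) rz_new += r[i] * z[i];
    if (it == 0) {
      p = z;
    } else {
      const double beta = rz_new / rz;
      for (std::size_t i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    }
    rz = rz_new;
    op.matvec(p.data(), q.data());
    for (std::size_t i = 0; i < n; ++i) if (fixed[i]) q[i] = 0.0;
    double pq = 0.0;
    for (std::size_t i = 0; i < n; ++i) pq += p[i] * q[i];
    if (pq <= 0.0) break;  // loss of positive-definiteness (should not occur)
    const double alpha = rz / pq;
    rnorm2 = 0.0;
    for (std::size_t i = 0; i < n; ++i) {
      u[i] += alpha * p[i];
      r[i] -= alpha * q[i];
      rnorm2 += r[i] * r[i];
    }
    ++it;
    relres = bnorm > 0 ? std::sqrt(rnorm2) / bnorm : 0.0;
    history.push_back(relres);
    converged = relres <= tol;
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  // nodal forces (reactions at constrained dofs) and element energies
  std::vector<double> f(n);
  op.matvec(u.data(), f.data());
  std::vector<double> w((std::size_t)nx * ny * nz);
  op.energies(u.data(), w.data());

  return List::create(
      _["u"] = NumericVector(u.begin(), u.end()),
      _["f"] = NumericVector(f.begin(), f.end()),
      _["energy"] = NumericVector(w.begin(), w.end()),
      _["iterations"] = it,
      _["relres"] = relres,
      _["converged"] = converged,
      _["history"] = NumericVector(history.begin(), history.end()));
}
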