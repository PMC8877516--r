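#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation for the linearized
// finite-difference Poisson-Boltzmann system
//
//   sum_edges eps_e (phi_nb - phi_0) - kap_0 phi_0 = -src_0
//
// phi      : nx*ny*nz potential, column-major (i fastest); boundary layer
//            holds Dirichlet values and is never updated
// epsx/y/z : edge dielectric; epsx[i,j,k] is the edge from node (i,j,k)
//            to (i+1,j,k), etc. (last slab along own axis unused)
// kap      : eps_out * kappa^2 * h^2 per node (0 in the ion-exclusion zone)
// src      : 4*pi*C_coul*q/h per node (0 off charge-bearing nodes)
//
// Returns the iteration count and final max |update| in kT/e.
// [[Rcpp::export(name = ".sor_solve")]]
List sor_solve(NumericVector phi,
               NumericVector epsx, NumericVector epsy, NumericVector epsz,
               NumericVector kap, NumericVector src,
               IntegerVector dims, double omega, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double *p  = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *kp = REAL(kap), *sr = REAL(src);
  double maxd = R_PosInf;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    maxd = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((j + k + 1 + color) & 1);
          R_xlen_t base = sy * j + sz * k;
          for (int i = istart; i < nx - 1; i += 2) {
            R_xlen_t id = base + i;
            double exm = ex[id - sx], exp_ = ex[id];
            double eym = ey[id - sy], eyp = ey[id];
            double ezm = ez[id - sz], ezp = ez[id];
            double num = exm * p[id - sx] + exp_ * p[id + sx]
                       + eym * p[id - sy] + eyp * p[id + sy]
                       + ezm * p[id - sz] + ezp * p[id + sz]
                       + sr[id];
            double den = exm + exp_ + eym + eyp + ezm + ezp + kp[id];
            double gs  = num / den;
            double d   = omega * (gs - p[id]);
            p[id] += d;
            d = std::fabs(d);
            if (d > maxd) maxd = d;
          }
        }
      }
    }
    if (maxd < tol) break;
  }
  bool conv = maxd < tol;
  if (it > maxit) it = maxit;
  return List::create(_["iterations"] = it,
                      _["max_update"] = maxd,
                      _["converged"]  = conv);
}
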