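#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Jacobi-preconditioned conjugate gradient for the symmetric positive
// semi-definite finite-volume Laplacian stored in compressed sparse column
// form (identical to CSR by symmetry). The pure-Neumann operator has the
// constant vector in its null space; the right-hand side is projected onto
// its orthogonal complement and the iterate is re-centered every iteration
// so the solve stays in the quotient space.
// [[Rcpp::export]]
List cg_neumann(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                NumericVector b, double tol, int maxit) {
  const int n = b.size();
  const int *ap = Ap.begin();
  const int *ai = Ai.begin();
  const double *ax = Ax.begin();
  std::vector<double> diag(n, 0.0);
  for (int col = 0; col < n; ++col)
    for (int k = ap[col]; k < ap[col + 1]; ++k)
      if (ai[k] == col) diag[col] = ax[k];
  for (int i = 0; i < n; ++i)
    if (diag[i] <= 0.0) stop("non-positive diagonal in system matrix");

  std::vector<double> x(n, 0.0), r(n), z(n), p(n), q(n);
  // Project b onto mean-zero (Neumann compatibility).
  double bmean = 0.0;
  for (int i = 0; i < n; ++i) bmean += b[i];
  bmean /= n;
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = b[i] - bmean;
    bnorm += r[i] * r[i];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["x"] = NumericVector(n), _["iterations"] = 0,
                        _["relres"] = 0.0, _["converged"] = true);
  }

  double rz = 0.0;
  for (int i = 0; i < n; ++i) {
    z[i] = r[i] / diag[i];
    p[i] = z[i];
    rz += r[i] * z[i];
  }

  double relres = 1.0;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    // q = A p (CSC; columns double as rows by symmetry)
    std::fill(q.begin(), q.end(), 0.0);
    for (int col = 0; col < n; ++col) {
      const double pc = p[col];
      if (pc == 0.0) continue;
      for (int k = ap[col]; k < ap[col + 1]; ++k) q[ai[k]] += ax[k] * pc;
    }
    double pq = 0.0;
    for (int i = 0; i < n; ++i) pq += p[i] * q[i];
    if (pq <= 0.0) break; // numerical breakdown (null-space drift)
    const double alpha = rz / pq;
    double rnorm = 0.0, xmean = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * q[i];
      rnorm += r[i] * r[i];
      xmean += x[i];
    }
    xmean /= n;
    for (int i = 0; i < n; ++i) x[i] -= xmean;
    relres = std::sqrt(rnorm) / bnorm;
    if (relres <= tol) break;
    double rz_new = 0.0, rmean = 0.0;
    for (int i = 0; i < n; ++i) rmean += r[i];
    rmean /= n;
    for (int i = 0; i < n; ++i) {
      r[i] -= rmean;
      z[i] = r[i] / diag[i];
      rz_new += r[i] * z[i];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = std::min(it, maxit),
                      _["relres"] = relres,
                      _["converged"] = relres <= tol);
}

// Breadth-first reachability over the 6-connected conductive voxel graph.
// `cond` is a logical grid flattened in column-major order with dimensions
// `dims`; `seeds` are 1-based linear indices. Returns a logical vector
// marking every conductive voxel reachable from the seeds.
// [[Rcpp::export]]
LogicalVector reachable_voxels(LogicalVector cond, IntegerVector dims,
                               IntegerVector seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector seen(n, false);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t v = seeds[s] - 1;
    if (v >= 0 && v < n && cond[v] && !seen[v]) {
      seen[v] = true;
      q.push(v);
    }
  }
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  while (!q.empty()) {
    R_xlen_t v = q.front();
    q.pop();
    const int ix = v % nx, iy = (v / nx) % ny, iz = v / sz;
    const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
    const bool ok[6] = {ix > 0, ix < nx - 1, iy > 0, iy < ny - 1,
                        iz > 0, iz < nz - 1};
    for (int k = 0; k < 6; ++k) {
      if (ok[k] && cond[nb[k]] && !seen[nb[k]]) {
        seen[nb[k]] = true;
        q.push(nb[k]);
      }
    }
  }
  return seen;
}
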