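#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Matrix-free 7-point matvec for a structured grid.
// y = diag .* x - sum over faces of G * x_neighbor.
// G arrays hold one conductance per interior face along each index direction;
// faces adjacent to Dirichlet or insulated cells must be pre-zeroed by the
// caller (their contribution is folded into rhs / the unit diagonal).
static void matvec(int n1, int n2, int n3,
                   const double* G1, const double* G2, const double* G3,
                   const double* diag, const double* x, double* y) {
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  for (R_xlen_t id = 0; id < n; ++id) y[id] = diag[id] * x[id];
  // faces along dim 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      R_xlen_t fb = (R_xlen_t)(n1 - 1) * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1 - 1; ++i) {
        double g = G1[fb + i];
        if (g != 0.0) {
          y[base + i]     -= g * x[base + i + 1];
          y[base + i + 1] -= g * x[base + i];
        }
      }
    }
  // faces along dim 2
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2 - 1; ++j) {
      R_xlen_t a = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      R_xlen_t b = (R_xlen_t)n1 * (j + 1 + (R_xlen_t)n2 * k);
      R_xlen_t fb = (R_xlen_t)n1 * (j + (R_xlen_t)(n2 - 1) * k);
      for (int i = 0; i < n1; ++i) {
        double g = G2[fb + i];
        if (g != 0.0) {
          y[a + i] -= g * x[b + i];
          y[b + i] -= g * x[a + i];
        }
      }
    }
  // faces along dim 3
  if (n3 > 1)
    for (int k = 0; k < n3 - 1; ++k) {
      R_xlen_t a = (R_xlen_t)n1 * n2 * k;
      R_xlen_t b = (R_xlen_t)n1 * n2 * (k + 1);
      const double* Gk = G3 + (R_xlen_t)n1 * n2 * k;
      for (R_xlen_t i = 0; i < (R_xlen_t)n1 * n2; ++i) {
        double g = Gk[i];
        if (g != 0.0) {
          y[a + i] -= g * x[b + i];
          y[b + i] -= g * x[a + i];
        }
      }
    }
}

// Jacobi-preconditioned conjugate gradient for the SPD backward-Euler system.
// [[Rcpp::export(name = ".pcg_structured")]]
List pcg_structured(int n1, int n2, int n3,
                    NumericVector G1, NumericVector G2, NumericVector G3,
                    NumericVector diag, NumericVector rhs, NumericVector x0,
                    double tol, int maxit) {
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (diag.size() != n || rhs.size() != n || x0.size() != n)
    stop("pcg: inconsistent vector lengths");
  NumericVector x = clone(x0);
  std::vector<double> r(n), z(n), p(n), Ap(n);
  matvec(n1, n2, n3, G1.begin(), G2.begin(), G3.begin(), diag.begin(),
         x.begin(), Ap.data());
  double bnorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    r[i] = rhs[i] - Ap[i];
    bnorm += rhs[i] * rhs[i];
  }
  bnorm = std::sqrt(bnorm);
  double stop_norm = tol * (bnorm > 0 ? bnorm : 1.0);
  double rz = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    z[i] = r[i] / diag[i];
    p[i] = z[i];
    rz += r[i] * z[i];
  }
  int it = 0;
  double rnorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) rnorm += r[i] * r[i];
  rnorm = std::sqrt(rnorm);
  while (rnorm > stop_norm && it < maxit) {
    matvec(n1, n2, n3, G1.begin(), G2.begin(), G3.begin(), diag.begin(),
           p.data(), Ap.data());
    double pAp = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) stop("pcg: matrix not positive definite");
    double alpha = rz / pAp;
    rnorm = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rnorm += r[i] * r[i];
    }
    rnorm = std::sqrt(rnorm);
    double rz_new = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      z[i] = r[i] / diag[i];
      rz_new += r[i] * z[i];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    ++it;
  }
  bool converged = rnorm <= stop_norm;
  return List::create(_["x"] = x, _["iterations"] = it,
                      _["relres"] = bnorm > 0 ? rnorm / bnorm : rnorm,
                      _["converged"] = converged);
}

// 6-connected component labeling of a logical mask on a structured grid.
// Returns integer labels (0 outside the mask, 1..n_components inside).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, int n1, int n2, int n3) {
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("label_components: mask length mismatch");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    stack.push_back(seed);
    lab[seed] = next;
    while (!stack.empty()) {
      R_xlen_t id = stack.back();
      stack.pop_back();
      int i = id % n1;
      int j = (id / n1) % n2;
      int k = id / ((R_xlen_t)n1 * n2);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
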