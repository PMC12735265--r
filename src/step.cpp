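#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fused backward-Euler step for the Pennes/enthalpy solver. Mirrors the R
// reference implementation (step_implicit) but keeps the Picard loop, face
// conductances, property evaluation and CG solve in one compiled pass.

struct Props {
  double ku, kf, cu, cf, rhou, rhof, Qlf, Tmu, Tml, wb, rhob, cb, Tb, Qm;
  double Cu, Cf, Cm, Hml, Hmu, Tref;
  void init() {
    Cu = rhou * cu; Cf = rhof * cf;
    Cm = (rhou + rhof) / 2.0 * (cu + cf) / 2.0 + Qlf / (Tmu - Tml);
    Tref = -200.0;
    Hml = Cf * (Tml - Tref);
    Hmu = Hml + Cm * (Tmu - Tml);
  }
  inline double cond(double T) const {
    if (T > Tmu) return ku;
    if (T < Tml) return kf;
    return (ku + kf) / 2.0;
  }
  inline double cap(double T) const {
    if (T > Tmu) return Cu;
    if (T < Tml) return Cf;
    return Cm;
  }
  inline double enth(double T) const {
    if (T < Tml) return Cf * (T - Tref);
    if (T > Tmu) return Hmu + Cu * (T - Tmu);
    return Hml + Cm * (T - Tml);
  }
  inline double frac(double T) const {
    double f = (Tmu - T) / (Tmu - Tml);
    return f < 0 ? 0 : (f > 1 ? 1 : f);
  }
  // exact solve of (Vdt)(H(T)-Hn) + p T = q  (monotone piecewise linear)
  inline double scalar_solve(double Hn, double Vdt, double p, double q) const {
    double Tf2 = (q + Vdt * (Hn - Hml + Cf * Tml)) / (Vdt * Cf + p);
    if (Tf2 < Tml) return Tf2;
    double Tl2 = (q + Vdt * (Hn - Hmu + Cu * Tmu)) / (Vdt * Cu + p);
    if (Tl2 > Tmu) return Tl2;
    return (q + Vdt * (Hn - Hml + Cm * Tml)) / (Vdt * Cm + p);
  }
};

static inline double harm2(double a, double b) { return 2.0 * a * b / (a + b); }

// matvec y = diag x - sum G x_nb (G zero across non-open faces)
static void matvec2(int n1, int n2, int n3, const std::vector<double>& G1,
                    const std::vector<double>& G2, const std::vector<double>& G3,
                    const std::vector<double>& diag, const double* x, double* y) {
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  for (R_xlen_t i = 0; i < n; ++i) y[i] = diag[i] * x[i];
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      R_xlen_t fb = (R_xlen_t)(n1 - 1) * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1 - 1; ++i) {
        double g = G1[fb + i];
        if (g != 0.0) {
          y[base + i] -= g * x[base + i + 1];
          y[base + i + 1] -= g * x[base + i];
        }
      }
    }
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
  if (n3 > 1)
    for (int k = 0; k < n3 - 1; ++k) {
      R_xlen_t a = (R_xlen_t)n1 * n2 * k;
      R_xlen_t b = (R_xlen_t)n1 * n2 * (k + 1);
      const double* Gk = G3.data() + (R_xlen_t)n1 * n2 * k;
      for (R_xlen_t i = 0; i < (R_xlen_t)n1 * n2; ++i) {
        double g = Gk[i];
        if (g != 0.0) {
          y[a + i] -= g * x[b + i];
          y[b + i] -= g * x[a + i];
        }
      }
    }
}

// [[Rcpp::export(name = ".bioheat_step_cpp")]]
List bioheat_step_cpp(IntegerVector dims, NumericVector Tn_in,
                      NumericVector V, NumericVector fac1, NumericVector fac2,
                      NumericVector fac3, IntegerVector ctype,
                      List tissue, bool frozen_shutdown, double dt,
                      double Tfix, NumericVector q_extra,
                      double picard_tol, int picard_max,
                      double lin_tol, int lin_maxit) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  Props P;
  P.ku = tissue["k_u"]; P.kf = tissue["k_f"];
  P.cu = tissue["c_u"]; P.cf = tissue["c_f"];
  P.rhou = tissue["rho_u"]; P.rhof = tissue["rho_f"];
  P.Qlf = tissue["Q_lf"]; P.Tmu = tissue["T_mu"]; P.Tml = tissue["T_ml"];
  P.wb = tissue["w_b"]; P.rhob = tissue["rho_b"]; P.cb = tissue["c_b"];
  P.Tb = tissue["T_b"]; P.Qm = tissue["Q_m"];
  P.init();
  const double wbc = P.wb * P.rhob * P.cb;
  const bool qx_vec = q_extra.size() == n;
  const double qx0 = q_extra.size() == 1 ? q_extra[0] : 0.0;

  std::vector<double> T(Tn_in.begin(), Tn_in.end());   // current iterate
  std::vector<double> Tn(Tn_in.begin(), Tn_in.end());
  std::vector<double> Hn(n);
  for (R_xlen_t i = 0; i < n; ++i) Hn[i] = P.enth(Tn[i]);
  std::vector<double> kcell(n), diag(n), rhs(n), damp(n, 1.0), dprev(n, 0.0);
  const R_xlen_t nf1 = (R_xlen_t)(n1 - 1) * n2 * n3;
  const R_xlen_t nf2 = (R_xlen_t)n1 * (n2 - 1) * n3;
  const R_xlen_t nf3 = n3 > 1 ? (R_xlen_t)n1 * n2 * (n3 - 1) : 0;
  std::vector<double> G1(nf1), G2(nf2), G3(nf3);
  std::vector<double> Sall(n), Sfix(n);
  std::vector<double> r(n), z(n), p(n), Ap(n), x(n);

  auto idx = [n1, n2](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
  };

  // conductivity is piecewise constant in temperature, so face conductances
  // change only when some cell switches phase branch: cache on the branch
  // pattern and skip rebuilds when it is unchanged
  std::vector<signed char> branch(n, -1), branch_new(n);
  auto branches_changed = [&]() {
    bool changed = false;
    for (R_xlen_t i = 0; i < n; ++i) {
      signed char b = T[i] > P.Tmu ? 0 : (T[i] < P.Tml ? 2 : 1);
      branch_new[i] = b;
      if (b != branch[i]) changed = true;
    }
    if (changed) branch.assign(branch_new.begin(), branch_new.end());
    return changed;
  };
  auto build_faces = [&]() {
    std::fill(Sall.begin(), Sall.end(), 0.0);
    std::fill(Sfix.begin(), Sfix.end(), 0.0);
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1 - 1; ++i) {
          R_xlen_t a = idx(i, j, k), b = idx(i + 1, j, k);
          R_xlen_t f = (R_xlen_t)i + (R_xlen_t)(n1 - 1) * (j + (R_xlen_t)n2 * k);
          int ta = ctype[a], tb = ctype[b];
          double g = 0.0;
          if (ta == 0 && tb == 0) {
            g = harm2(kcell[a], kcell[b]) * fac1[f];
            Sall[a] += g; Sall[b] += g;
          } else if (ta == 0 && tb == 1) {
            Sfix[a] += harm2(kcell[a], kcell[b]) * fac1[f];
          } else if (ta == 1 && tb == 0) {
            Sfix[b] += harm2(kcell[a], kcell[b]) * fac1[f];
          }
          G1[f] = g;
        }
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2 - 1; ++j)
        for (int i = 0; i < n1; ++i) {
          R_xlen_t a = idx(i, j, k), b = idx(i, j + 1, k);
          R_xlen_t f = (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)(n2 - 1) * k);
          int ta = ctype[a], tb = ctype[b];
          double g = 0.0;
          if (ta == 0 && tb == 0) {
            g = harm2(kcell[a], kcell[b]) * fac2[f];
            Sall[a] += g; Sall[b] += g;
          } else if (ta == 0 && tb == 1) {
            Sfix[a] += harm2(kcell[a], kcell[b]) * fac2[f];
          } else if (ta == 1 && tb == 0) {
            Sfix[b] += harm2(kcell[a], kcell[b]) * fac2[f];
          }
          G2[f] = g;
        }
    if (n3 > 1)
      for (int k = 0; k < n3 - 1; ++k)
        for (int j = 0; j < n2; ++j)
          for (int i = 0; i < n1; ++i) {
            R_xlen_t a = idx(i, j, k), b = idx(i, j, k + 1);
            R_xlen_t f = a;
            int ta = ctype[a], tb = ctype[b];
            double g = 0.0;
            if (ta == 0 && tb == 0) {
              g = harm2(kcell[a], kcell[b]) * fac3[f];
              Sall[a] += g; Sall[b] += g;
            } else if (ta == 0 && tb == 1) {
              Sfix[a] += harm2(kcell[a], kcell[b]) * fac3[f];
            } else if (ta == 1 && tb == 0) {
              Sfix[b] += harm2(kcell[a], kcell[b]) * fac3[f];
            }
            G3[f] = g;
          }
  };

  auto pcg = [&](double tol, int maxit, double& relres) -> int {
    matvec2(n1, n2, n3, G1, G2, G3, diag, x.data(), Ap.data());
    double bnorm = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      r[i] = rhs[i] - Ap[i];
      bnorm += rhs[i] * rhs[i];
    }
    bnorm = std::sqrt(bnorm);
    double stop_norm = tol * (bnorm > 0 ? bnorm : 1.0);
    double rz = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      z[i] = r[i] / diag[i]; p[i] = z[i]; rz += r[i] * z[i];
    }
    double rnorm = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) rnorm += r[i] * r[i];
    rnorm = std::sqrt(rnorm);
    int it = 0;
    while (rnorm > stop_norm && it < maxit) {
      matvec2(n1, n2, n3, G1, G2, G3, diag, p.data(), Ap.data());
      double pAp = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) pAp += p[i] * Ap[i];
      if (pAp <= 0.0) stop("bioheat step: matrix not positive definite");
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
    relres = bnorm > 0 ? rnorm / bnorm : rnorm;
    if (rnorm > stop_norm) return -1;
    return it;
  };

  int iters = 0, cg_total = 0;
  for (int m = 0; m < picard_max; ++m) {
    ++iters;
    if (branches_changed() || m == 0) {
      for (R_xlen_t i = 0; i < n; ++i) kcell[i] = P.cond(T[i]);
      build_faces();
    }
    for (R_xlen_t i = 0; i < n; ++i) {
      if (ctype[i] != 0) { diag[i] = 1.0; rhs[i] = ctype[i] == 1 ? Tfix : Tn[i];
                           x[i] = rhs[i]; continue; }
      double Hlag = P.enth(T[i]);
      double dT = T[i] - Tn[i];
      double chord = std::fabs(dT) < 1e-9 ? P.cap(T[i]) : (Hlag - Hn[i]) / dT;
      double Ccap = std::max(chord, P.cap(T[i]));
      double scale = frozen_shutdown ? 1.0 - P.frac(T[i]) : 1.0;
      double acoef = wbc * scale;
      double qx = qx_vec ? q_extra[i] : qx0;
      diag[i] = V[i] * Ccap / dt + V[i] * acoef + Sall[i] + Sfix[i];
      rhs[i] = V[i] / dt * (Ccap * T[i] - (Hlag - Hn[i])) +
        V[i] * (acoef * P.Tb + P.Qm * scale + qx) + Sfix[i] * Tfix;
      x[i] = T[i];
    }
    double relres;
    int cg = pcg(lin_tol, lin_maxit, relres);
    if (cg < 0)
      stop("bioheat step: linear solve did not converge (relres %e)", relres);
    cg_total += cg;
    double dmax = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double di = x[i] - T[i];
      if (std::fabs(di) > dmax) dmax = std::fabs(di);
    }
    if (dmax < picard_tol || m == picard_max - 1) {
      T = x;
      break;
    }
    for (R_xlen_t i = 0; i < n; ++i) {
      double di = x[i] - T[i];
      if (di * dprev[i] < 0) damp[i] *= 0.5;
      double step = damp[i] * di;
      dprev[i] = step;
      T[i] += step;
    }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (!std::isfinite(T[i])) stop("bioheat step: non-finite temperature");

  // finish cells violating their own enthalpy balance (stalled at the kink)
  for (int sweep = 0; sweep < 3; ++sweep) {
    if (branches_changed()) {
      for (R_xlen_t i = 0; i < n; ++i) kcell[i] = P.cond(T[i]);
      build_faces();
    }
    // neighbor-weighted sums
    std::fill(Ap.begin(), Ap.end(), 0.0);  // reuse Ap as gsum
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1 - 1; ++i) {
          R_xlen_t a = idx(i, j, k), b = idx(i + 1, j, k);
          R_xlen_t f = (R_xlen_t)i + (R_xlen_t)(n1 - 1) * (j + (R_xlen_t)n2 * k);
          if (G1[f] != 0.0) { Ap[a] += G1[f] * T[b]; Ap[b] += G1[f] * T[a]; }
        }
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2 - 1; ++j)
        for (int i = 0; i < n1; ++i) {
          R_xlen_t a = idx(i, j, k), b = idx(i, j + 1, k);
          R_xlen_t f = (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)(n2 - 1) * k);
          if (G2[f] != 0.0) { Ap[a] += G2[f] * T[b]; Ap[b] += G2[f] * T[a]; }
        }
    if (n3 > 1)
      for (int k = 0; k < n3 - 1; ++k)
        for (int j = 0; j < n2; ++j)
          for (int i = 0; i < n1; ++i) {
            R_xlen_t a = idx(i, j, k), b = idx(i, j, k + 1);
            if (G3[a] != 0.0) { Ap[a] += G3[a] * T[b]; Ap[b] += G3[a] * T[a]; }
          }
    bool any_bad = false;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (ctype[i] != 0) continue;
      double scale = frozen_shutdown ? 1.0 - P.frac(T[i]) : 1.0;
      double acoef = wbc * scale;
      double qx = qx_vec ? q_extra[i] : qx0;
      double pcoef = Sall[i] + Sfix[i] + V[i] * acoef;
      double qcoef = Ap[i] + Sfix[i] * Tfix +
        V[i] * (acoef * P.Tb + P.Qm * scale + qx);
      double resid = V[i] / dt * (P.enth(T[i]) - Hn[i]) + pcoef * T[i] - qcoef;
      double rtol = V[i] / dt * P.cap(T[i]) * picard_tol;
      if (std::fabs(resid) > rtol) {
        T[i] = P.scalar_solve(Hn[i], V[i] / dt, pcoef, qcoef);
        any_bad = true;
      }
    }
    if (!any_bad) break;
  }

  // energy bookkeeping at the final state/coefficients
  if (branches_changed()) {
    for (R_xlen_t i = 0; i < n; ++i) kcell[i] = P.cond(T[i]);
    build_faces();
  }
  double src = 0.0, sink = 0.0, gross = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (ctype[i] != 0) continue;
    double scale = frozen_shutdown ? 1.0 - P.frac(T[i]) : 1.0;
    double qx = qx_vec ? q_extra[i] : qx0;
    src += V[i] * (wbc * scale * (P.Tb - T[i]) + P.Qm * scale + qx) * dt;
    sink += Sfix[i] * (Tfix - T[i]) * dt;
  }
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1 - 1; ++i) {
        R_xlen_t f = (R_xlen_t)i + (R_xlen_t)(n1 - 1) * (j + (R_xlen_t)n2 * k);
        if (G1[f] != 0.0)
          gross += std::fabs(G1[f] * (T[idx(i + 1, j, k)] - T[idx(i, j, k)]));
      }
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2 - 1; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t f = (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)(n2 - 1) * k);
        if (G2[f] != 0.0)
          gross += std::fabs(G2[f] * (T[idx(i, j + 1, k)] - T[idx(i, j, k)]));
      }
  if (n3 > 1)
    for (int k = 0; k < n3 - 1; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          R_xlen_t a = idx(i, j, k);
          if (G3[a] != 0.0)
            gross += std::fabs(G3[a] * (T[idx(i, j, k + 1)] - T[a]));
        }
  gross = gross * dt + std::fabs(src) + std::fabs(sink);

  return List::create(_["T"] = NumericVector(T.begin(), T.end()),
                      _["picard_iters"] = iters,
                      _["cg_iters"] = cg_total,
                      _["source_J"] = src,
                      _["probe_sink_J"] = sink,
                      _["gross_J"] = gross,
                      _["T_fix"] = Tfix);
}
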