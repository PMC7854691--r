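// Augmented-Lagrangian merit function and gradient for the trapezoidal
// collocation transcription of the pacing optimal control problem.
// States v, f, e and control u live on N grid nodes; the decision vector
// is z = c(v, f, e, u). Collocation defects are scaled per metre (the
// energy defect additionally by sc_e); the bend constraint is scaled by
// f_max^2.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sigma_eval1(double e, double e0, double smax,
                                 double srest, double sfinal,
                                 double b1, double b2) {
  if (e >= b2) return smax + (srest - smax) * (e - b2) / (e0 - b2);
  if (e >= b1) return smax;
  double ec = e > 0.0 ? e : 0.0;
  return sfinal + (smax - sfinal) * ec / b1;
}

static inline double sigma_deriv1(double e, double e0, double smax,
                                  double srest, double sfinal,
                                  double b1, double b2) {
  if (e >= b2) return (srest - smax) / (e0 - b2);
  if (e < b1) return (smax - sfinal) / b1;
  return 0.0;
}

// [[Rcpp::export(name = ".ocp_al_eval")]]
List ocp_al_eval(NumericVector z,
                 NumericVector h,
                 NumericVector lamv, NumericVector lamf,
                 NumericVector lame, NumericVector eta,
                 double mu,
                 double tau, double fM, double e0,
                 double smax, double srest, double sfinal,
                 double phi_ramp, double phi_final,
                 double de0, bool clip,
                 NumericVector kap2, NumericVector wq,
                 double sc_e, double reg_eps, bool has_bend,
                 bool want_defects) {
  const int N = wq.size();
  const double b1 = phi_final * e0, b2 = phi_ramp * e0;
  const double fM2 = fM * fM;
  // defects are kept in state-difference units, normalised by the mean
  // spacing, so that penalty rows are equally conditioned on strongly
  // graded grids; the reported violation is per metre
  double Hb = 0.0;
  for (int k = 0; k < N - 1; ++k) Hb += h[k];
  Hb /= (N - 1);

  std::vector<double> a(N), b(N), w(N), psi(N), r(N), dpsi(N);
  const double* v = &z[0];
  const double* f = &z[N];
  const double* e = &z[2 * N];
  const double* u = &z[3 * N];

  for (int j = 0; j < N; ++j) {
    a[j] = f[j] / v[j] - 1.0 / tau;
    b[j] = u[j] / v[j];
    double sig = sigma_eval1(e[j], e0, smax, srest, sfinal, b1, b2);
    double rj = sig - f[j] * v[j];
    double ps, dp = 0.0;
    if (clip) {
      ps = rj <= 0.0 ? 1.0 : 0.0;
    } else if (rj > 0.0) {
      double gap = (e0 - e[j]) / de0;
      if (gap <= 0.0) {
        ps = 0.0;
      } else if (gap >= 1.0) {
        ps = 1.0;
      } else {
        ps = gap;
        dp = -1.0 / de0;
      }
    } else {
      ps = 1.0;
    }
    r[j] = rj;
    psi[j] = ps;
    dpsi[j] = dp;
    w[j] = rj * ps / v[j];
  }

  double J = 0.0;
  for (int j = 0; j < N; ++j) {
    J += wq[j] / v[j] + reg_eps * wq[j] * u[j] * u[j] / v[j];
  }

  std::vector<double> cv(N - 1), cf(N - 1), ce(N - 1);
  double pen = 0.0, viol = 0.0;
  for (int k = 0; k < N - 1; ++k) {
    double hk = h[k];
    cv[k] = (v[k + 1] - v[k] - 0.5 * hk * (a[k] + a[k + 1])) / Hb;
    cf[k] = (f[k + 1] - f[k] - 0.5 * hk * (b[k] + b[k + 1])) / Hb;
    ce[k] = (e[k + 1] - e[k] - 0.5 * hk * (w[k] + w[k + 1])) / (Hb * sc_e);
    pen += lamv[k] * cv[k] + lamf[k] * cf[k] + lame[k] * ce[k] +
      0.5 * mu * (cv[k] * cv[k] + cf[k] * cf[k] + ce[k] * ce[k]);
    // violation in the same state-difference units the penalty controls
    double m = std::max(std::fabs(cv[k]),
                        std::max(std::fabs(cf[k]), std::fabs(ce[k])));
    if (m > viol) viol = m;
  }

  std::vector<double> g(N), mm(N);
  if (has_bend) {
    for (int j = 0; j < N; ++j) {
      g[j] = (f[j] * f[j] + v[j] * v[j] * v[j] * v[j] * kap2[j] - fM2) / fM2;
      mm[j] = std::max(0.0, eta[j] + mu * g[j]);
      pen += (mm[j] * mm[j] - eta[j] * eta[j]) / (2.0 * mu);
      if (g[j] > viol) viol = g[j];
    }
  }

  NumericVector grad(4 * N);
  for (int j = 0; j < N; ++j) {
    double A_prev = j > 0 ? lamv[j - 1] + mu * cv[j - 1] : 0.0;
    double A_next = j < N - 1 ? lamv[j] + mu * cv[j] : 0.0;
    double B_prev = j > 0 ? lamf[j - 1] + mu * cf[j - 1] : 0.0;
    double B_next = j < N - 1 ? lamf[j] + mu * cf[j] : 0.0;
    double C_prev = j > 0 ? lame[j - 1] + mu * ce[j - 1] : 0.0;
    double C_next = j < N - 1 ? lame[j] + mu * ce[j] : 0.0;
    double h_prev = j > 0 ? h[j - 1] : 0.0;
    double h_next = j < N - 1 ? h[j] : 0.0;

    double vj = v[j], fj = f[j], ej = e[j], uj = u[j];
    double dsig = sigma_deriv1(ej, e0, smax, srest, sfinal, b1, b2);
    double dw_dv = -fj * psi[j] / vj - r[j] * psi[j] / (vj * vj);
    double dw_df = -psi[j];
    double dw_de = (dsig * psi[j] + r[j] * dpsi[j]) / vj;
    // multiplier-weighted half-spacings for the trapezoid rhs terms
    double Ah2 = (A_prev * h_prev + A_next * h_next) / (2.0 * Hb);
    double Bh2 = (B_prev * h_prev + B_next * h_next) / (2.0 * Hb);
    double Ch2 = (C_prev * h_prev + C_next * h_next) / (2.0 * Hb);

    double gv = (A_prev - A_next) / Hb + Ah2 * fj / (vj * vj) +
      Bh2 * uj / (vj * vj) - Ch2 * dw_dv / sc_e -
      wq[j] / (vj * vj) - reg_eps * wq[j] * uj * uj / (vj * vj);
    double gf = -Ah2 / vj + (B_prev - B_next) / Hb -
      Ch2 * dw_df / sc_e;
    double ge = (C_prev - C_next) / (Hb * sc_e) -
      Ch2 * dw_de / sc_e;
    double gu = -Bh2 / vj +
      2.0 * reg_eps * wq[j] * uj / vj;

    if (has_bend) {
      gv += mm[j] * (4.0 * vj * vj * vj * kap2[j]) / fM2;
      gf += mm[j] * (2.0 * fj) / fM2;
    }
    grad[j] = gv;
    grad[N + j] = gf;
    grad[2 * N + j] = ge;
    grad[3 * N + j] = gu;
  }

  List out = List::create(
    _["value"] = J + pen,
    _["objective"] = J,
    _["grad"] = grad,
    _["viol"] = viol
  );
  if (want_defects) {
    out["cv"] = NumericVector(cv.begin(), cv.end());
    out["cf"] = NumericVector(cf.begin(), cf.end());
    out["ce"] = NumericVector(ce.begin(), ce.end());
    if (has_bend) out["g"] = NumericVector(g.begin(), g.end());
  }
  return out;
}
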