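// Hot path of the estimation engine: closed-form two-compartment
// concentrations and the per-subject conditional objective. The inner
// eta search evaluates these thousands of times per outer iteration.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double expm1_ratio(double a, double t) {
  // (1 - exp(-a t)) / a, stable as a -> 0
  if (a < 1e-12) return t;
  return -expm1(-a * t) / a;
}

// central concentration (ng/mL) for one dose given at time 0; t >= 0
static void conc_single(const double* t, int n, double dose, double tinf,
                        double CL, double V1, double Q, double V2,
                        double* out) {
  if (dose == 0.0) {
    for (int i = 0; i < n; i++) out[i] = 0.0;
    return;
  }
  double k10 = CL / V1, k12 = Q / V1, k21 = Q / V2;
  double s = k10 + k12 + k21, p = k10 * k21;
  double disc = s * s - 4.0 * p;
  if (disc < 0.0) disc = 0.0;           // rounding guard
  double rt = std::sqrt(disc);
  double a = (s + rt) / 2.0;
  double b = (a > 0.0) ? p / a : 0.0;   // product form avoids cancellation
  double denom = a - b;
  if (denom < 1e-10 * a) {              // near-repeated root
    b = b * (1.0 - 1e-8) - 1e-12;
    denom = a - b;
  }
  double A = (a - k21) / denom, B = (k21 - b) / denom;
  double scale = 1000.0 / V1;           // mg/L -> ng/mL
  if (tinf <= 0.0) {
    for (int i = 0; i < n; i++) {
      double ebt = (b > 0.0) ? std::exp(-b * t[i]) : 1.0;
      out[i] = dose * scale * (A * std::exp(-a * t[i]) + B * ebt);
    }
  } else {
    double R0 = dose / tinf;
    double cA = R0 * scale * A * expm1_ratio(a, tinf);
    double cB = R0 * scale * B * expm1_ratio(b, tinf);
    for (int i = 0; i < n; i++) {
      if (t[i] <= tinf) {
        out[i] = R0 * scale * (A * expm1_ratio(a, t[i]) +
                               B * expm1_ratio(b, t[i]));
      } else {
        double tp = t[i] - tinf;
        double ebt = (b > 0.0) ? std::exp(-b * tp) : 1.0;
        out[i] = cA * std::exp(-a * tp) + cB * ebt;
      }
    }
  }
}

// [[Rcpp::export(.conc2cmt_cpp)]]
NumericVector conc2cmt_cpp(NumericVector t, double dose, double tinf,
                           double CL, double V1, double Q, double V2) {
  int n = t.size();
  NumericVector out(n);
  conc_single(REAL(t), n, dose, tinf, CL, V1, Q, V2, REAL(out));
  return out;
}

// superposition over a dose schedule; dose times <= observation times
// contribute, later doses are ignored for that observation
// [[Rcpp::export(.conc_profile_cpp)]]
NumericVector conc_profile_cpp(NumericVector t, NumericVector dose_time,
                               NumericVector dose_amt,
                               NumericVector dose_dur,
                               double CL, double V1, double Q, double V2) {
  int n = t.size(), nd = dose_time.size();
  NumericVector out(n);
  std::vector<double> rel(n), tmp(n);
  for (int j = 0; j < nd; j++) {
    int m = 0;
    for (int i = 0; i < n; i++) {
      double r = t[i] - dose_time[j];
      if (r >= 0.0) rel[m++] = r;
    }
    if (m == 0) continue;
    conc_single(rel.data(), m, dose_amt[j], dose_dur[j], CL, V1, Q, V2,
                tmp.data());
    int k = 0;
    for (int i = 0; i < n; i++)
      if (t[i] - dose_time[j] >= 0.0) out[i] += tmp[k++];
  }
  return out;
}

struct SubjCtx {
  const double *typ, *oinv, *times, *dv, *dtime, *damt, *ddur;
  const int *bsv_idx;
  int d, n, nd;
  double ldet2piO, sp2, sa2;
};

// concentration profile at eta into f[n]; returns false on overflow
static bool eta_profile(const SubjCtx& c, const double* eta, double* f) {
  double p[4] = {c.typ[0], c.typ[1], c.typ[2], c.typ[3]};
  for (int k = 0; k < c.d; k++) p[c.bsv_idx[k] - 1] *= std::exp(eta[k]);
  for (int i = 0; i < c.n; i++) f[i] = 0.0;
  std::vector<double> rel(c.n), tmp(c.n);
  for (int j = 0; j < c.nd; j++) {
    int m = 0;
    for (int i = 0; i < c.n; i++) {
      double r = c.times[i] - c.dtime[j];
      if (r >= 0.0) rel[m++] = r;
    }
    if (m == 0) continue;
    conc_single(rel.data(), m, c.damt[j], c.ddur[j],
                p[0], p[1], p[2], p[3], tmp.data());
    int k = 0;
    for (int i = 0; i < c.n; i++)
      if (c.times[i] - c.dtime[j] >= 0.0) f[i] += tmp[k++];
  }
  for (int i = 0; i < c.n; i++)
    if (!std::isfinite(f[i])) return false;
  return true;
}

static double cond_obj_core(const SubjCtx& c, const double* eta,
                            double* fbuf) {
  double prior = c.ldet2piO;
  for (int k = 0; k < c.d; k++) {
    if (!std::isfinite(eta[k]) || std::fabs(eta[k]) > 20.0) {
      // sloped plateau so a wandering line search retreats
      double pen = 1e12;
      for (int j = 0; j < c.d; j++)
        if (std::isfinite(eta[j])) pen += std::min(std::fabs(eta[j]), 1e6);
      return pen;
    }
    prior += eta[k] * eta[k] * c.oinv[k];
  }
  if (c.n == 0) return prior;
  if (!eta_profile(c, eta, fbuf)) return 1e12;
  const double LOG2PI = 1.8378770664093454836;
  double ll = 0.0;
  for (int i = 0; i < c.n; i++) {
    double g = c.sp2 * fbuf[i] * fbuf[i] + c.sa2;
    double r = c.dv[i] - fbuf[i];
    ll += LOG2PI + std::log(g) + r * r / g;
  }
  return ll + prior;
}

static SubjCtx make_ctx(NumericVector& typ, IntegerVector& bsv_idx,
                        NumericVector& oinv, double ldet2piO, double sp2,
                        double sa2, NumericVector& times, NumericVector& dv,
                        NumericVector& dose_time, NumericVector& dose_amt,
                        NumericVector& dose_dur) {
  SubjCtx c;
  c.typ = REAL(typ); c.oinv = REAL(oinv);
  c.times = REAL(times); c.dv = REAL(dv);
  c.dtime = REAL(dose_time); c.damt = REAL(dose_amt);
  c.ddur = REAL(dose_dur);
  c.bsv_idx = INTEGER(bsv_idx);
  c.d = oinv.size(); c.n = times.size(); c.nd = dose_time.size();
  c.ldet2piO = ldet2piO; c.sp2 = sp2; c.sa2 = sa2;
  return c;
}

// conditional (penalized) -2 log joint density for one subject, with
// the residual variance evaluated at eta (FOCE-I interaction)
// [[Rcpp::export(.cond_obj_cpp)]]
double cond_obj_cpp(NumericVector eta, NumericVector typ,
                    IntegerVector bsv_idx, NumericVector oinv,
                    double ldet2piO, double sp2, double sa2,
                    NumericVector times, NumericVector dv,
                    NumericVector dose_time, NumericVector dose_amt,
                    NumericVector dose_dur) {
  SubjCtx c = make_ctx(typ, bsv_idx, oinv, ldet2piO, sp2, sa2, times, dv,
                       dose_time, dose_amt, dose_dur);
  std::vector<double> f(std::max(c.n, 1));
  return cond_obj_core(c, REAL(eta), f.data());
}

// solve M x = b for symmetric positive-definite M (d <= 4) by Cholesky
// with ridge escalation; returns false if hopeless
static bool chol_solve(int d, double* M, const double* b, double* x) {
  double ridge = 0.0;
  for (int attempt = 0; attempt < 6; attempt++) {
    double L[16];
    for (int i = 0; i < d * d; i++) L[i] = M[i];
    if (ridge > 0.0) for (int i = 0; i < d; i++) L[i * d + i] += ridge;
    bool ok = true;
    for (int i = 0; i < d && ok; i++) {
      for (int j = 0; j <= i; j++) {
        double s = L[i * d + j];
        for (int k = 0; k < j; k++) s -= L[i * d + k] * L[j * d + k];
        if (i == j) {
          if (s <= 1e-12) { ok = false; break; }
          L[i * d + i] = std::sqrt(s);
        } else L[i * d + j] = s / L[j * d + j];
      }
    }
    if (ok) {
      double y[4];
      for (int i = 0; i < d; i++) {
        double s = b[i];
        for (int k = 0; k < i; k++) s -= L[i * d + k] * y[k];
        y[i] = s / L[i * d + i];
      }
      for (int i = d - 1; i >= 0; i--) {
        double s = y[i];
        for (int k = i + 1; k < d; k++) s -= L[k * d + i] * x[k];
        x[i] = s / L[i * d + i];
      }
      return true;
    }
    double diag_max = 1e-8;
    for (int i = 0; i < d; i++)
      diag_max = std::max(diag_max, std::fabs(M[i * d + i]));
    ridge = (ridge == 0.0) ? 1e-6 * diag_max : ridge * 100.0;
  }
  return false;
}

// damped Newton search for the conditional mode; returns convergence
// flag, leaves the mode in eta, the objective in val and the profile
// at the mode in f
static bool newton_core(const SubjCtx& c, std::vector<double>& eta,
                        double& val, std::vector<double>& f,
                        int maxit, double tol) {
  int d = c.d, n = c.n;
  std::vector<double> fp(n), fm(n), J(n * d);
  val = cond_obj_core(c, eta.data(), f.data());
  if (val >= 1e12) {                      // bad start: reset to zero
    std::fill(eta.begin(), eta.end(), 0.0);
    val = cond_obj_core(c, eta.data(), f.data());
  }
  bool converged = false;
  const double h = 1e-4;
  for (int iter = 0; iter < maxit; iter++) {
    // Jacobian by central differences
    std::vector<double> ep(eta), em(eta);
    for (int k = 0; k < d; k++) {
      ep[k] += h; em[k] -= h;
      if (!eta_profile(c, ep.data(), fp.data()) ||
          !eta_profile(c, em.data(), fm.data())) break;
      for (int i = 0; i < n; i++)
        J[i * d + k] = (fp[i] - fm[i]) / (2.0 * h);
      ep[k] = eta[k]; em[k] = eta[k];
    }
    // gradient of l/2 and Fisher curvature M
    double grad[4], M[16];
    for (int k = 0; k < d; k++) grad[k] = c.oinv[k] * eta[k];
    for (int a = 0; a < d * d; a++) M[a] = 0.0;
    for (int k = 0; k < d; k++) M[k * d + k] = c.oinv[k];
    for (int i = 0; i < n; i++) {
      double fi = f[i];
      double g = c.sp2 * fi * fi + c.sa2;
      double r = c.dv[i] - fi;
      for (int k = 0; k < d; k++) {
        double Jik = J[i * d + k];
        double gk = 2.0 * c.sp2 * fi * Jik;   // dg/deta_k
        grad[k] += 0.5 * (gk / g) * (1.0 - r * r / g) - r * Jik / g;
        for (int l = 0; l <= k; l++) {
          double Jil = J[i * d + l];
          double gl = 2.0 * c.sp2 * fi * Jil;
          double add = Jik * Jil / g + 0.5 * gk * gl / (g * g);
          M[k * d + l] += add;
          if (l != k) M[l * d + k] += add;
        }
      }
    }
    double gnorm = 0.0;
    for (int k = 0; k < d; k++) gnorm = std::max(gnorm, std::fabs(grad[k]));
    if (gnorm < tol) { converged = true; break; }
    double step[4];
    if (!chol_solve(d, M, grad, step)) break;
    // backtracking line search on the full objective
    double t = 1.0, newval = 0.0;
    bool improved = false;
    std::vector<double> cand(d), fc(n);
    for (int ls = 0; ls < 12; ls++) {
      for (int k = 0; k < d; k++) cand[k] = eta[k] - t * step[k];
      newval = cond_obj_core(c, cand.data(), fc.data());
      if (newval < val - 1e-12) { improved = true; break; }
      t *= 0.5;
    }
    if (!improved) { converged = (gnorm < 1e-3); break; }
    double maxstep = 0.0;
    for (int k = 0; k < d; k++) {
      maxstep = std::max(maxstep, std::fabs(t * step[k]));
      eta[k] = cand[k];
    }
    val = newval;
    std::copy(fc.begin(), fc.end(), f.begin());
    if (maxstep < tol) { converged = true; break; }
  }
  return converged;
}

// inner conditional-mode search: damped Newton on the penalized
// objective using the Fisher (Gauss-Newton) curvature, FD Jacobian
// [[Rcpp::export(.inner_newton_cpp)]]
List inner_newton_cpp(NumericVector eta0, NumericVector typ,
                      IntegerVector bsv_idx, NumericVector oinv,
                      double ldet2piO, double sp2, double sa2,
                      NumericVector times, NumericVector dv,
                      NumericVector dose_time, NumericVector dose_amt,
                      NumericVector dose_dur, int maxit, double tol) {
  SubjCtx c = make_ctx(typ, bsv_idx, oinv, ldet2piO, sp2, sa2, times, dv,
                       dose_time, dose_amt, dose_dur);
  std::vector<double> eta(eta0.begin(), eta0.end());
  std::vector<double> f(std::max(c.n, 1));
  double val;
  if (c.d == 0 || c.n == 0) {
    std::fill(eta.begin(), eta.end(), 0.0);
    val = cond_obj_core(c, eta.data(), f.data());
    return List::create(_["eta"] = NumericVector(eta.begin(), eta.end()),
                        _["value"] = val, _["converged"] = true);
  }
  bool converged = newton_core(c, eta, val, f, maxit, tol);
  return List::create(_["eta"] = NumericVector(eta.begin(), eta.end()),
                      _["value"] = val, _["converged"] = converged);
}

// one subject's FOCE-I marginal OFV contribution: solve for the
// conditional mode, linearize there and evaluate
// log det 2*pi*V + r~' V^-1 r~ with V = J Omega J' + diag(g(eta_hat))
// [[Rcpp::export(.subject_foce_cpp)]]
List subject_foce_cpp(NumericVector eta0, NumericVector typ,
                      IntegerVector bsv_idx, NumericVector oinv,
                      double ldet2piO, double sp2, double sa2,
                      NumericVector times, NumericVector dv,
                      NumericVector dose_time, NumericVector dose_amt,
                      NumericVector dose_dur, NumericVector omega,
                      int maxit, double tol) {
  SubjCtx c = make_ctx(typ, bsv_idx, oinv, ldet2piO, sp2, sa2, times, dv,
                       dose_time, dose_amt, dose_dur);
  int d = c.d, n = c.n;
  std::vector<double> eta(eta0.begin(), eta0.end());
  std::vector<double> f(std::max(n, 1));
  double val;
  if (d == 0 || n == 0) {
    std::fill(eta.begin(), eta.end(), 0.0);
    return List::create(_["eta"] = NumericVector(eta.begin(), eta.end()),
                        _["ofv"] = 0.0, _["converged"] = true);
  }
  bool converged = newton_core(c, eta, val, f, maxit, tol);
  // Jacobian at the mode
  const double h = 1e-4;
  std::vector<double> fp(n), fm(n), J(n * d);
  std::vector<double> ep(eta), em(eta);
  for (int k = 0; k < d; k++) {
    ep[k] += h; em[k] -= h;
    if (!eta_profile(c, ep.data(), fp.data()) ||
        !eta_profile(c, em.data(), fm.data()))
      return List::create(_["eta"] = NumericVector(eta.begin(), eta.end()),
                          _["ofv"] = R_PosInf, _["converged"] = false);
    for (int i = 0; i < n; i++) J[i * d + k] = (fp[i] - fm[i]) / (2.0 * h);
    ep[k] = eta[k]; em[k] = eta[k];
  }
  // V (n x n) and residual about the linearized population mean
  std::vector<double> V(n * n, 0.0), rt(n);
  for (int i = 0; i < n; i++) {
    double g = c.sp2 * f[i] * f[i] + c.sa2;
    for (int j = 0; j <= i; j++) {
      double s = 0.0;
      for (int k = 0; k < d; k++)
        s += J[i * d + k] * omega[k] * J[j * d + k];
      V[i * n + j] = s;
      V[j * n + i] = s;
    }
    V[i * n + i] += g;
    double je = 0.0;
    for (int k = 0; k < d; k++) je += J[i * d + k] * eta[k];
    rt[i] = c.dv[i] - f[i] + je;
  }
  // Cholesky: logdet and quadratic form
  std::vector<double> L(n * n, 0.0);
  double logdet = 0.0;
  for (int i = 0; i < n; i++) {
    for (int j = 0; j <= i; j++) {
      double s = V[i * n + j];
      for (int k = 0; k < j; k++) s -= L[i * n + k] * L[j * n + k];
      if (i == j) {
        if (s <= 0.0)
          return List::create(
            _["eta"] = NumericVector(eta.begin(), eta.end()),
            _["ofv"] = R_PosInf, _["converged"] = false);
        L[i * n + i] = std::sqrt(s);
        logdet += 2.0 * std::log(L[i * n + i]);
      } else L[i * n + j] = s / L[j * n + j];
    }
  }
  std::vector<double> y(n);
  double quad = 0.0;
  for (int i = 0; i < n; i++) {
    double s = rt[i];
    for (int k = 0; k < i; k++) s -= L[i * n + k] * y[k];
    y[i] = s / L[i * n + i];
    quad += y[i] * y[i];
  }
  const double LOG2PI = 1.8378770664093454836;
  double ofv = n * LOG2PI + logdet + quad;
  return List::create(_["eta"] = NumericVector(eta.begin(), eta.end()),
                      _["ofv"] = ofv, _["converged"] = converged);
}
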