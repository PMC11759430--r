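#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stefan-Boltzmann constant (W m-2 K-4) and specific gas constant of dry air
// (J kg-1 K-1). Must match the values used in R/constants.R.
static const double SB_CONST = 5.670374419e-8;
static const double R_DRY_AIR = 287.05;

// Saturation vapour pressure (Pa). es_form: 0 = Tetens (over water), 1 = Buck.
static inline double sat_vp(double T, int es_form) {
  double tc = T - 273.15;
  if (es_form == 1)
    return 611.21 * std::exp((18.678 - tc / 234.5) * (tc / (257.14 + tc)));
  return 610.78 * std::exp(17.27 * tc / (tc + 237.3));
}

// Linear interpolation with constant extrapolation on a sorted grid.
static inline double interp1(const NumericVector& x, const NumericVector& y,
                             double t) {
  int n = x.size();
  if (n == 1 || t <= x[0]) return y[0];
  if (t >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - x[lo]) / (x[hi] - x[lo]);
  return y[lo] + w * (y[hi] - y[lo]);
}

struct EBModel {
  // environment trace columns
  NumericVector et, e_Tair, e_RH, e_Trefl;
  // protocol segments
  NumericVector p_t0, p_t1, p_I;
  double Patm, alpha, eps, gbh, gsw, k, Cs, lambda;
  int es_form;

  double irradiance(double t) const {
    int n = p_t0.size();
    for (int i = 0; i < n; ++i)
      if (t >= p_t0[i] && t < p_t1[i]) return p_I[i];
    if (n > 0 && t >= p_t1[n - 1]) return 0.0;  // after protocol: dark
    return 0.0;
  }

  // next protocol boundary strictly greater than t (or +Inf)
  double next_boundary(double t) const {
    double nb = R_PosInf;
    int n = p_t0.size();
    for (int i = 0; i < n; ++i) {
      if (p_t0[i] > t + 1e-12 && p_t0[i] < nb) nb = p_t0[i];
      if (p_t1[i] > t + 1e-12 && p_t1[i] < nb) nb = p_t1[i];
    }
    return nb;
  }

  double rhs(double t, double T, double Is) const {
    double Tair = interp1(et, e_Tair, t);
    double RH = interp1(et, e_RH, t);
    double Trefl = interp1(et, e_Trefl, t);
    double rho_air = Patm / (R_DRY_AIR * Tair);
    double T2 = T * T, Tr2 = Trefl * Trefl;
    double SW = alpha * Is;
    double LW = 2.0 * eps * SB_CONST * (Tr2 * Tr2 - T2 * T2);
    double H = 2.0 * rho_air * Cs * gbh * (T - Tair);
    double gbw = gbh / 0.92;
    double gtw = (gsw <= 0.0 || gbw <= 0.0) ? 0.0
                 : 1.0 / (1.0 / gsw + 1.0 / gbw);
    double VPD = sat_vp(T, es_form) - RH * sat_vp(Tair, es_form);
    double LE = 2.0 * lambda * (0.622 * rho_air / Patm) * gtw * VPD;
    return (SW + LW - H - LE) / k;
  }
};

// Cash-Karp embedded RK45 coefficients
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 3.0 / 10.0, A42 = -9.0 / 10.0, A43 = 6.0 / 5.0;
static const double A51 = -11.0 / 54.0, A52 = 5.0 / 2.0, A53 = -70.0 / 27.0,
                    A54 = 35.0 / 27.0;
static const double A61 = 1631.0 / 55296.0, A62 = 175.0 / 512.0,
                    A63 = 575.0 / 13824.0, A64 = 44275.0 / 110592.0,
                    A65 = 253.0 / 4096.0;
static const double C2 = 1.0 / 5.0, C3 = 3.0 / 10.0, C4 = 3.0 / 5.0, C5 = 1.0,
                    C6 = 7.0 / 8.0;
static const double B1 = 37.0 / 378.0, B3 = 250.0 / 621.0, B4 = 125.0 / 594.0,
                    B6 = 512.0 / 1771.0;
static const double D1 = 2825.0 / 27648.0, D3 = 18575.0 / 48384.0,
                    D4 = 13525.0 / 55296.0, D5 = 277.0 / 14336.0, D6 = 0.25;

// Integrate dT/dt = rhs from out_times[0] to out_times[last], recording T at
// every output time. Steps never cross a protocol boundary, so the
// discontinuous forcing is handled exactly.
// [[Rcpp::export]]
NumericVector integrate_eb_cpp(double T0, NumericVector out_times,
                               NumericMatrix protocol, NumericMatrix env,
                               double Patm, double alpha, double eps,
                               double gbh, double gsw, double k, double Cs,
                               double lambda, int es_form, double rtol,
                               double atol) {
  int n_out = out_times.size();
  NumericVector out(n_out);
  EBModel m;
  m.et = env(_, 0); m.e_Tair = env(_, 1); m.e_RH = env(_, 2);
  m.e_Trefl = env(_, 3);
  m.p_t0 = protocol(_, 0); m.p_t1 = protocol(_, 1); m.p_I = protocol(_, 2);
  m.Patm = Patm; m.alpha = alpha; m.eps = eps; m.gbh = gbh; m.gsw = gsw;
  m.k = k; m.Cs = Cs; m.lambda = lambda; m.es_form = es_form;

  double t = out_times[0], T = T0;
  out[0] = T;
  double h = 0.1;
  long n_steps = 0;
  const long max_steps = 50000000L;

  for (int i = 1; i < n_out; ++i) {
    double t_target = out_times[i];
    if (t_target <= t)
      stop("output times must be strictly increasing");
    while (t < t_target - 1e-12) {
      double h_try = h;
      double nb = m.next_boundary(t);
      if (t + h_try > t_target) h_try = t_target - t;
      if (t + h_try > nb) h_try = nb - t;
      if (h_try < 1e-12) { t = std::min(t_target, nb); continue; }
      // irradiance constant within the step: evaluate at midpoint
      double Is = m.irradiance(t + 0.5 * h_try);
      double k1 = m.rhs(t, T, Is);
      double k2 = m.rhs(t + C2 * h_try, T + h_try * (A21 * k1), Is);
      double k3 = m.rhs(t + C3 * h_try, T + h_try * (A31 * k1 + A32 * k2), Is);
      double k4 = m.rhs(t + C4 * h_try,
                        T + h_try * (A41 * k1 + A42 * k2 + A43 * k3), Is);
      double k5 = m.rhs(t + C5 * h_try,
                        T + h_try * (A51 * k1 + A52 * k2 + A53 * k3 + A54 * k4),
                        Is);
      double k6 = m.rhs(t + C6 * h_try,
                        T + h_try * (A61 * k1 + A62 * k2 + A63 * k3 +
                                     A64 * k4 + A65 * k5), Is);
      double T5 = T + h_try * (B1 * k1 + B3 * k3 + B4 * k4 + B6 * k6);
      double T4 = T + h_try * (D1 * k1 + D3 * k3 + D4 * k4 + D5 * k5 +
                               D6 * k6);
      double sc = atol + rtol * std::max(std::fabs(T), std::fabs(T5));
      double err = std::fabs(T5 - T4) / sc;
      if (!std::isfinite(err))
        stop("energy-balance integration diverged (non-finite state)");
      if (err <= 1.0) {
        t += h_try;
        T = T5;
        double fac = (err == 0.0) ? 5.0 : 0.9 * std::pow(err, -0.2);
        if (fac > 5.0) fac = 5.0;
        h = h_try * fac;
      } else {
        double fac = 0.9 * std::pow(err, -0.25);
        if (fac < 0.1) fac = 0.1;
        h = h_try * fac;
        if (h < 1e-10)
          stop("step size underflow in energy-balance integration");
      }
      if (++n_steps > max_steps)
        stop("maximum number of integration steps exceeded");
    }
    t = t_target;
    out[i] = T;
  }
  return out;
}

// Direct access to the compiled right-hand side (for consistency checks).
// [[Rcpp::export]]
double eb_rhs_cpp(double t, double T, NumericMatrix protocol,
                  NumericMatrix env, double Patm, double alpha, double eps,
                  double gbh, double gsw, double k, double Cs, double lambda,
                  int es_form) {
  EBModel m;
  m.et = env(_, 0); m.e_Tair = env(_, 1); m.e_RH = env(_, 2);
  m.e_Trefl = env(_, 3);
  m.p_t0 = protocol(_, 0); m.p_t1 = protocol(_, 1); m.p_I = protocol(_, 2);
  m.Patm = Patm; m.alpha = alpha; m.eps = eps; m.gbh = gbh; m.gsw = gsw;
  m.k = k; m.Cs = Cs; m.lambda = lambda; m.es_form = es_form;
  return m.rhs(t, T, m.irradiance(t));
}
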