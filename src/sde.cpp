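#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Drive evaluation codes: voltage 0=dc,1=ramp,2=ac(cos),3=ac(sin);
// temperature 0=const,1=ac(sin).
static inline double drive_voltage(int kind, const double *p, double t) {
  switch (kind) {
  case 0: return p[0];
  case 1: { // V_start, V_end, duration
    double f = t / p[2];
    if (f < 0.0) f = 0.0;
    if (f > 1.0) f = 1.0;
    return p[0] + (p[1] - p[0]) * f;
  }
  case 2: return p[0] + p[1] * std::cos(p[2] * t + p[3]);
  default: return p[0] + p[1] * std::sin(p[2] * t + p[3]);
  }
}

static inline double drive_temperature(int kind, const double *p, double t) {
  if (kind == 0) return p[0];
  return p[0] * (1.0 + p[1] * std::sin(p[2] * t + p[3]));
}

// Polynomial force -dU/dx with U = sum c_k (x - x_w)^k.
static inline double poly_force(const double *coef, int ncoef, double x_w,
                                double x) {
  double s = x - x_w, dU = 0.0, pw = 1.0;
  for (int k = 1; k < ncoef; ++k) {
    dU += k * coef[k] * pw;
    pw *= s;
  }
  return -dU;
}

// Linear interpolation on a uniform force grid (tabulated potentials).
static inline double grid_force(const double *fx, int n, double x0,
                                double dxg, double x) {
  double u = (x - x0) / dxg;
  if (u <= 0.0) return fx[0];
  if (u >= n - 1) return fx[n - 1];
  int i = (int)u;
  double w = u - i;
  return fx[i] * (1.0 - w) + fx[i + 1] * w;
}

// Reflect a position into [-h, h] (repeated folding handles any excursion).
static inline double reflect(double x, double h) {
  while (x > h || x < -h) {
    if (x > h) x = 2.0 * h - x;
    if (x < -h) x = -2.0 * h - x;
  }
  return x;
}

// [[Rcpp::export(name = ".sde_core")]]
List sde_core(NumericVector x0, double T_init, double V_init,
              double dt, int n_steps, int record_stride,
              double R_t, double lambda, double L, double eta, double q,
              double C_th, double kappa, double k_B, double field_sign,
              int pot_kind, NumericVector pot_coef, double well_position,
              NumericVector grid_x0_dx, NumericVector grid_F,
              double R_ext, double tau, double D_V,
              int v_kind, NumericVector v_par,
              int t_kind, NumericVector t_par,
              bool freeze_particles, bool clamp_temperature) {
  const int np = x0.size();
  const double half = L / 2.0;
  const double Rmin = (np == 2)
    ? R_t * (2.0 * std::exp(L / (2.0 * lambda)) + 1.0)
    : 2.0 * R_t * std::exp(L / (2.0 * lambda));
  const int n_rec = n_steps / record_stride + 1;

  NumericVector rec_t(n_rec), rec_T(n_rec), rec_V(n_rec), rec_I(n_rec),
    rec_G(n_rec), rec_Vext(n_rec), rec_T0(n_rec);
  NumericMatrix rec_x(n_rec, np);

  double x[2] = {x0[0], np == 2 ? x0[1] : 0.0};
  double T = T_init, V = V_init;
  const double *vp = v_par.begin(), *tp = t_par.begin();
  const double *pc = pot_coef.begin();
  const int ncoef = pot_coef.size();
  const double gx0 = grid_x0_dx[0], gdx = grid_x0_dx[1];
  const double *gF = grid_F.begin();
  const int ng = grid_F.size();
  const double sqdt = std::sqrt(dt);
  const double vnoise = std::sqrt(D_V) / tau;

  RNGScope scope;
  int irec = 0;

  for (int step = 0; step <= n_steps; ++step) {
    double t = step * dt;
    double R = (np == 2)
      ? R_t * (std::exp((half + x[0]) / lambda) +
               std::exp((x[1] - x[0]) / lambda) +
               std::exp((half - x[1]) / lambda))
      : 2.0 * R_t * std::exp(half / lambda) * std::cosh(x[0] / lambda);
    double Vext = drive_voltage(v_kind, vp, t);
    double T0 = drive_temperature(t_kind, tp, t);

    if (step % record_stride == 0 && irec < n_rec) {
      rec_t[irec] = t;
      for (int i = 0; i < np; ++i) rec_x(irec, i) = x[i];
      rec_T[irec] = T; rec_V[irec] = V;
      rec_I[irec] = V / R; rec_G[irec] = Rmin / R;
      rec_Vext[irec] = Vext; rec_T0[irec] = T0;
      ++irec;
    }
    if (step == n_steps) break;

    // position update (Euler-Maruyama, Ito: diffusion at current T)
    if (!freeze_particles) {
      double sig = std::sqrt(2.0 * k_B * (T > 0.0 ? T : 0.0) / eta);
      for (int i = 0; i < np; ++i) {
        double Fp = (pot_kind == 0)
          ? poly_force(pc, ncoef, well_position, x[i])
          : grid_force(gF, ng, gx0, gdx, x[i]);
        double drift = (Fp + field_sign * q * V / L) / eta;
        x[i] += drift * dt + sig * sqdt * norm_rand();
        x[i] = reflect(x[i], half);
      }
      if (np == 2 && x[0] > x[1]) { // renumber to keep x1 <= x2
        double tmp = x[0]; x[0] = x[1]; x[1] = tmp;
      }
    }

    // temperature update (Joule heating vs Newton cooling)
    if (clamp_temperature) {
      T = T0;
    } else {
      T += (V * V / (C_th * R) - kappa * (T - T0)) * dt;
    }

    // voltage update (Kirchhoff current law for the RC readout)
    double dV = (Vext - (1.0 + R_ext / R) * V) / tau * dt;
    if (D_V > 0.0) dV += vnoise * sqdt * norm_rand();
    V += dV;

    if (!std::isfinite(x[0]) || !std::isfinite(T) || !std::isfinite(V) ||
        (np == 2 && !std::isfinite(x[1]))) {
      stop("integration failure at t = %g (x = %g, T = %g, V = %g)",
           t, x[0], T, V);
    }
  }

  return List::create(_["t"] = rec_t, _["x"] = rec_x, _["T"] = rec_T,
                      _["V"] = rec_V, _["I"] = rec_I, _["G_norm"] = rec_G,
                      _["V_ext"] = rec_Vext, _["T0"] = rec_T0);
}
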