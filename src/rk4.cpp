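#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of the input trace I given on a uniform grid of step dt
// (t = 0 at the first sample). Clamped at the ends.
static inline double interp_input(const NumericVector& I, double dt, double t) {
  double s = t / dt;
  int n = I.size();
  if (s <= 0.0) return I[0];
  if (s >= n - 1) return I[n - 1];
  int i0 = (int)std::floor(s);
  double f = s - i0;
  return I[i0] * (1.0 - f) + I[i0 + 1] * f;
}

// Periodic linear interpolation of Z on a uniform grid over [0, 2*pi).
static inline double interp_prc(const NumericVector& z, double phi) {
  int n = z.size();
  double two_pi = 2.0 * M_PI;
  double u = phi - two_pi * std::floor(phi / two_pi);
  if (u >= two_pi) u = 0.0;
  double s = u / (two_pi / n);
  int i0 = (int)std::floor(s);
  if (i0 >= n) i0 = n - 1;
  double f = s - i0;
  int i1 = (i0 + 1) % n;
  return z[i0] * (1.0 - f) + z[i1] * f;
}

static inline double rk4_step(const NumericVector& I, const NumericVector& z,
                              double dt_grid, double t0, double h, double phi0,
                              double omega) {
  double k1 = omega + interp_prc(z, phi0) * interp_input(I, dt_grid, t0);
  double k2 = omega + interp_prc(z, phi0 + 0.5 * h * k1) *
                          interp_input(I, dt_grid, t0 + 0.5 * h);
  double k3 = omega + interp_prc(z, phi0 + 0.5 * h * k2) *
                          interp_input(I, dt_grid, t0 + 0.5 * h);
  double k4 = omega + interp_prc(z, phi0 + h * k3) *
                          interp_input(I, dt_grid, t0 + h);
  return phi0 + h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

// Integrate dphi/dt = omega_i + Z(phi) I(t) with fixed-step RK4 at the input
// grid step. omega_i is redrawn at each cycle boundary (phi crossing a
// multiple of 2*pi) as 2*pi/(T + eps[cycle]); eps draws are supplied so that
// all randomness stays on the R side. Event crossings (phases ev_phase mod
// 2*pi, ev_phase[0] must be 0 = the cycle boundary) are located by linear
// interpolation within the step; at a cycle boundary the remainder of the
// step is re-integrated with the new omega so that, without input, every
// cycle lasts exactly T + eps[cycle].
// [[Rcpp::export(rng = false)]]
List sim_phase_rk4(NumericVector input, double dt, double T_nat,
                   NumericVector z_grid, NumericVector ev_phase,
                   NumericVector eps, double duration) {
  const double two_pi = 2.0 * M_PI;
  int n_ev = ev_phase.size();
  if (n_ev < 1 || ev_phase[0] != 0.0)
    stop("ev_phase[1] must be 0 (cycle boundary)");
  int n_steps = (int)std::llround(duration / dt);
  NumericVector phi_out(n_steps + 1);
  std::vector<double> ev_times;
  std::vector<int> ev_kind;
  std::vector<double> cyc_T;

  // next crossing threshold per event kind (unwrapped phase)
  std::vector<double> next_cross(n_ev);
  for (int j = 0; j < n_ev; ++j)
    next_cross[j] = (ev_phase[j] == 0.0) ? two_pi : ev_phase[j];

  int cyc = 0;
  if (cyc >= eps.size()) stop("eps vector too short");
  double omega = two_pi / (T_nat + eps[cyc]);
  cyc_T.push_back(T_nat + eps[cyc]);
  // event at t = 0: phi(0) = 0 is a cycle-boundary event by convention
  ev_times.push_back(0.0);
  ev_kind.push_back(0);

  double phi = 0.0;
  phi_out[0] = 0.0;
  for (int i = 0; i < n_steps; ++i) {
    double t_cur = i * dt;
    double t_end = t_cur + dt;
    double phi_cur = phi;
    double phi_new = rk4_step(input, z_grid, dt, t_cur, t_end - t_cur,
                              phi_cur, omega);
    // scan crossings in phase order
    for (;;) {
      int jmin = -1;
      double thr_min = R_PosInf;
      for (int j = 0; j < n_ev; ++j) {
        if (next_cross[j] > phi_cur && next_cross[j] <= phi_new &&
            next_cross[j] < thr_min) {
          thr_min = next_cross[j];
          jmin = j;
        }
      }
      if (jmin < 0) break;
      double t_star = t_cur +
        (t_end - t_cur) * (thr_min - phi_cur) / (phi_new - phi_cur);
      ev_times.push_back(t_star);
      ev_kind.push_back(jmin);
      next_cross[jmin] += two_pi;
      if (jmin == 0) {  // cycle boundary: redraw omega, re-anchor
        ++cyc;
        if (cyc >= eps.size()) stop("eps vector too short");
        omega = two_pi / (T_nat + eps[cyc]);
        cyc_T.push_back(T_nat + eps[cyc]);
        phi_cur = thr_min;
        t_cur = t_star;
        if (t_end - t_cur <= 0) { phi_new = phi_cur; break; }
        phi_new = rk4_step(input, z_grid, dt, t_cur, t_end - t_cur,
                           phi_cur, omega);
      }
    }
    phi = phi_new;
    phi_out[i + 1] = phi;
  }
  return List::create(_["phi"] = phi_out,
                      _["event_time"] = wrap(ev_times),
                      _["event_kind"] = wrap(ev_kind),
                      _["cycle_period"] = wrap(cyc_T));
}
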