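#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integrator for the two-state myocyte model.
//
// States: ca   free cytosolic Ca, nmol/l
//         sr   SR Ca content, umol/l of total cell volume
//
// Total-Ca fluxes (umol/l/s), all linear in (ca - ca_rest):
//   J_cal   = |i_cal| * kq / 2          (2 charges per Ca)
//   J_ncx   = g_ncx * cm * (ca - ca_rest) * kq   (1 net charge per Ca)
//   J_pmca  = k_pmca * beta * 1e-3 * (ca - ca_rest)
//   J_serca = k_serca * beta * 1e-3 * (ca - ca_rest)   (0 while caffeine open)
// with kq = 1e6 / (F * vol), converting pA to umol/l/s.
//
// Free Ca follows d(ca)/dt = (sum of total fluxes) * 1e3 / beta, so during a
// caffeine transient the free decay rate constant is exactly
//   g_ncx * (cm/vol) * 1e9 / (F * beta) + k_pmca
// (see caffeine_decay_rate() on the R side).
//
// Events (applied between steps, aligned to the grid):
//   stimulus onset: instantaneous SR dump of
//     frac_rel * max(0, (p - theta)/(1 - theta)) * sr, p = g_cal/trig_ref
//   caffeine onset: full SR dump; SERCA futile afterwards; with ni_block the
//     NCX coefficient is zero from caffeine onset.

static const double FARADAY = 96485.0;

struct ModelPars {
  double ca_rest, beta, k_serca, k_pmca, g_ncx, g_cal, k_inact, f_sus;
  double cm, vol, kq;
  double step_dur;
  bool caff_open;
  bool ncx_blocked;
  double last_stim; // -1 if none yet
};

static inline double ical_at(const ModelPars& p, double t) {
  if (p.last_stim < 0.0 || p.caff_open) return 0.0;
  double s = t - p.last_stim;
  if (s < 0.0 || s > p.step_dur) return 0.0;
  // inward (negative) L-type current, pA
  return -p.g_cal * p.cm * ((1.0 - p.f_sus) * std::exp(-p.k_inact * s) + p.f_sus);
}

static inline void deriv(const ModelPars& p, double t, double ca, double sr,
                         double& dca, double& dsr) {
  double ical = ical_at(p, t);
  double j_cal = -ical * p.kq / 2.0;
  double dd = ca - p.ca_rest;
  double j_ncx = (p.ncx_blocked ? 0.0 : p.g_ncx) * p.cm * dd * p.kq;
  double j_pmca = p.k_pmca * p.beta * 1e-3 * dd;
  double j_serca = p.caff_open ? 0.0 : p.k_serca * p.beta * 1e-3 * dd;
  dca = (j_cal - j_serca - j_ncx - j_pmca) * 1e3 / p.beta;
  dsr = p.caff_open ? 0.0 : j_serca;
}

// [[Rcpp::export]]
List sim_core(double ca_rest, double beta, double k_serca, double k_pmca,
              double g_ncx, double g_cal, double k_inact, double f_sus,
              double frac_rel, double trig_ref, double trig_theta,
              double cm, double vol, double sr_init,
              NumericVector stim_times, double step_dur,
              double caff_time, bool ni_block,
              double t_end, double dt, double out_dt) {
  if (dt <= 0.0 || out_dt < dt)
    stop("invalid integration steps (dt = %g, out_dt = %g)", dt, out_dt);

  ModelPars p;
  p.ca_rest = ca_rest; p.beta = beta; p.k_serca = k_serca; p.k_pmca = k_pmca;
  p.g_ncx = g_ncx; p.g_cal = g_cal; p.k_inact = k_inact; p.f_sus = f_sus;
  p.cm = cm; p.vol = vol; p.kq = 1e6 / (FARADAY * vol);
  p.step_dur = step_dur; p.caff_open = false; p.ncx_blocked = false;
  p.last_stim = -1.0;

  const long n_steps = (long)std::lround(t_end / dt);
  const long m = (long)std::lround(out_dt / dt);
  const long n_out = n_steps / m + 1;

  NumericVector time(n_out), ca_out(n_out), sr_out(n_out),
                ical_out(n_out), incx_out(n_out);

  // event step indices
  std::vector<long> stim_idx(stim_times.size());
  for (int i = 0; i < stim_times.size(); ++i)
    stim_idx[i] = (long)std::lround(stim_times[i] / dt);
  long caff_idx = R_FINITE(caff_time) ? (long)std::lround(caff_time / dt) : -1;

  double trig = 0.0;
  if (trig_ref > 0.0) {
    double pn = g_cal / trig_ref;
    trig = (pn - trig_theta) / (1.0 - trig_theta);
    if (trig < 0.0) trig = 0.0;
  }
  double rel_frac = frac_rel * trig;
  if (rel_frac > 1.0) rel_frac = 1.0;

  double ca = ca_rest, sr = sr_init;
  size_t next_stim = 0;
  long out_i = 0;

  for (long i = 0; i <= n_steps; ++i) {
    double t = i * dt;

    // events at grid point i
    if (caff_idx >= 0 && i == caff_idx) {
      p.caff_open = true;
      if (ni_block) p.ncx_blocked = true;
      ca += sr * 1e3 / p.beta;
      sr = 0.0;
    }
    while (next_stim < stim_idx.size() && stim_idx[next_stim] == i) {
      if (!p.caff_open) {
        double dump = rel_frac * sr;
        sr -= dump;
        ca += dump * 1e3 / p.beta;
        p.last_stim = t;
      }
      ++next_stim;
    }

    if (i % m == 0) {
      time[out_i] = t;
      ca_out[out_i] = ca;
      sr_out[out_i] = sr;
      ical_out[out_i] = ical_at(p, t);
      incx_out[out_i] = -(p.ncx_blocked ? 0.0 : p.g_ncx) * p.cm * (ca - p.ca_rest);
      ++out_i;
    }
    if (i == n_steps) break;

    // RK4 step
    double k1c, k1s, k2c, k2s, k3c, k3s, k4c, k4s;
    deriv(p, t, ca, sr, k1c, k1s);
    deriv(p, t + dt / 2.0, ca + dt / 2.0 * k1c, sr + dt / 2.0 * k1s, k2c, k2s);
    deriv(p, t + dt / 2.0, ca + dt / 2.0 * k2c, sr + dt / 2.0 * k2s, k3c, k3s);
    deriv(p, t + dt, ca + dt * k3c, sr + dt * k3s, k4c, k4s);
    ca += dt / 6.0 * (k1c + 2.0 * k2c + 2.0 * k3c + k4c);
    sr += dt / 6.0 * (k1s + 2.0 * k2s + 2.0 * k3s + k4s);

    if (!std::isfinite(ca) || !std::isfinite(sr))
      stop("integration blow-up: non-finite state at t = %g s", t + dt);
    if (sr < -1e-9)
      stop("negative SR content (%g umol/l) at t = %g s", sr, t + dt);
    if (sr < 0.0) sr = 0.0;
  }

  return List::create(_["time"] = time, _["ca_free"] = ca_out,
                      _["ca_sr"] = sr_out, _["i_cal"] = ical_out,
                      _["i_ncx"] = incx_out);
}
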