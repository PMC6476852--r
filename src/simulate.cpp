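// Core fixed-step integrator for the kicked-Windkessel model.
//
// State y = (p_a, p_c, p_v, phi, Phi).  Continuous dynamics are advanced by
// classical RK4; integer crossings of the cardiac phase phi trigger an
// instantaneous volume transfer (the "kick"), integer crossings of the
// respiratory phase Phi schedule a decaying neural impulse at delay tau.
// Events are located by linear interpolation inside the step and the step is
// split at the event time.  Everything is deterministic.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Pars {
  double Ca, Cv, Cc, Zvc, Zav, Zca, p0, p1, r, r0, tau, taun, R, k;
};

Pars as_pars(const List& p) {
  Pars q;
  q.Ca  = p["C_a"];  q.Cv  = p["C_v"];  q.Cc  = p["C_c"];
  q.Zvc = p["Z_vc"]; q.Zav = p["Z_av"]; q.Zca = p["Z_ca"];
  q.p0  = p["p0"];   q.p1  = p["p1"];
  q.r   = p["r"];    q.r0  = p["r0"];
  q.tau = p["tau"];  q.taun = p["tau_n"]; q.R = p["R"];
  q.k   = p["kick_unit_time"];
  return q;
}

inline double intrathoracic(double Phi, const Pars& p) {
  return p.p0 + p.p1 * (1.0 + std::cos(2.0 * M_PI * Phi));
}

// Phase-effectiveness gain F on [0, 1).
inline double phase_eff(double phi) {
  double om = 1.0 - phi;
  return std::pow(phi, 1.3) * (phi - 0.45) +
         (om * om * om) / (0.008 + om * om * om);
}

// Sum of decaying neural impulses active at time t.  kick_times holds the
// activation instants t_j + tau, sorted ascending; contributions older than
// 10 * tau_n are truncated (attenuation < e^-10).  Theta(0) = 1.
inline double forcing(double t, const std::vector<double>& kick_times,
                      std::size_t& first_active, const Pars& p) {
  double horizon = 10.0 * p.taun;
  while (first_active < kick_times.size() &&
         t - kick_times[first_active] > horizon)
    ++first_active;
  double s = 0.0;
  for (std::size_t j = first_active; j < kick_times.size(); ++j) {
    double a = t - kick_times[j];
    if (a < 0.0) break;
    s += p.r0 * std::exp(-a / p.taun);
  }
  return s;
}

struct State {
  double pa, pc, pv, phi, Phi;
};

struct Deriv {
  double pa, pc, pv, phi, Phi;
};

inline Deriv rhs(double t, const State& y, const Pars& p,
                 const std::vector<double>& kicks, std::size_t& first_active,
                 bool& clamped) {
  Deriv d;
  double pav = y.pa - y.pv;
  double pvc = y.pv - y.pc;
  double qin = std::max(p.Zvc * pvc, 0.0);  // ideal diode on CC inflow
  d.pa = -p.Zav * pav / p.Ca;
  d.pc = qin / p.Cc;
  d.pv = (p.Zav * pav - qin) / p.Cv;
  double phim = y.phi - std::floor(y.phi);
  double dphi = p.r + forcing(t, kicks, first_active, p) * phase_eff(phim);
  if (dphi < 0.0) { dphi = 0.0; clamped = true; }
  d.phi = dphi;
  d.Phi = p.R;
  return d;
}

inline State rk4(double t, const State& y, double h, const Pars& p,
                 const std::vector<double>& kicks, std::size_t& first_active,
                 bool& clamped) {
  auto add = [](const State& a, const Deriv& d, double f) {
    State s;
    s.pa = a.pa + f * d.pa;   s.pc = a.pc + f * d.pc;
    s.pv = a.pv + f * d.pv;   s.phi = a.phi + f * d.phi;
    s.Phi = a.Phi + f * d.Phi;
    return s;
  };
  Deriv k1 = rhs(t, y, p, kicks, first_active, clamped);
  Deriv k2 = rhs(t + h / 2, add(y, k1, h / 2), p, kicks, first_active, clamped);
  Deriv k3 = rhs(t + h / 2, add(y, k2, h / 2), p, kicks, first_active, clamped);
  Deriv k4 = rhs(t + h, add(y, k3, h), p, kicks, first_active, clamped);
  State out;
  out.pa  = y.pa  + h / 6 * (k1.pa  + 2 * k2.pa  + 2 * k3.pa  + k4.pa);
  out.pc  = y.pc  + h / 6 * (k1.pc  + 2 * k2.pc  + 2 * k3.pc  + k4.pc);
  out.pv  = y.pv  + h / 6 * (k1.pv  + 2 * k2.pv  + 2 * k3.pv  + k4.pv);
  out.phi = y.phi + h / 6 * (k1.phi + 2 * k2.phi + 2 * k3.phi + k4.phi);
  out.Phi = y.Phi + h / 6 * (k1.Phi + 2 * k2.Phi + 2 * k3.Phi + k4.Phi);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".wk_phase_eff_cpp")]]
NumericVector wk_phase_eff_cpp(NumericVector phi) {
  NumericVector out(phi.size());
  for (R_xlen_t i = 0; i < phi.size(); ++i) out[i] = phase_eff(phi[i]);
  return out;
}

// [[Rcpp::export(name = ".wk_simulate_cpp")]]
List wk_simulate_cpp(List params, double duration, double dt,
                     NumericVector init, int record_stride) {
  Pars p = as_pars(params);
  State y{init[0], init[1], init[2], init[3], init[4]};
  int nsteps = (int)std::lround(duration / dt);

  std::vector<double> rec_t, rec_pa, rec_pc, rec_pv, rec_phi, rec_Phi;
  std::vector<int> rec_ev;  // 0 plain sample, 1 pre-kick, 2 post-kick
  std::vector<double> beat_t, beat_dV, breath_t;
  std::vector<double> kicks;  // activation times t_j + tau
  std::size_t first_active = 0;
  int clamp_steps = 0, neg_ejections = 0;

  std::size_t guess = (std::size_t)(nsteps / std::max(record_stride, 1)) + 128;
  rec_t.reserve(guess); rec_pa.reserve(guess); rec_pc.reserve(guess);
  rec_pv.reserve(guess); rec_phi.reserve(guess); rec_Phi.reserve(guess);
  rec_ev.reserve(guess);

  auto record = [&](double t, const State& s, int ev) {
    rec_t.push_back(t);
    rec_pa.push_back(s.pa);  rec_pc.push_back(s.pc);  rec_pv.push_back(s.pv);
    rec_phi.push_back(s.phi); rec_Phi.push_back(s.Phi);
    rec_ev.push_back(ev);
  };

  record(0.0, y, 0);

  for (int n = 0; n < nsteps; ++n) {
    double t0 = n * dt, t1 = (n + 1) * dt;
    bool clamped = false;
    State y0 = y;
    State y1 = rk4(t0, y0, dt, p, kicks, first_active, clamped);

    if (y1.phi - y0.phi >= 1.0)
      stop("cardiac phase advanced >= 1 cycle in one step at t=%f; reduce dt",
           t0);
    if (!std::isfinite(y1.pa) || !std::isfinite(y1.pc) ||
        !std::isfinite(y1.pv) || !std::isfinite(y1.phi))
      stop("non-finite state at t=%f", t1);

    // Respiratory integer crossing: record the onset, schedule the kick.
    if (std::floor(y1.Phi) > std::floor(y0.Phi)) {
      double j = std::floor(y1.Phi);
      double tj = t0 + dt * (j - y0.Phi) / (y1.Phi - y0.Phi);
      breath_t.push_back(tj);
      kicks.push_back(tj + p.tau);
    }

    // Cardiac integer crossing: split the step at the beat.
    if (std::floor(y1.phi) > std::floor(y0.phi)) {
      double i = std::floor(y1.phi);
      double ti = t0 + dt * (i - y0.phi) / (y1.phi - y0.phi);
      State yb = (ti > t0) ? rk4(t0, y0, ti - t0, p, kicks, first_active,
                                 clamped)
                           : y0;
      yb.phi = i;  // snap to the integer at the located crossing
      record(ti, yb, 1);
      double pI = intrathoracic(yb.Phi, p);
      double dV = p.k * p.Zca * (yb.pc - pI);
      if (dV < 0.0) ++neg_ejections;
      yb.pa += dV / p.Ca;
      yb.pc -= dV / p.Cc;
      record(ti, yb, 2);
      beat_t.push_back(ti);
      beat_dV.push_back(dV);
      y = (t1 > ti) ? rk4(ti, yb, t1 - ti, p, kicks, first_active, clamped)
                    : yb;
    } else {
      y = y1;
    }

    if (clamped) ++clamp_steps;
    if ((n + 1) % record_stride == 0 || n + 1 == nsteps) record(t1, y, 0);
  }

  return List::create(
      _["t"] = rec_t, _["p_a"] = rec_pa, _["p_c"] = rec_pc, _["p_v"] = rec_pv,
      _["phi"] = rec_phi, _["Phi"] = rec_Phi, _["event"] = rec_ev,
      _["beat_times"] = beat_t, _["ejected_volumes"] = beat_dV,
      _["breath_onsets"] = breath_t, _["clamp_events"] = clamp_steps,
      _["negative_ejections"] = neg_ejections);
}
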