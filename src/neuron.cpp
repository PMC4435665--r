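#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-compartment thalamocortical relay neuron.
// States: 0 V (mV), 1 mT, 2 hT, 3 r (HCN), 4 q (HVA), 5 mNa, 6 hNa, 7 nK.
// Units: ms, mV, pA, nS, pF.  Fixed-step RK4.

struct Pars {
  double cm, gl, el;
  double gt, eca, gh, eh, ghva;
  double gna, gk, ena, ek, vt;
  double block_t, block_h;
  // gate rows: 0 = T act, 1 = T inact, 2 = HCN act, 3 = HVA act
  double v50[4], slope[4], tsc[4], tau_ms[4];
  int tau_form[4]; // 0 t_act_tc, 1 t_inact_tc, 2 hcn_tc, 3 constant
};

static inline double boltz(double v, double v50, double slope) {
  return 1.0 / (1.0 + std::exp((v - v50) / slope));
}

// x/(1-exp(-x/k)) with the removable singularity handled
static inline double vtrap(double x, double k) {
  if (std::fabs(x / k) < 1e-6) return k * (1.0 - x / k / 2.0);
  return x / (1.0 - std::exp(-x / k));
}

static inline double tau_t_act(double v) {
  return 0.612 + 1.0 / (std::exp(-(v + 132.0) / 16.7) + std::exp((v + 16.8) / 18.2));
}
static inline double tau_t_inact(double v) {
  if (v < -80.0) return std::exp((v + 467.0) / 66.6);
  return 28.0 + std::exp(-(v + 22.0) / 10.5);
}
static inline double tau_hcn(double v) {
  // slow activation at hyperpolarized V; deactivation collapses above ~-60 mV
  double tau = 1.0 / (std::exp(-14.59 - 0.086 * v) + std::exp(8.6 + 0.2 * v));
  return tau < 1.0 ? 1.0 : tau;
}

static inline double gate_tau_form(int form, double v, double tau_ms) {
  switch (form) {
    case 0: return tau_t_act(v);
    case 1: return tau_t_inact(v);
    case 2: return tau_hcn(v);
    default: return tau_ms;
  }
}

static inline double ionic_current(const Pars& p, const double* y) {
  const double v = y[0];
  double i = p.gl * (v - p.el);
  i += p.gt * (1.0 - p.block_t) * y[1] * y[1] * y[2] * (v - p.eca);
  i += p.gh * (1.0 - p.block_h) * y[3] * (v - p.eh);
  i += p.ghva * y[4] * y[4] * (v - p.eca);
  i += p.gna * y[5] * y[5] * y[5] * y[6] * (v - p.ena);
  i += p.gk * y[7] * y[7] * y[7] * y[7] * (v - p.ek);
  return i;
}

// dy/dt; mode 0 = current clamp (drive = injected pA),
// mode 1 = voltage clamp (drive = command mV, r_eff in MOhm; r_eff <= 0 means ideal clamp)
static void deriv(const Pars& p, const double* y, double drive, int mode,
                  double r_eff, double* dy) {
  double v = y[0];
  if (mode == 1 && r_eff <= 0.0) v = drive;

  // gating derivatives
  const double minf = boltz(v, p.v50[0], p.slope[0]);
  const double hinf = boltz(v, p.v50[1], p.slope[1]);
  const double rinf = boltz(v, p.v50[2], p.slope[2]);
  const double qinf = boltz(v, p.v50[3], p.slope[3]);
  dy[1] = (minf - y[1]) / (gate_tau_form(p.tau_form[0], v, p.tau_ms[0]) * p.tsc[0]);
  dy[2] = (hinf - y[2]) / (gate_tau_form(p.tau_form[1], v, p.tau_ms[1]) * p.tsc[1]);
  dy[3] = (rinf - y[3]) / (gate_tau_form(p.tau_form[2], v, p.tau_ms[2]) * p.tsc[2]);
  dy[4] = (qinf - y[4]) / (gate_tau_form(p.tau_form[3], v, p.tau_ms[3]) * p.tsc[3]);

  const double vs = v - p.vt;
  const double am = 0.32 * vtrap(vs - 13.0, 4.0);
  const double bm = 0.28 * vtrap(-(vs - 40.0), 5.0);
  const double ah = 0.128 * std::exp(-(vs - 17.0) / 18.0);
  const double bh = 4.0 / (1.0 + std::exp(-(vs - 40.0) / 5.0));
  const double an = 0.032 * vtrap(vs - 15.0, 5.0);
  const double bn = 0.5 * std::exp(-(vs - 10.0) / 40.0);
  dy[5] = am * (1.0 - y[5]) - bm * y[5];
  dy[6] = ah * (1.0 - y[6]) - bh * y[6];
  dy[7] = an * (1.0 - y[7]) - bn * y[7];

  if (mode == 0) {
    dy[0] = (drive - ionic_current(p, y)) / p.cm;
  } else if (r_eff > 0.0) {
    // pipette current through the residual series resistance charges the membrane
    const double ipip = 1000.0 * (drive - y[0]) / r_eff; // pA
    dy[0] = (ipip - ionic_current(p, y)) / p.cm;
  } else {
    dy[0] = 0.0; // ideal clamp: V slaved to command
  }
}

static void rk4_step(const Pars& p, double* y, double drive, int mode,
                     double r_eff, double h) {
  double k1[8], k2[8], k3[8], k4[8], yt[8];
  deriv(p, y, drive, mode, r_eff, k1);
  for (int i = 0; i < 8; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  deriv(p, yt, drive, mode, r_eff, k2);
  for (int i = 0; i < 8; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  deriv(p, yt, drive, mode, r_eff, k3);
  for (int i = 0; i < 8; ++i) yt[i] = y[i] + h * k3[i];
  deriv(p, yt, drive, mode, r_eff, k4);
  for (int i = 0; i < 8; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  if (mode == 1 && r_eff <= 0.0) y[0] = drive;
}

static Pars unpack(NumericVector p, NumericMatrix gates) {
  Pars q;
  q.cm = p["cm"]; q.gl = p["g_leak"]; q.el = p["e_leak"];
  q.gt = p["g_t"]; q.eca = p["e_ca"]; q.gh = p["g_h"]; q.eh = p["e_h"];
  q.ghva = p["g_hva"]; q.gna = p["g_na"]; q.gk = p["g_k"];
  q.ena = p["e_na"]; q.ek = p["e_k"]; q.vt = p["v_spike"];
  q.block_t = p["block_t"]; q.block_h = p["block_h"];
  for (int g = 0; g < 4; ++g) {
    q.v50[g] = gates(g, 0); q.slope[g] = gates(g, 1); q.tsc[g] = gates(g, 2);
    q.tau_form[g] = (int)gates(g, 3); q.tau_ms[g] = gates(g, 4);
  }
  return q;
}

// [[Rcpp::export]]
NumericVector neuron_relax_cpp(NumericVector params, NumericMatrix gates,
                               double level, int mode, double r_eff,
                               double dt, double relax_ms) {
  Pars p = unpack(params, gates);
  double y[8];
  double v0 = (mode == 1) ? level : p.el;
  y[0] = v0;
  y[1] = boltz(v0, p.v50[0], p.slope[0]);
  y[2] = boltz(v0, p.v50[1], p.slope[1]);
  y[3] = boltz(v0, p.v50[2], p.slope[2]);
  y[4] = boltz(v0, p.v50[3], p.slope[3]);
  const double vs = v0 - p.vt;
  double am = 0.32 * vtrap(vs - 13.0, 4.0), bm = 0.28 * vtrap(-(vs - 40.0), 5.0);
  double ah = 0.128 * std::exp(-(vs - 17.0) / 18.0),
         bh = 4.0 / (1.0 + std::exp(-(vs - 40.0) / 5.0));
  double an = 0.032 * vtrap(vs - 15.0, 5.0), bn = 0.5 * std::exp(-(vs - 10.0) / 40.0);
  y[5] = am / (am + bm); y[6] = ah / (ah + bh); y[7] = an / (an + bn);

  long n = (long)std::ceil(relax_ms / dt);
  for (long i = 0; i < n; ++i) {
    rk4_step(p, y, level, mode, r_eff, dt);
    if (!std::isfinite(y[0]) || std::fabs(y[0]) > 500.0)
      stop("integration diverged during relaxation at t = %f ms", i * dt);
  }
  NumericVector out(8);
  for (int i = 0; i < 8; ++i) out[i] = y[i];
  return out;
}

// [[Rcpp::export]]
List neuron_sim_cpp(NumericVector params, NumericMatrix gates,
                    NumericVector command, double dt_cmd, int mode,
                    double r_eff, double dt_int, NumericVector init_state,
                    bool return_states) {
  Pars p = unpack(params, gates);
  const int ncmd = command.size();
  if (init_state.size() != 8) stop("init_state must have length 8");
  double y[8];
  for (int i = 0; i < 8; ++i) y[i] = init_state[i];
  if (mode == 1 && r_eff <= 0.0) y[0] = command[0];

  int nsub = (int)std::max(1.0, std::round(dt_cmd / dt_int));
  double h = dt_cmd / nsub;

  NumericVector resp(ncmd);
  NumericMatrix states;
  if (return_states) states = NumericMatrix(ncmd, 8);

  for (int i = 0; i < ncmd; ++i) {
    const double drive = command[i];
    // record response at the sample time, before integrating through it
    if (mode == 0) {
      resp[i] = y[0];
    } else if (r_eff > 0.0) {
      resp[i] = 1000.0 * (drive - y[0]) / r_eff;
    } else {
      double icap = (i > 0) ? p.cm * (command[i] - command[i - 1]) / dt_cmd : 0.0;
      double ytmp[8]; for (int k = 0; k < 8; ++k) ytmp[k] = y[k];
      ytmp[0] = drive;
      resp[i] = ionic_current(p, ytmp) + icap;
    }
    if (return_states) {
      for (int k = 0; k < 8; ++k) states(i, k) = y[k];
      if (mode == 1 && r_eff <= 0.0) states(i, 0) = drive;
    }
    for (int s = 0; s < nsub; ++s) rk4_step(p, y, drive, mode, r_eff, h);
    if (!std::isfinite(y[0]) || std::fabs(y[0]) > 500.0)
      stop("integration diverged at t = %f ms", (i + 1) * dt_cmd);
  }

  if (return_states) return List::create(_["response"] = resp, _["states"] = states);
  return List::create(_["response"] = resp);
}
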