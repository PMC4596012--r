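// Core integrator for the single-compartment conductance-based neuron:
// exponential-Euler gate and voltage updates, four-annulus calcium handling
// with an implicit (closed-form) buffering substep, GHK receptor drive, and
// the optional integral-control transcription/translation engine.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY = 96485.33212; // C/mol
static const double GAS_R = 8.31446;       // J/(mol K)

// state vector layout
// [0] v ; [1..18] gates ; [19..22] ca shells ; [23..26] bound buffer ;
// [27..38] mRNA ; [39..50] dynamic conductances ; [51] absolute time (ms)
static const int IV = 0, IG0 = 1, ICA = 19, ICB = 23,
                 IM = 27, IGD = 39, IT = 51, NSTATE = 52;

struct GateSpec {
  double vhalf, slope, tau;
  // optional voltage dependence of tau: tau(v) = floor + (tau - floor) /
  // (1 + exp((v - tau_vhalf)/tau_k)); vdep = 0 keeps tau fixed
  int vdep; double tau_floor, tau_vhalf, tau_k;
};

struct Core {
  double area_cm2, Cm;
  double g[12]; // maximal conductances (mS/cm2), roster order
  // voltage gates (16): Na m,h,s; DR n; A n,l; M; HCN; T m,h; R m,h; N m,h; L m,h
  GateSpec gate[16];
  int exp_na_m, exp_t_m, exp_r_m, exp_n_m;
  double sk_ca_half_mM, sk_hill, sk_tau;
  double bk_k1, bk_k2, bk_tau, bk_d1, bk_d2, bk_abar, bk_bbar;
  double e_na, e_k, e_h, e_ca, e_leak;
  double nar, p_ca_rel, p_na_rel, p_k_rel;
  double na_in, na_out, k_in, k_out, ca_in, ca_out, mg_out, temperature;
  int ca_ghk; double ca_drive_vref;
  double d_ca, vol[4], interf[3], drr[3], sv_outer_cm;
  double b_total, k_on, k_off;
  double vmax_serca, k_p, gamma_eff, ca_crt, ca_er, beta_er, leakL;
  double thr, refrac;
};

static double getd(const List& par, const char* nm) { return as<double>(par[nm]); }

static void fill_core(const List& par, Core& c) {
  c.area_cm2 = getd(par, "area");
  c.Cm = getd(par, "Cm");
  NumericVector g = par["g"];
  for (int i = 0; i < 12; ++i) c.g[i] = g[i];
  NumericVector gv = par["gate_vhalf"], gs = par["gate_slope"], gt = par["gate_tau"];
  NumericVector tvd = par["gate_tau_vdep"], tfl = par["gate_tau_floor"],
                tvh = par["gate_tau_vhalf"], tks = par["gate_tau_k"];
  for (int i = 0; i < 16; ++i) {
    c.gate[i].vhalf = gv[i]; c.gate[i].slope = gs[i]; c.gate[i].tau = gt[i];
    c.gate[i].vdep = (int)tvd[i]; c.gate[i].tau_floor = tfl[i];
    c.gate[i].tau_vhalf = tvh[i]; c.gate[i].tau_k = tks[i];
  }
  c.exp_na_m = (int)getd(par, "exp_na_m");
  c.exp_t_m = (int)getd(par, "exp_t_m");
  c.exp_r_m = (int)getd(par, "exp_r_m");
  c.exp_n_m = (int)getd(par, "exp_n_m");
  c.sk_ca_half_mM = getd(par, "sk_ca_half"); c.sk_hill = getd(par, "sk_hill");
  c.sk_tau = getd(par, "sk_tau");
  c.bk_k1 = getd(par, "bk_k1"); c.bk_k2 = getd(par, "bk_k2");
  c.bk_tau = getd(par, "bk_tau");
  c.bk_d1 = getd(par, "bk_d1"); c.bk_d2 = getd(par, "bk_d2");
  c.bk_abar = getd(par, "bk_abar"); c.bk_bbar = getd(par, "bk_bbar");
  c.e_na = getd(par, "E_Na"); c.e_k = getd(par, "E_K"); c.e_h = getd(par, "E_h");
  c.e_ca = getd(par, "E_Ca"); c.e_leak = getd(par, "E_leak");
  c.ca_ghk = (int)getd(par, "ca_ghk");
  c.ca_drive_vref = getd(par, "ca_drive_vref");
  c.nar = getd(par, "nar");
  c.p_ca_rel = getd(par, "P_Ca"); c.p_na_rel = getd(par, "P_Na");
  c.p_k_rel = getd(par, "P_K");
  c.na_in = getd(par, "na_in"); c.na_out = getd(par, "na_out");
  c.k_in = getd(par, "k_in"); c.k_out = getd(par, "k_out");
  c.ca_in = getd(par, "ca_in"); c.ca_out = getd(par, "ca_out");
  c.mg_out = getd(par, "mg_out"); c.temperature = getd(par, "temperature");
  c.d_ca = getd(par, "d_ca");
  NumericVector vol = par["ann_volume"], itf = par["ann_interface"], drr = par["ann_dr"];
  for (int i = 0; i < 4; ++i) c.vol[i] = vol[i];
  for (int i = 0; i < 3; ++i) { c.interf[i] = itf[i]; c.drr[i] = drr[i]; }
  c.sv_outer_cm = getd(par, "sv_outer_cm");
  c.b_total = getd(par, "buffer_total");
  c.k_on = getd(par, "k_on"); c.k_off = getd(par, "k_off");
  c.vmax_serca = getd(par, "v_max_serca"); c.k_p = getd(par, "k_p");
  c.gamma_eff = getd(par, "gamma_eff"); c.ca_crt = getd(par, "ca_crt");
  c.ca_er = getd(par, "ca_er"); c.beta_er = getd(par, "beta_er");
  c.leakL = getd(par, "leak_constant");
  c.thr = getd(par, "spike_threshold"); c.refrac = getd(par, "spike_refractory");
}

static inline double boltz(double v, double half, double slope) {
  return 1.0 / (1.0 + std::exp(-(v - half) / slope));
}

static inline double ipow(double x, int n) {
  double r = x;
  for (int i = 1; i < n; ++i) r *= x;
  return r;
}

// single-ion GHK current density, mA/cm2 (P cm/s, concentrations mM)
static inline double ghk(double P, int z, double v_mV, double cin, double cout,
                         double temperature) {
  double u = z * v_mV * 1e-3 * FARADAY / (GAS_R * temperature);
  double pref = P * z * FARADAY * 1e-3; // 1e-6 (mM -> mol/cm3) * 1e3 (A -> mA)
  if (std::fabs(u) < 1e-4) {
    return pref * ((cin - cout) + u / 2.0 * (cin + cout) +
                   u * u / 12.0 * (cin - cout));
  }
  double e = std::exp(-u);
  return pref * u * (cin - cout * e) / (1.0 - e);
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List par, NumericVector state0, NumericMatrix epochs, List ctrl) {
  Core c;
  fill_core(par, c);

  const double dt = as<double>(ctrl["dt"]);
  const double record_dt = as<double>(ctrl["record_dt"]);
  const double i_hold_pA = as<double>(ctrl["i_hold"]);
  const bool homeo = as<bool>(ctrl["homeostasis"]);
  const bool record_g = as<bool>(ctrl["record_g"]);
  double ca_target = 0, tau_g = 10;
  NumericVector tau_m(12), windup(12);
  if (homeo) {
    ca_target = as<double>(ctrl["ca_target"]);
    tau_g = as<double>(ctrl["tau_g"]);
    tau_m = as<NumericVector>(ctrl["tau_m"]);
    windup = as<NumericVector>(ctrl["windup_max"]);
  }

  std::vector<double> st(NSTATE);
  for (int i = 0; i < NSTATE; ++i) st[i] = state0[i];
  double v = st[IV];
  double* gate = &st[IG0];
  double* ca = &st[ICA];
  double* cab = &st[ICB];
  double* mrna = &st[IM];
  double* gdyn = &st[IGD];
  const double t0 = st[IT];

  // GHK-shaped VGCC driving force, anchored to the ohmic value at vref
  double ca_drive_scale = 0.0;
  if (c.ca_ghk) {
    double ref = ghk(1.0, 2, c.ca_drive_vref, c.ca_in, c.ca_out, c.temperature);
    ca_drive_scale = (c.ca_drive_vref - c.e_ca) / ref;
  }

  double gdecay[18];
  for (int i = 0; i < 16; ++i) gdecay[i] = 1.0 - std::exp(-dt / c.gate[i].tau);
  gdecay[16] = 1.0 - std::exp(-dt / c.sk_tau);
  gdecay[17] = 1.0 - std::exp(-dt / c.bk_tau);
  const double gdec_trans = 1.0 - std::exp(-dt / tau_g);

  const double i_inj_scale = 1e-6 / c.area_cm2; // pA -> uA/cm2
  const double i_hold = i_hold_pA * i_inj_scale;

  double total_dur = 0;
  for (int e = 0; e < epochs.nrow(); ++e) total_dur += epochs(e, 1);
  const long nstep_total = (long)std::llround(total_dur / dt);
  const long rec_every = std::max((long)1, (long)std::llround(record_dt / dt));
  const long nrec = nstep_total / rec_every + 1;

  NumericVector rec_t(nrec), rec_v(nrec), rec_ca(nrec), rec_i(nrec);
  NumericMatrix rec_gmat(record_g ? nrec : 1, 12);
  std::vector<double> spike_t, spike_peak;

  long irec = 0;
  double tnow = t0;

  rec_t[irec] = tnow; rec_v[irec] = v; rec_ca[irec] = ca[0]; rec_i[irec] = 0;
  if (record_g) for (int i = 0; i < 12; ++i) rec_gmat(irec, i) = gdyn[i];
  ++irec;

  double last_spike = -1e18, cur_peak = -1e18;
  bool in_spike = v >= c.thr;
  std::string err = "";
  long step_count = 0;

  for (int e = 0; e < epochs.nrow() && err.empty(); ++e) {
    const int kind = (int)epochs(e, 0);
    const double dur = epochs(e, 1), amp = epochs(e, 2), freq = epochs(e, 3);
    const double f_ripple = epochs(e, 4);
    const double period = (kind == 2) ? 1000.0 / freq : 0.0;
    const double span_ms = (kind == 5) ? epochs(e, 5) : 0.0;
    const long nstep = (long)std::llround(dur / dt);

    for (long s = 0; s < nstep; ++s, ++step_count) {
      const double te = (s + 1) * dt; // epoch-local time at end of step
      tnow += dt;

      // ---- afferent drive ----
      double p_ampar = 0.0, i_inj = i_hold, i_inj_pA = 0.0;
      if (kind == 1) {
        p_ampar = amp / 2.0 * (1.0 - std::cos(2 * M_PI * freq * te / 1000.0));
      } else if (kind == 2) {
        double tt = te - period * std::floor(te / period);
        if (tt <= 150.0) {
          double w = std::exp(-(tt - 55.0) * (tt - 55.0) / 800.0) -
                     0.3 * std::exp(-(tt - 40.0) * (tt - 40.0) / 450.0) *
                         std::sin(2 * M_PI * f_ripple * tt / 1000.0);
          if (w > 0) p_ampar = amp * w;
        }
      } else if (kind == 4) {
        i_inj_pA = amp;
        i_inj += amp * i_inj_scale;
      } else if (kind == 5) {
        i_inj_pA = amp * std::sin(M_PI * freq * te * te / (1000.0 * span_ms));
        i_inj += i_inj_pA * i_inj_scale;
      }

      // ---- gate update (exponential Euler toward steady state) ----
      for (int i = 0; i < 16; ++i) {
        double xinf = boltz(v, c.gate[i].vhalf, c.gate[i].slope);
        double dec = gdecay[i];
        if (c.gate[i].vdep) {
          double tau = c.gate[i].tau_floor +
                       (c.gate[i].tau - c.gate[i].tau_floor) /
                           (1.0 + std::exp((v - c.gate[i].tau_vhalf) /
                                           c.gate[i].tau_k));
          dec = 1.0 - std::exp(-dt / tau);
        }
        gate[i] += (xinf - gate[i]) * dec;
      }
      {
        double r = std::pow(ca[0] / c.sk_ca_half_mM, c.sk_hill);
        gate[16] += (r / (1.0 + r) - gate[16]) * gdecay[16];
        double vfrt = v * 1e-3 * FARADAY / (GAS_R * c.temperature);
        double a = c.bk_abar / (1.0 + c.bk_k1 * std::exp(-2 * c.bk_d1 * vfrt) / ca[0]);
        double b = c.bk_bbar / (1.0 + ca[0] / (c.bk_k2 * std::exp(-2 * c.bk_d2 * vfrt)));
        gate[17] += (a / (a + b) - gate[17]) * gdecay[17];
      }

      // ---- channel open fractions ----
      const double* g = homeo ? gdyn : c.g;
      double open[12];
      open[0] = 1.0;                                           // Leak
      open[1] = ipow(gate[0], c.exp_na_m) * gate[1] * gate[2]; // NaF
      open[2] = gate[3];                                       // KDR
      open[3] = gate[4] * gate[5];                             // KA
      open[4] = gate[6];                                       // KM
      open[5] = gate[7];                                       // HCN
      open[6] = ipow(gate[8], c.exp_t_m) * gate[9];            // CaT
      open[7] = ipow(gate[10], c.exp_r_m) * gate[11];          // CaR
      open[8] = ipow(gate[12], c.exp_n_m) * gate[13];          // CaN
      open[9] = gate[14] * gate[15];                           // CaL
      open[10] = gate[16];                                     // SK
      open[11] = gate[17];                                     // BK
      static const int eidx[12] = {0, 1, 2, 2, 2, 3, 4, 4, 4, 4, 2, 2};
      const double erev[5] = {c.e_leak, c.e_na, c.e_k, c.e_h, c.e_ca};

      double G = 0.0, GE = 0.0;
      double cadrive = v - c.e_ca; // mV
      if (c.ca_ghk)
        cadrive = ca_drive_scale * ghk(1.0, 2, v, c.ca_in, c.ca_out, c.temperature);
      double g_ca_open = g[6] * open[6] + g[7] * open[7] + g[8] * open[8] +
                         g[9] * open[9];
      double i_vgcc = g_ca_open * cadrive; // uA/cm2
      for (int i = 0; i < 12; ++i) {
        if (c.ca_ghk && i >= 6 && i <= 9) continue; // held constant in step
        double gi = g[i] * open[i];
        G += gi;
        GE += gi * erev[eidx[i]];
      }

      // ---- synaptic GHK currents (held constant within the step) ----
      double i_syn = 0.0, i_nmda_ca = 0.0; // uA/cm2, mA/cm2
      if (p_ampar > 0) {
        double blk = 1.0 / (1.0 + c.mg_out * std::exp(-0.062 * v) / 3.57);
        double pn = c.nar * p_ampar;
        double iampa = ghk(p_ampar, 1, v, c.na_in, c.na_out, c.temperature) +
                       ghk(p_ampar, 1, v, c.k_in, c.k_out, c.temperature);
        double inmda_na = blk * ghk(pn * c.p_na_rel, 1, v, c.na_in, c.na_out, c.temperature);
        double inmda_k = blk * ghk(pn * c.p_k_rel, 1, v, c.k_in, c.k_out, c.temperature);
        i_nmda_ca = blk * ghk(pn * c.p_ca_rel, 2, v, c.ca_in, c.ca_out, c.temperature);
        i_syn = (iampa + inmda_na + inmda_k + i_nmda_ca) * 1e3; // mA -> uA/cm2
      }

      // ---- voltage update (exponential Euler on the linearized equation) ----
      if (kind == 3) {
        v = -65.0; // voltage clamp during reset; gates/calcium keep evolving
      } else if (G > 1e-9) {
        double vinf = (GE - i_syn - (c.ca_ghk ? i_vgcc : 0.0) + i_inj) / G;
        v = vinf + (v - vinf) * std::exp(-dt * G / c.Cm);
      } else { // essentially conductance-free membrane: pure current integration
        v += dt * (GE - G * v - i_syn - (c.ca_ghk ? i_vgcc : 0.0) + i_inj) / c.Cm;
      }

      // ---- spike detection ----
      if (!in_spike && v >= c.thr) {
        if (tnow - last_spike >= c.refrac) {
          last_spike = tnow;
          in_spike = true;
          cur_peak = v;
        }
      } else if (in_spike) {
        if (v > cur_peak) cur_peak = v;
        if (v < c.thr) {
          spike_t.push_back(last_spike);
          spike_peak.push_back(cur_peak);
          in_spike = false;
        }
      }

      // ---- calcium: diffusion + membrane fluxes + implicit buffering ----
      {
        double flux[3], dca[4] = {0, 0, 0, 0};
        for (int i = 0; i < 3; ++i)
          flux[i] = c.d_ca * (ca[i + 1] - ca[i]) / c.drr[i] * c.interf[i];
        dca[0] += flux[0] / c.vol[0];
        dca[1] += (flux[1] - flux[0]) / c.vol[1];
        dca[2] += (flux[2] - flux[1]) / c.vol[2];
        dca[3] += -flux[2] / c.vol[3];

        if (c.ca_ghk)
          i_vgcc = g_ca_open * ca_drive_scale *
                   ghk(1.0, 2, v, c.ca_in, c.ca_out, c.temperature);
        else
          i_vgcc = g_ca_open * (v - c.e_ca);
        double i_ca_chan = i_vgcc * 1e-3; // mA/cm2
        double j_in = -(i_ca_chan + i_nmda_ca) * c.sv_outer_cm / (2.0 * FARADAY);
        double j_serca = c.vmax_serca * ca[0] * ca[0] /
                         (ca[0] * ca[0] + c.k_p * c.k_p);
        double j_leak = c.leakL * (1.0 - ca[0] / c.ca_er);
        double j_pump = ca[0] > c.ca_crt ? c.gamma_eff * (ca[0] - c.ca_crt) : 0.0;
        dca[0] += j_in + c.beta_er * (j_leak - j_serca) - j_pump;

        for (int i = 0; i < 4; ++i) {
          double cai = ca[i] + dt * dca[i];
          if (cai < 0) cai = 0;
          // implicit buffering substep (conserves cai + cab exactly)
          double stot = cai + cab[i];
          double b = 1.0 / dt + c.k_on * (c.b_total - stot) + c.k_off;
          double cc = -(cai / dt + c.k_off * stot);
          double canew = (-b + std::sqrt(b * b - 4.0 * c.k_on * cc)) /
                         (2.0 * c.k_on);
          cab[i] = stot - canew;
          ca[i] = canew;
        }
      }

      // ---- homeostasis: integral control of mRNA, relaxation of g ----
      if (homeo) {
        double errsig = ca_target - ca[0];
        for (int i = 0; i < 12; ++i) {
          mrna[i] += dt * errsig / tau_m[i];
          if (mrna[i] < 0) mrna[i] = 0;
          gdyn[i] += (mrna[i] - gdyn[i]) * gdec_trans;
          if (gdyn[i] < 0) gdyn[i] = 0;
          if (gdyn[i] > windup[i]) {
            err = "windup: conductance " + std::to_string(i + 1) +
                  " exceeded its safety ceiling";
            break;
          }
        }
        if (!err.empty()) break;
      }

      if ((step_count & 1023) == 0) {
        if (!std::isfinite(v)) { err = "integration failure: voltage is not finite"; break; }
        if (!std::isfinite(ca[0])) { err = "integration failure: cytosolic calcium is not finite"; break; }
      }

      if (((step_count + 1) % rec_every) == 0 && irec < nrec) {
        rec_t[irec] = tnow; rec_v[irec] = v; rec_ca[irec] = ca[0];
        rec_i[irec] = i_inj_pA;
        if (record_g) for (int i = 0; i < 12; ++i) rec_gmat(irec, i) = gdyn[i];
        ++irec;
      }
    }
  }

  st[IV] = v;
  st[IT] = tnow;
  NumericVector out_state(NSTATE);
  for (int i = 0; i < NSTATE; ++i) out_state[i] = st[i];

  Range keep(0, std::max((long)0, irec - 1));
  List out = List::create(
      _["time"] = rec_t[keep], _["v"] = rec_v[keep], _["ca"] = rec_ca[keep],
      _["i_inj"] = rec_i[keep],
      _["spike_times"] = wrap(spike_t), _["spike_peaks"] = wrap(spike_peak),
      _["state"] = out_state, _["error"] = err);
  if (record_g) {
    NumericMatrix gm(irec, 12);
    for (long r = 0; r < irec; ++r)
      for (int i = 0; i < 12; ++i) gm(r, i) = rec_gmat(r, i);
    out["g"] = gm;
  }
  return out;
}
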