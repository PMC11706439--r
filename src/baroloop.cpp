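// Core numerics: double-cosine elastance, diode valves, closed-loop
// right-hand sides (1CH/4CH, regulated/unregulated), and a fixed-step
// classical RK4 delay-differential integrator with a ring-buffer history
// of the filtered arterial pressure (cubic Hermite interpolation at lags).
//
// The regulated system is a DDE: the efferent static characteristics read
// the filtered pressure at t - D (D per effector). Beat-to-beat effectors
// (heart period, ventricular contractility) are promoted through a
// Gaussian-bump relaxation centred on beat onsets, which keeps the whole
// system a smooth DDE (no discrete events in the state equations).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- packed parameter layout (keep in sync with .packed_names in R) ----
enum {
  IP_TAU_HR0 = 0, IP_ELVMIN, IP_ELVMAX, IP_ERVMIN, IP_ERVMAX,
  IP_ELAMIN, IP_ELAMAX, IP_ERAMIN, IP_ERAMAX,
  IP_TINITV, IP_TS1V, IP_TS2V, IP_TINITA, IP_TS1A, IP_TS2A,
  IP_RMV, IP_RAV, IP_RTV, IP_RPV,
  IP_CART, IP_RSYS, IP_CVEN, IP_CPULA, IP_RPUL, IP_CPULV,
  IP_MCFP, IP_VUNV0,
  IP_PN, IP_FMIN, IP_FMAX, IP_KA, IP_FCS0,
  IP_TAUP, IP_TAUZ,
  IP_FESINF, IP_FES0, IP_FESMIN, IP_KES,
  IP_FEV0, IP_FEVINF, IP_KEV,
  IP_G_ELV, IP_TAU_ELV, IP_D_ELV,
  IP_G_ERV, IP_TAU_ERV, IP_D_ERV,
  IP_G_RSYS, IP_TAU_RSYS, IP_D_RSYS,
  IP_G_VUN, IP_TAU_VUN, IP_D_VUN,
  IP_G_TS, IP_TAU_TS, IP_D_TS,
  IP_G_TV, IP_TAU_TV, IP_D_TV,
  IP_PINIT,
  NPACK
};

static const double INV_SQRT_2PI = 0.3989422804014327;

// ---- elementary pieces ----

// double-cosine activation, half-open cycle coordinate tc in [0, tau)
static inline double activation(double tc, double tes, double tep) {
  if (tc < 0.0) return 0.0;
  if (tc < tes) return 0.5 * (1.0 - std::cos(M_PI * tc / tes));
  if (tc < tep) return 0.5 * (1.0 + std::cos(M_PI * (tc - tes) / (tep - tes)));
  return 0.0;
}

static inline double activation_deriv(double tc, double tes, double tep) {
  if (tc < 0.0) return 0.0;
  if (tc < tes) return 0.5 * M_PI / tes * std::sin(M_PI * tc / tes);
  if (tc < tep) return -0.5 * M_PI / (tep - tes) *
                       std::sin(M_PI * (tc - tes) / (tep - tes));
  return 0.0;
}

// Ohmic diode valve: small resistance forward, 1000x reverse
static inline double valve(double pu, double pd, double r) {
  double dp = pu - pd;
  return (dp > 0.0) ? dp / r : dp / (1000.0 * r);
}

// afferent sigmoid: filtered pressure -> carotid-sinus spiking frequency
static inline double f_cs(double pt, const double* p) {
  double z = (pt - p[IP_PN]) / p[IP_KA];
  double s = 1.0 / (1.0 + std::exp(-z));   // overflow-safe sigmoid
  return p[IP_FMIN] + (p[IP_FMAX] - p[IP_FMIN]) * s;
}

// sympathetic efferent (exponential decay in f_cs)
static inline double f_es(double fcs, const double* p) {
  return p[IP_FESINF] + (p[IP_FES0] - p[IP_FESINF]) * std::exp(-p[IP_KES] * fcs);
}

// vagal efferent (sigmoid in f_cs)
static inline double f_ev(double fcs, const double* p) {
  double z = (fcs - p[IP_FCS0]) / p[IP_KEV];
  double s = 1.0 / (1.0 + std::exp(-z));
  return p[IP_FEV0] + (p[IP_FEVINF] - p[IP_FEV0]) * s;
}

// sympathetic static characteristic with cutoff at f_es,min
static inline double sigma_symp(double fes_d, double G, const double* p) {
  double x = fes_d - p[IP_FESMIN];
  return (x >= 0.0) ? G * std::log1p(x) : 0.0;
}

// chamber elastance and its EXACT time-derivative along the solution,
// including the dependence of the timing (fractions of the held period)
// on the promoted period: tau_dot and dheld_emax are the promotion
// rates of the held period and held maximal elastance. The cycle shift
// for atria wraps modulo tau (atrial systole spans the beat boundary).
static inline void chamber_elastance(double tc, double tau, double tau_dot,
                                     double fi, double f1, double f2,
                                     double emin, double emax,
                                     double dheld_emax,
                                     double* E, double* dEdt, double* e_out) {
  double tca = tc - fi * tau;
  double dtca_dt = 1.0 - fi * tau_dot;
  if (tca < 0.0) { tca += tau; dtca_dt = 1.0 + (1.0 - fi) * tau_dot; }
  double tes = (f1 - fi) * tau, tep = (f2 - fi) * tau;
  double e, de_dtca, de_dtau;
  if (tca < tes) {
    double u = M_PI * tca / tes;
    e = 0.5 * (1.0 - std::cos(u));
    de_dtca = 0.5 * M_PI / tes * std::sin(u);
    // d e / d tes * d tes / d tau
    de_dtau = 0.5 * std::sin(u) * (-M_PI * tca / (tes * tes)) * (f1 - fi);
  } else if (tca < tep) {
    double w = tep - tes;
    double v = M_PI * (tca - tes) / w;
    e = 0.5 * (1.0 + std::cos(v));
    de_dtca = -0.5 * M_PI / w * std::sin(v);
    double dv_dtes = M_PI * (tca - tep) / (w * w);
    double dv_dtep = -M_PI * (tca - tes) / (w * w);
    de_dtau = -0.5 * std::sin(v) *
              (dv_dtes * (f1 - fi) + dv_dtep * (f2 - fi));
  } else {
    e = 0.0; de_dtca = 0.0; de_dtau = 0.0;
  }
  double de_dt = de_dtca * dtca_dt + de_dtau * tau_dot;
  *E = (emax - emin) * e + emin;
  *dEdt = (emax - emin) * de_dt + e * dheld_emax;
  if (e_out) *e_out = e;
}

// ---- state layouts ----
// 1CH unreg (3):  P_LV, P_art, P_ven
// 1CH reg  (10):  + P~, dELV, dR, dTs, dTv, heldTau, heldELV
// 4CH unreg (6):  P_LV, P_art, P_RA, P_RV, P_pulA, P_LA
// 4CH reg  (16):  + P~, dELV, dERV, dR, dVun, dTs, dTv,
//                   heldTau, heldELV, heldERV
struct Layout {
  int n;            // number of states
  int ipt;          // index of P~ (-1 if unregulated)
  int i_dELV, i_dERV, i_dR, i_dVun, i_dTs, i_dTv;
  int i_hTau, i_hELV, i_hERV;
};

static Layout layout_for(int variant, bool reg) {
  Layout L;
  L.ipt = -1;
  L.i_dELV = L.i_dERV = L.i_dR = L.i_dVun = L.i_dTs = L.i_dTv = -1;
  L.i_hTau = L.i_hELV = L.i_hERV = -1;
  if (variant == 1) {
    if (!reg) { L.n = 3; return L; }
    L.n = 10; L.ipt = 3; L.i_dELV = 4; L.i_dR = 5; L.i_dTs = 6; L.i_dTv = 7;
    L.i_hTau = 8; L.i_hELV = 9;
  } else {
    if (!reg) { L.n = 6; return L; }
    L.n = 16; L.ipt = 6; L.i_dELV = 7; L.i_dERV = 8; L.i_dR = 9; L.i_dVun = 10;
    L.i_dTs = 11; L.i_dTv = 12; L.i_hTau = 13; L.i_hELV = 14; L.i_hERV = 15;
  }
  return L;
}

// lagged filtered-pressure values, one slot per efferent pathway
struct Lags { double elv, erv, rsys, vun, ts, tv; };

// full right-hand side; `lag` supplies P~(t - D) per pathway (ignored when
// unregulated). Writes dy; returns flows/elastances through `aux` if not null.
struct Aux {
  double Qmv, Qav, Qtv, Qpv, Qsys, Qpul;
  double Elv, Erv, Era, Ela;
  double tau, Rsys_t;
};

static void rhs(int variant, bool reg, const double* p, double t, double tb,
                const double* y, const Lags& lag, double sigma_w, double gain,
                double* dy, Aux* aux) {
  Layout L = layout_for(variant, reg);

  // current effector values
  double tau   = reg ? y[L.i_hTau] : p[IP_TAU_HR0];
  double ELVmx = reg ? y[L.i_hELV] : p[IP_ELVMAX];
  double Rsys  = reg ? p[IP_RSYS] + y[L.i_dR] : p[IP_RSYS];
  if (Rsys < 1e-6) Rsys = 1e-6;
  if (tau  < 1e-3) tau  = 1e-3;

  // promotion bump: one-sided (post-onset) half-Gaussian with doubled
  // amplitude, so the full mass `gain` acts after every detected onset
  // and the promotion never anticipates a moving beat time
  double g = 0.0;
  double dhTau = 0.0, dhELV = 0.0, dhERV = 0.0;
  if (reg) {
    double a1 = (t - tb) / sigma_w;
    g = 2.0 * gain * INV_SQRT_2PI / sigma_w * std::exp(-0.5 * a1 * a1);
  }

  // efferent statics and effector relaxation
  double sig_elv = 0, sig_erv = 0, sig_r = 0, sig_vun = 0, sig_ts = 0, sig_tv = 0;
  if (reg) {
    sig_elv = sigma_symp(f_es(f_cs(lag.elv, p), p), p[IP_G_ELV], p);
    sig_r   = sigma_symp(f_es(f_cs(lag.rsys, p), p), p[IP_G_RSYS], p);
    sig_ts  = sigma_symp(f_es(f_cs(lag.ts, p), p), p[IP_G_TS], p);
    sig_tv  = p[IP_G_TV] * f_ev(f_cs(lag.tv, p), p);
    if (variant == 2) {
      sig_erv = sigma_symp(f_es(f_cs(lag.erv, p), p), p[IP_G_ERV], p);
      sig_vun = sigma_symp(f_es(f_cs(lag.vun, p), p), p[IP_G_VUN], p);
    }
    dy[L.i_dELV] = (sig_elv - y[L.i_dELV]) / p[IP_TAU_ELV];
    dy[L.i_dR]   = (sig_r   - y[L.i_dR])   / p[IP_TAU_RSYS];
    dy[L.i_dTs]  = (sig_ts  - y[L.i_dTs])  / p[IP_TAU_TS];
    dy[L.i_dTv]  = (sig_tv  - y[L.i_dTv])  / p[IP_TAU_TV];
    if (variant == 2) {
      dy[L.i_dERV] = (sig_erv - y[L.i_dERV]) / p[IP_TAU_ERV];
      dy[L.i_dVun] = (sig_vun - y[L.i_dVun]) / p[IP_TAU_VUN];
    }
    dhTau = g * (p[IP_TAU_HR0] + y[L.i_dTs] + y[L.i_dTv] - y[L.i_hTau]);
    dhELV = g * (p[IP_ELVMAX] + y[L.i_dELV] - y[L.i_hELV]);
    dy[L.i_hTau] = dhTau;
    dy[L.i_hELV] = dhELV;
    if (variant == 2) {
      dhERV = g * (p[IP_ERVMAX] + y[L.i_dERV] - y[L.i_hERV]);
      dy[L.i_hERV] = dhERV;
    }
  }

  // ventricular elastance on the current beat's held period
  double tc = t - tb;
  if (tc >= tau) tc -= tau * std::floor(tc / tau);   // safety; crossings handled outside
  double Elv, dElv;
  chamber_elastance(tc, tau, dhTau, p[IP_TINITV], p[IP_TS1V], p[IP_TS2V],
                    p[IP_ELVMIN], ELVmx, dhELV, &Elv, &dElv, nullptr);

  if (variant == 1) {
    double Plv = y[0], Part = y[1], Pven = y[2];
    double Qmv  = valve(Pven, Plv, p[IP_RMV]);
    double Qav  = valve(Plv, Part, p[IP_RAV]);
    double Qsys = (Part - Pven) / Rsys;
    double dPart = (Qav - Qsys) / p[IP_CART];
    dy[0] = (dElv / Elv) * Plv + Elv * (Qmv - Qav);
    dy[1] = dPart;
    dy[2] = (Qsys - Qmv) / p[IP_CVEN];
    if (reg)
      dy[L.ipt] = (Part + p[IP_TAUZ] * dPart - y[L.ipt]) / p[IP_TAUP];
    if (aux) {
      aux->Qmv = Qmv; aux->Qav = Qav; aux->Qsys = Qsys;
      aux->Qtv = aux->Qpv = aux->Qpul = NA_REAL;
      aux->Elv = Elv; aux->Erv = aux->Era = aux->Ela = NA_REAL;
      aux->tau = tau; aux->Rsys_t = Rsys;
    }
    return;
  }

  // ---- 4CH ----
  double ERVmx = reg ? y[L.i_hERV] : p[IP_ERVMAX];
  double Erv, dErv;   // shared ventricular timing
  chamber_elastance(tc, tau, dhTau, p[IP_TINITV], p[IP_TS1V], p[IP_TS2V],
                    p[IP_ERVMIN], ERVmx, dhERV, &Erv, &dErv, nullptr);

  // atrial activation: modular shift by tau_initA, systole spans the
  // cycle boundary (0.92 tau .. 1.0 tau by default)
  double Era, dEra, Ela, dEla;
  chamber_elastance(tc, tau, dhTau, p[IP_TINITA], p[IP_TS1A], p[IP_TS2A],
                    p[IP_ERAMIN], p[IP_ERAMAX], 0.0, &Era, &dEra, nullptr);
  chamber_elastance(tc, tau, dhTau, p[IP_TINITA], p[IP_TS1A], p[IP_TS2A],
                    p[IP_ELAMIN], p[IP_ELAMAX], 0.0, &Ela, &dEla, nullptr);

  double Plv = y[0], Part = y[1], Pra = y[2], Prv = y[3], Ppa = y[4], Pla = y[5];
  double Qmv  = valve(Pla, Plv, p[IP_RMV]);
  double Qav  = valve(Plv, Part, p[IP_RAV]);
  double Qtv  = valve(Pra, Prv, p[IP_RTV]);
  double Qpv  = valve(Prv, Ppa, p[IP_RPV]);
  double Qsys = (Part - Pra) / Rsys;
  double Qpul = (Ppa - Pla) / p[IP_RPUL];

  // a decrease in unstressed volume injects stressed volume: -dDeltaVun/dt
  double ireg = (reg && L.i_dVun >= 0) ? -dy[L.i_dVun] : 0.0;

  double dPart = (Qav - Qsys) / p[IP_CART];
  dy[0] = (dElv / Elv) * Plv + Elv * (Qmv - Qav);
  dy[1] = dPart;
  dy[2] = (Era * (Qsys + ireg - Qtv) + (dEra / Era) * Pra) /
          (1.0 + p[IP_CVEN] * Era);
  dy[3] = (dErv / Erv) * Prv + Erv * (Qtv - Qpv);
  dy[4] = (Qpv - Qpul) / p[IP_CPULA];
  dy[5] = (Ela * (Qpul - Qmv) + (dEla / Ela) * Pla) /
          (1.0 + p[IP_CPULV] * Ela);
  if (reg)
    dy[L.ipt] = (Part + p[IP_TAUZ] * dPart - y[L.ipt]) / p[IP_TAUP];
  if (aux) {
    aux->Qmv = Qmv; aux->Qav = Qav; aux->Qtv = Qtv; aux->Qpv = Qpv;
    aux->Qsys = Qsys; aux->Qpul = Qpul;
    aux->Elv = Elv; aux->Erv = Erv; aux->Era = Era; aux->Ela = Ela;
    aux->tau = tau; aux->Rsys_t = Rsys;
  }
}

// total stressed volume (+ unstressed deviation for regulated 4CH, so the
// monitored quantity is conserved in every variant)
static double total_volume(int variant, bool reg, const double* p,
                           double t, double tb, const double* y) {
  Layout L = layout_for(variant, reg);
  double tau   = reg ? y[L.i_hTau] : p[IP_TAU_HR0];
  double ELVmx = reg ? y[L.i_hELV] : p[IP_ELVMAX];
  double tc = t - tb; if (tc >= tau) tc -= tau * std::floor(tc / tau);
  double eV = activation(tc, p[IP_TS1V] * tau, p[IP_TS2V] * tau);
  double Elv = (ELVmx - p[IP_ELVMIN]) * eV + p[IP_ELVMIN];
  if (variant == 1)
    return y[0] / Elv + p[IP_CART] * y[1] + p[IP_CVEN] * y[2];
  double ERVmx = reg ? y[L.i_hERV] : p[IP_ERVMAX];
  double Erv = (ERVmx - p[IP_ERVMIN]) * eV + p[IP_ERVMIN];
  double tca = tc - p[IP_TINITA] * tau; if (tca < 0) tca += tau;
  double eA = activation(tca, (p[IP_TS1A] - p[IP_TINITA]) * tau,
                         (p[IP_TS2A] - p[IP_TINITA]) * tau);
  double Era = (p[IP_ERAMAX] - p[IP_ERAMIN]) * eA + p[IP_ERAMIN];
  double Ela = (p[IP_ELAMAX] - p[IP_ELAMIN]) * eA + p[IP_ELAMIN];
  double v = y[0] / Elv + p[IP_CART] * y[1] +
             p[IP_CVEN] * y[2] + y[2] / Era +
             y[3] / Erv + p[IP_CPULA] * y[4] +
             p[IP_CPULV] * y[5] + y[5] / Ela;
  if (reg) v += y[L.i_dVun];   // stressed + unstressed deviation
  return v;
}

// ---- history ring buffer (value + derivative of P~ at fixed-step nodes) ----
struct History {
  std::vector<double> val, der;
  double t0, h, p0;   // p0: constant pre-history
  int cap, count;     // count = number of stored nodes (node i at t0 + i*h)
  void init(double t0_, double h_, double p0_, double maxlag) {
    t0 = t0_; h = h_; p0 = p0_;
    cap = (int)std::ceil(maxlag / h) + 8;
    val.assign(cap, 0.0); der.assign(cap, 0.0); count = 0;
  }
  void push(double v, double d) {
    val[count % cap] = v; der[count % cap] = d; ++count;
  }
  // cubic Hermite interpolation of P~ at time tq (<= last stored node time)
  double at(double tq) const {
    if (tq <= t0 || count == 0) return p0;
    double s = (tq - t0) / h;
    int i = (int)std::floor(s);
    double u = s - i;
    if (i >= count - 1) { // at (or numerically past) the newest node
      return val[(count - 1) % cap];
    }
    double y0 = val[i % cap], y1 = val[(i + 1) % cap];
    double d0 = der[i % cap] * h, d1 = der[(i + 1) % cap] * h;
    double u2 = u * u, u3 = u2 * u;
    return (2 * u3 - 3 * u2 + 1) * y0 + (u3 - 2 * u2 + u) * d0 +
           (-2 * u3 + 3 * u2) * y1 + (u3 - u2) * d1;
  }
};

static inline Lags lags_at(const History& H, const double* p, double t,
                           bool reg, int variant) {
  Lags L{0, 0, 0, 0, 0, 0};
  if (!reg) return L;
  L.elv  = H.at(t - p[IP_D_ELV]);
  L.rsys = H.at(t - p[IP_D_RSYS]);
  L.ts   = H.at(t - p[IP_D_TS]);
  L.tv   = H.at(t - p[IP_D_TV]);
  if (variant == 2) {
    L.erv = H.at(t - p[IP_D_ERV]);
    L.vun = H.at(t - p[IP_D_VUN]);
  }
  return L;
}

// per-beat output accumulator
struct BeatAcc {
  double pmax[6], pmin[6], vmax, vmin, t_start;
  void reset(double t, int np) {
    for (int k = 0; k < np; ++k) { pmax[k] = -1e300; pmin[k] = 1e300; }
    vmax = -1e300; vmin = 1e300; t_start = t;
  }
  void absorb(const double* y, double vlv, int np) {
    for (int k = 0; k < np; ++k) {
      if (y[k] > pmax[k]) pmax[k] = y[k];
      if (y[k] < pmin[k]) pmin[k] = y[k];
    }
    if (vlv > vmax) vmax = vlv;
    if (vlv < vmin) vmin = vlv;
  }
};

struct RunResult {
  NumericMatrix traj;          // optional sampled trajectory
  std::vector<double> beats;   // beat onset times
  std::vector<double> beat_tau;
  double out[16];              // CO, tau, Vmax, Vmin, then pmax/pmin pairs
  int n_out;
  double vol_drift;            // max |V - V0| / V0 over samples
  double vol_correction;       // max per-step projection defect (relative)
  bool ok;
  double t_fail;
};

// core integration loop
static RunResult integrate_core(const double* p, int variant, bool reg,
                                double t_end, double h, double sample_dt,
                                double sigma_w, double gain,
                                const std::vector<double>& y0,
                                bool store) {
  Layout L = layout_for(variant, reg);
  const int n = L.n;
  const int npress = (variant == 1) ? 3 : 6;
  RunResult R; R.ok = true; R.t_fail = NA_REAL;

  std::vector<double> y(y0), k1(n), k2(n), k3(n), k4(n), yt(n);
  double t = 0.0, tb = 0.0;

  History H;
  double maxlag = 1.0;
  if (reg) {
    maxlag = std::max(p[IP_D_ELV], std::max(p[IP_D_RSYS],
             std::max(p[IP_D_TS], p[IP_D_TV])));
    if (variant == 2)
      maxlag = std::max(maxlag, std::max(p[IP_D_ERV], p[IP_D_VUN]));
    maxlag = std::max(maxlag, 2 * h);
  }
  H.init(0.0, h, reg ? y0[L.ipt] : 0.0, maxlag);

  long nstep = (long)std::ceil(t_end / h - 1e-9);
  int nsamp = store ? (int)std::floor(t_end / sample_dt + 1e-9) + 1 : 0;
  int ncol = 0;
  // trajectory columns: time, states..., V_LV, (V_RV), total_volume,
  // Q's, E_LV, tau, Rsys_t (assembled below)
  int extra = (variant == 1) ? 8 : 12;
  if (store) {
    ncol = 1 + n + extra;
    R.traj = NumericMatrix(nsamp, ncol);
  }
  int isamp = 0;
  double next_sample = 0.0;
  double vol0 = total_volume(variant, reg, p, 0.0, 0.0, y0.data());
  R.vol_drift = 0.0;

  BeatAcc cur, done;
  cur.reset(0.0, npress);
  bool have_done = false;
  R.beats.push_back(0.0);

  Aux aux;
  Lags lg = lags_at(H, p, 0.0, reg, variant);
  rhs(variant, reg, p, 0.0, tb, y.data(), lg, sigma_w, gain, k1.data(), &aux);

  auto sample_row = [&](double tt, const double* yy, const Aux& ax) {
    if (!store || isamp >= nsamp) return;
    double vlv = yy[0] / ax.Elv;
    double vol = total_volume(variant, reg, p, tt, tb, yy);
    double dr = std::fabs(vol - vol0) / std::fabs(vol0);
    if (dr > R.vol_drift) R.vol_drift = dr;
    int c = 0;
    R.traj(isamp, c++) = tt;
    for (int j = 0; j < n; ++j) R.traj(isamp, c++) = yy[j];
    R.traj(isamp, c++) = vlv;
    if (variant == 2) R.traj(isamp, c++) = yy[3] / ax.Erv;
    R.traj(isamp, c++) = vol;
    R.traj(isamp, c++) = ax.Qmv;
    R.traj(isamp, c++) = ax.Qav;
    if (variant == 2) {
      R.traj(isamp, c++) = ax.Qtv;
      R.traj(isamp, c++) = ax.Qpv;
    }
    R.traj(isamp, c++) = ax.Qsys;
    if (variant == 2) R.traj(isamp, c++) = ax.Qpul;
    R.traj(isamp, c++) = ax.Elv;
    R.traj(isamp, c++) = ax.tau;
    R.traj(isamp, c++) = ax.Rsys_t;
    ++isamp;
  };

  sample_row(0.0, y.data(), aux);
  next_sample += sample_dt;
  cur.absorb(y.data(), y[0] / aux.Elv, npress);
  H.push(reg ? y[L.ipt] : 0.0, reg ? k1[L.ipt] : 0.0);

  // chamber elastance at the current state (for extrema tracking)
  auto elv_now = [&]() {
    double tau_c = reg ? y[L.i_hTau] : p[IP_TAU_HR0];
    double em = reg ? y[L.i_hELV] : p[IP_ELVMAX];
    double tc = t - tb; if (tc >= tau_c) tc -= tau_c * std::floor(tc / tau_c);
    double e = activation(tc, p[IP_TS1V] * tau_c, p[IP_TS2V] * tau_c);
    return (em - p[IP_ELVMIN]) * e + p[IP_ELVMIN];
  };

  // beat bookkeeping, applied promptly after every (sub)step so the
  // cycle coordinate never runs past the held period by more than a
  // substep (the wrap would otherwise fight the promotion bump)
  auto after_step = [&]() {
    cur.absorb(y.data(), y[0] / elv_now(), npress);
    double tau_now = reg ? y[L.i_hTau] : p[IP_TAU_HR0];
    if (t - tb >= tau_now - 1e-12) {
      double blen = t - cur.t_start;
      done = cur; done.t_start = blen; have_done = true;
      R.beat_tau.push_back(tau_now);
      tb = tb + tau_now;
      R.beats.push_back(tb);
      cur.reset(t, npress);
      cur.absorb(y.data(), y[0] / elv_now(), npress);
    }
  };

  // one classical RK4 step of size hh from (t, y), in place
  auto rk4_step = [&](double hh) {
    lg = lags_at(H, p, t, reg, variant);
    rhs(variant, reg, p, t, tb, y.data(), lg, sigma_w, gain, k1.data(), nullptr);

    double th = t + 0.5 * hh;
    for (int j = 0; j < n; ++j) yt[j] = y[j] + 0.5 * hh * k1[j];
    lg = lags_at(H, p, th, reg, variant);
    rhs(variant, reg, p, th, tb, yt.data(), lg, sigma_w, gain, k2.data(), nullptr);

    for (int j = 0; j < n; ++j) yt[j] = y[j] + 0.5 * hh * k2[j];
    rhs(variant, reg, p, th, tb, yt.data(), lg, sigma_w, gain, k3.data(), nullptr);

    double t1 = t + hh;
    for (int j = 0; j < n; ++j) yt[j] = y[j] + hh * k3[j];
    lg = lags_at(H, p, t1, reg, variant);
    rhs(variant, reg, p, t1, tb, yt.data(), lg, sigma_w, gain, k4.data(), nullptr);

    for (int j = 0; j < n; ++j)
      y[j] += hh / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
    t = t1;
  };

  // valve pressure gradients (sign changes flag a diode switching event)
  auto valve_signs = [&](unsigned& mask) {
    mask = 0;
    if (variant == 1) {
      if (y[2] > y[0]) mask |= 1;            // MV: ven -> LV
      if (y[0] > y[1]) mask |= 2;            // AV: LV -> art
    } else {
      if (y[5] > y[0]) mask |= 1;            // MV: LA -> LV
      if (y[0] > y[1]) mask |= 2;            // AV
      if (y[2] > y[3]) mask |= 4;            // TV
      if (y[3] > y[4]) mask |= 8;            // PV
    }
  };

  // activation branch codes (rising / falling / off) for every active
  // chamber at a given absolute time; a change inside a step marks an
  // elastance curvature joint
  auto branch_code = [&](double tt) {
    double tau_c = reg ? y[L.i_hTau] : p[IP_TAU_HR0];
    double tc = tt - tb;
    if (tc >= tau_c) tc -= tau_c * std::floor(tc / tau_c);
    int code = (tc < p[IP_TS1V] * tau_c) ? 0 :
               (tc < p[IP_TS2V] * tau_c) ? 1 : 2;
    if (variant == 2) {
      double tca = tc - p[IP_TINITA] * tau_c;
      if (tca < 0) tca += tau_c;
      int ca = (tca < (p[IP_TS1A] - p[IP_TINITA]) * tau_c) ? 0 :
               (tca < (p[IP_TS2A] - p[IP_TINITA]) * tau_c) ? 1 : 2;
      code = 3 * code + ca;
    }
    return code;
  };

  // conservative projection: the closed loop conserves total volume
  // exactly; step truncation at valve/activation kinks would otherwise
  // let the invariant wander (path-dependently in the parameters).
  // After each step the (tiny) defect is distributed uniformly over the
  // pressure states, pinning the invariant to machine precision.
  double max_defect = 0.0;
  auto project_volume = [&](double v_target) {
    double vol = total_volume(variant, reg, p, t, tb, y.data());
    double rel = std::fabs(v_target - vol) / std::fabs(v_target);
    if (rel > max_defect) max_defect = rel;
    double tau_c = reg ? y[L.i_hTau] : p[IP_TAU_HR0];
    double em = reg ? y[L.i_hELV] : p[IP_ELVMAX];
    double tc = t - tb; if (tc >= tau_c) tc -= tau_c * std::floor(tc / tau_c);
    double eV = activation(tc, p[IP_TS1V] * tau_c, p[IP_TS2V] * tau_c);
    double Elv = (em - p[IP_ELVMIN]) * eV + p[IP_ELVMIN];
    double S;
    if (variant == 1) {
      S = 1.0 / Elv + p[IP_CART] + p[IP_CVEN];
    } else {
      double erm = reg ? y[L.i_hERV] : p[IP_ERVMAX];
      double Erv = (erm - p[IP_ERVMIN]) * eV + p[IP_ERVMIN];
      double tca = tc - p[IP_TINITA] * tau_c; if (tca < 0) tca += tau_c;
      double eA = activation(tca, (p[IP_TS1A] - p[IP_TINITA]) * tau_c,
                             (p[IP_TS2A] - p[IP_TINITA]) * tau_c);
      double Era = (p[IP_ERAMAX] - p[IP_ERAMIN]) * eA + p[IP_ERAMIN];
      double Ela = (p[IP_ELAMAX] - p[IP_ELAMIN]) * eA + p[IP_ELAMIN];
      S = 1.0 / Elv + p[IP_CART] + p[IP_CVEN] + 1.0 / Era +
          1.0 / Erv + p[IP_CPULA] + p[IP_CPULV] + 1.0 / Ela;
    }
    double dP = (v_target - vol) / S;
    int npr = (variant == 1) ? 3 : 6;
    for (int k = 0; k < npr; ++k) y[k] += dP;
  };

  std::vector<double> y_save(n);
  for (long s = 0; s < nstep; ++s) {
    // resolve the stiff promotion bump: sub-step near a bump centre
    bool near_bump = false;
    if (reg) {
      double tau_now = y[L.i_hTau];
      double d1 = std::fabs(t + 0.5 * h - tb);
      double d2 = std::fabs(t + 0.5 * h - (tb + tau_now));
      near_bump = std::min(d1, d2) < 8.0 * sigma_w + h;
    }
    if (near_bump) {
      for (int sub = 0; sub < 16; ++sub) { rk4_step(h / 16.0); after_step(); }
    } else {
      // trial step; redo with substeps if a valve switched inside it,
      // so the diode kink never sits inside a full-length step
      double t_save = t, tb_save = tb;
      y_save = y;
      unsigned m0, m1;
      int b0 = branch_code(t), b1 = branch_code(t + h);
      valve_signs(m0);
      rk4_step(h);
      valve_signs(m1);
      if (m0 != m1 || b0 != b1) {
        t = t_save; tb = tb_save; y = y_save;
        for (int sub = 0; sub < 16; ++sub) { rk4_step(h / 16.0); after_step(); }
      } else {
        after_step();
      }
    }
    t = (s + 1) * h;   // keep the node grid exact for the history buffer

    if (!std::isfinite(y[0]) || !std::isfinite(y[1])) {
      R.ok = false; R.t_fail = t; break;
    }
    project_volume(vol0);

    // derivative at the new node for the history buffer + sampling aux
    lg = lags_at(H, p, t, reg, variant);
    rhs(variant, reg, p, t, tb, y.data(), lg, sigma_w, gain, k1.data(), &aux);
    H.push(reg ? y[L.ipt] : 0.0, reg ? k1[L.ipt] : 0.0);

    if (t >= next_sample - 1e-9) {
      sample_row(t, y.data(), aux);
      next_sample += sample_dt;
    }
  }

  // outputs from the last COMPLETE beat
  R.n_out = 4 + 2 * npress;
  if (have_done && R.ok) {
    double blen = done.t_start;
    R.out[0] = (done.vmax - done.vmin) / blen;  // CO (ml/s)
    R.out[1] = blen;                            // heart period
    R.out[2] = done.vmax; R.out[3] = done.vmin;
    for (int k = 0; k < npress; ++k) {
      R.out[4 + 2 * k]     = done.pmax[k];
      R.out[4 + 2 * k + 1] = done.pmin[k];
    }
  } else {
    for (int k = 0; k < R.n_out; ++k) R.out[k] = NA_REAL;
    if (have_done == false) R.ok = false;
  }
  R.vol_correction = max_defect;
  if (store) {
    // truncate if fewer samples than allocated (failed run)
    if (isamp < nsamp) R.traj = R.traj(Range(0, std::max(isamp - 1, 0)), _);
  }
  return R;
}

static std::vector<double> default_init(const double* p, int variant, bool reg) {
  Layout L = layout_for(variant, reg);
  std::vector<double> y0(L.n, 0.0);
  int npress = (variant == 1) ? 3 : 6;
  for (int k = 0; k < npress; ++k) y0[k] = p[IP_PINIT];
  if (reg) {
    y0[L.ipt] = p[IP_PINIT];
    y0[L.i_hTau] = p[IP_TAU_HR0];
    y0[L.i_hELV] = p[IP_ELVMAX];
    if (variant == 2) y0[L.i_hERV] = p[IP_ERVMAX];
  }
  return y0;
}

// ---- exported interfaces ----

// [[Rcpp::export]]
List cv_integrate(NumericVector packed, int variant, bool regulated,
                  double t_end, double h, double sample_dt,
                  double sigma_w, double gain,
                  Nullable<NumericVector> init = R_NilValue,
                  bool store = true) {
  if (packed.size() != NPACK) stop("packed parameter vector has wrong length");
  const double* p = REAL(packed);
  Layout L = layout_for(variant, regulated);
  std::vector<double> y0;
  if (init.isNotNull()) {
    NumericVector iv(init);
    if ((int)iv.size() != L.n) stop("init state has wrong length");
    y0.assign(iv.begin(), iv.end());
  } else {
    y0 = default_init(p, variant, regulated);
  }
  RunResult R = integrate_core(p, variant, regulated, t_end, h, sample_dt,
                               sigma_w, gain, y0, store);
  return List::create(
    _["traj"] = R.traj,
    _["beats"] = NumericVector(R.beats.begin(), R.beats.end()),
    _["beat_tau"] = NumericVector(R.beat_tau.begin(), R.beat_tau.end()),
    _["outputs"] = NumericVector(R.out, R.out + R.n_out),
    _["vol_drift"] = R.vol_drift,
    _["vol_correction"] = R.vol_correction,
    _["ok"] = R.ok,
    _["t_fail"] = R.t_fail);
}

// batch evaluation for sensitivity analysis: one row of `packed_rows` per
// model run; returns the clinical output vector per run (extrema tracked at
// every integration step, no trajectory storage)
// [[Rcpp::export]]
NumericMatrix cv_batch_outputs(NumericMatrix packed_rows, int variant,
                               bool regulated, double t_end, double h,
                               double sigma_w, double gain) {
  if (packed_rows.ncol() != NPACK) stop("packed matrix has wrong width");
  int K = packed_rows.nrow();
  int npress = (variant == 1) ? 3 : 6;
  int n_out = 4 + 2 * npress;
  NumericMatrix out(K, n_out);
  std::vector<double> prow(NPACK);
  for (int i = 0; i < K; ++i) {
    for (int j = 0; j < NPACK; ++j) prow[j] = packed_rows(i, j);
    std::vector<double> y0 = default_init(prow.data(), variant, regulated);
    RunResult R = integrate_core(prow.data(), variant, regulated, t_end, h,
                                 0.0, sigma_w, gain, y0, false);
    for (int k = 0; k < n_out; ++k)
      out(i, k) = R.ok ? R.out[k] : NA_REAL;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// raw right-hand side, for oracle tests: lagged P~ values supplied explicitly
// in pathway order (E_LVmax, E_RVmax, R_sys, V_unV, tau_s, tau_v)
// [[Rcpp::export]]
NumericVector cv_rhs_raw(NumericVector packed, int variant, bool regulated,
                         double t, NumericVector state, double t_b,
                         NumericVector ptilde_lags,
                         double sigma_w = 1e-3, double gain = 12.0) {
  if (packed.size() != NPACK) stop("packed parameter vector has wrong length");
  Layout L = layout_for(variant, regulated);
  if ((int)state.size() != L.n) stop("state has wrong length");
  Lags lg{0, 0, 0, 0, 0, 0};
  if (regulated) {
    if (ptilde_lags.size() < 6) stop("need 6 lagged values");
    lg.elv = ptilde_lags[0]; lg.erv = ptilde_lags[1]; lg.rsys = ptilde_lags[2];
    lg.vun = ptilde_lags[3]; lg.ts = ptilde_lags[4]; lg.tv = ptilde_lags[5];
  }
  NumericVector dy(L.n);
  rhs(variant, regulated, REAL(packed), t, t_b, REAL(state), lg,
      sigma_w, gain, REAL(dy), nullptr);
  return dy;
}

// [[Rcpp::export]]
NumericVector cv_activation(NumericVector t_cycle, double tau_es, double tau_ep) {
  int m = t_cycle.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) out[i] = activation(t_cycle[i], tau_es, tau_ep);
  return out;
}

// [[Rcpp::export]]
NumericVector cv_valve_flow(NumericVector p_up, NumericVector p_down,
                            double r_val) {
  int m = std::max(p_up.size(), p_down.size());
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = valve(p_up[i % p_up.size()], p_down[i % p_down.size()], r_val);
  return out;
}

// [[Rcpp::export]]
double cv_total_volume(NumericVector packed, int variant, bool regulated,
                       double t, double t_b, NumericVector state) {
  return total_volume(variant, regulated, REAL(packed), t, t_b, REAL(state));
}
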