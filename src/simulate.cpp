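// Fixed-step integrator for the delay-differential cardiovascular model.
// Mirrors the pure-R equation layer (R/model_core.R); validated against its
// closed forms in the test suite. RK4 on the smooth branches, linear
// interpolation of the phase crossing for beat times, history ring with
// linear interpolation for the delayed sympathetic/parasympathetic signals.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double t0, t_sys, s_hat, s0, k_sc, k_sv, k_st, n_c;
  double r0c, k_Rv, k_pB, t_br;
  double p0, p0l, k1, k2, k1l, k2l;
  double a_s, b_s, y_s, a_sl, b_sl, y_sl, v_s0, v_sl0, k_sr, k_slr;
  double tau_c, tau_v, theta_c, theta_v, theta_p, k_cS, k_vS, k_v;
  double v_p0, k_pb, k_pr, k_phip, v_hat_p, n_p;
  double k_phic, c_hat_c, n_s;
  // preset
  double c_sb, c_slb, c_sv, c_slv, c_pv, c_pk, c_phis, c_phip;
  bool peaked, centered, denervated;
};

inline double getp(const List& l, const char* nm) {
  return as<double>(l[nm]);
}

inline double Fphi(double phi) {
  if (phi <= 0.0 || phi >= 1.0) return 0.0;
  double om = 1.0 - phi, om3 = om * om * om;
  return std::pow(phi, 1.3) * (phi - 0.45) * om3 / (0.008 + om3);
}

inline double fs_fun(const Pars& P, double cc) {
  double sat;
  if (cc <= 0.0) sat = cc;
  else {
    double cn = std::pow(cc, P.n_s), chn = std::pow(P.c_hat_c, P.n_s);
    sat = cc + (P.c_hat_c - cc) * cn / (chn + cn);
  }
  return 1.0 + (P.c_phis + P.k_phic) * sat;
}

inline double fp_fun(const Pars& P, double vp, double phi) {
  if (vp < 0.0) vp = 0.0;
  double vn = std::pow(vp, P.n_p), vhn = std::pow(P.v_hat_p, P.n_p);
  double g = vp + (P.v_hat_p - vp) * vn / (vhn + vn);
  return 1.0 + (P.c_phip + P.k_phip) * g * Fphi(phi);
}

inline double contractility(const Pars& P, double cc, double cv, double Lprev) {
  double sp = P.s0 + P.k_sc * cc + P.k_sv * cv + P.k_st * Lprev;
  if (sp <= 0.0) return sp;
  double sn = std::pow(sp, P.n_c), shn = std::pow(P.s_hat, P.n_c);
  return sp + (P.s_hat - sp) * sn / (shn + sn);
}

inline double symp(const Pars& P, double vb, double B, bool heart) {
  double a, b, y, v0, kr, cb, cv;
  if (heart) { a = P.a_s; b = P.b_s; y = P.y_s; v0 = P.v_s0; kr = P.k_sr;
               cb = P.c_sb; cv = P.c_sv; }
  else       { a = P.a_sl; b = P.b_sl; y = P.y_sl; v0 = P.v_sl0; kr = P.k_slr;
               cb = P.c_slb; cv = P.c_slv; }
  double arg = P.centered ? (b + cb) * (vb - v0) - cv
                          : (b + cb) * vb - cv - v0;
  return a * std::tanh(arg) + y + kr * B;
}

inline double para(const Pars& P, double vb, double B) {
  double v = P.c_pv + P.v_p0 + (P.c_pk + P.k_pb) * vb + P.k_pr * std::fabs(B);
  return v > 0.0 ? v : 0.0;
}

// history lookup with linear interpolation; index k holds time (k - pad)*dt
inline double hlook(const std::vector<double>& h, double t, double dt,
                    int pad, int last) {
  double u = t / dt + pad;
  if (u <= 0.0) return h[0];
  int i = (int)std::floor(u);
  if (i >= last) return h[last];
  double fr = u - i;
  return h[i] * (1.0 - fr) + h[i + 1] * fr;
}

} // namespace

// [[Rcpp::export]]
List cvs_simulate_cpp(List params, List preset, double duration, double dt,
                      NumericVector xi_seq, NumericVector zeta_seq,
                      bool peaked, bool centered, bool denervated,
                      double p_init, bool record_traces, int trace_every) {
  Pars P;
  P.t0 = getp(params, "t0"); P.t_sys = getp(params, "t_sys");
  P.s_hat = getp(params, "s_hat"); P.s0 = getp(params, "s0");
  P.k_sc = getp(params, "k_sc"); P.k_sv = getp(params, "k_sv");
  P.k_st = getp(params, "k_st"); P.n_c = getp(params, "n_c");
  P.r0c = getp(params, "r0c"); P.k_Rv = getp(params, "k_Rv");
  P.k_pB = getp(params, "k_pB"); P.t_br = getp(params, "t_br");
  P.p0 = getp(params, "p0"); P.p0l = getp(params, "p0l");
  P.k1 = getp(params, "k1"); P.k2 = getp(params, "k2");
  P.k1l = getp(params, "k1l"); P.k2l = getp(params, "k2l");
  P.a_s = getp(params, "a_s"); P.b_s = getp(params, "b_s");
  P.y_s = getp(params, "y_s"); P.a_sl = getp(params, "a_sl");
  P.b_sl = getp(params, "b_sl"); P.y_sl = getp(params, "y_sl");
  P.v_s0 = getp(params, "v_s0"); P.v_sl0 = getp(params, "v_sl0");
  P.k_sr = getp(params, "k_sr"); P.k_slr = getp(params, "k_slr");
  P.tau_c = getp(params, "tau_c"); P.tau_v = getp(params, "tau_v");
  P.theta_c = getp(params, "theta_c"); P.theta_v = getp(params, "theta_v");
  P.theta_p = getp(params, "theta_p");
  P.k_cS = getp(params, "k_cS"); P.k_vS = getp(params, "k_vS");
  P.k_v = getp(params, "k_v");
  P.v_p0 = getp(params, "v_p0"); P.k_pb = getp(params, "k_pb");
  P.k_pr = getp(params, "k_pr"); P.k_phip = getp(params, "k_phip");
  P.v_hat_p = getp(params, "v_hat_p"); P.n_p = getp(params, "n_p");
  P.k_phic = getp(params, "k_phic"); P.c_hat_c = getp(params, "c_hat_c");
  P.n_s = getp(params, "n_s");
  P.c_sb = getp(preset, "c_sb"); P.c_slb = getp(preset, "c_slb");
  P.c_sv = getp(preset, "c_sv"); P.c_slv = getp(preset, "c_slv");
  P.c_pv = getp(preset, "c_pv"); P.c_pk = getp(preset, "c_pk");
  P.c_phis = getp(preset, "c_phis"); P.c_phip = getp(preset, "c_phip");
  P.peaked = peaked; P.centered = centered; P.denervated = denervated;

  const int n_steps = (int)std::lround(duration / dt);
  const double max_delay = std::max(P.theta_c, std::max(P.theta_v, P.theta_p));
  const int pad = (int)std::ceil(max_delay / dt) + 2;

  std::vector<double> hs(n_steps + 1 + pad), hsl(n_steps + 1 + pad),
      hp(n_steps + 1 + pad);

  // resting values (v_b = 0, B = 0) pre-fill the t <= 0 history
  const double vs_rest = symp(P, 0.0, 0.0, true);
  const double vsl_rest = symp(P, 0.0, 0.0, false);
  const double vp_rest = para(P, 0.0, 0.0);
  for (int k = 0; k <= pad; ++k) { hs[k] = vs_rest; hsl[k] = vsl_rest; hp[k] = vp_rest; }

  // state
  double phi = 0.0;
  double cc = P.tau_c * P.k_cS * vs_rest;
  double cv = P.tau_v * P.k_vS * (vsl_rest + P.k_v);
  double p_state = p_init;            // pressure carried through diastole

  // cycle bookkeeping
  bool systole = true;
  double t_beat = 0.0, L_prev = P.t0, D_prev = p_init;
  int xi_idx = 0;
  double xi = 0.0;
  if (xi_seq.size() > 0) {
    xi = xi_seq[xi_idx++];
    while (P.t0 + xi <= 0.2 && xi_idx < xi_seq.size()) xi = xi_seq[xi_idx++];
  }

  // respiration
  double resp_phase = 0.0;
  int zeta_idx = 0;
  double T_resp = P.t_br + (zeta_seq.size() > 0 ? zeta_seq[zeta_idx++] : 0.0);
  if (T_resp < 0.5) T_resp = 0.5;
  double omega = 2.0 * M_PI / T_resp;

  std::vector<double> beat_times, sp_beats, dp_beats;
  double cyc_max = p_init, cyc_min = p_init;

  const int n_tr = record_traces ? (n_steps / trace_every + 1) : 0;
  NumericVector tr_t(n_tr), tr_p(n_tr), tr_phi(n_tr), tr_cc(n_tr), tr_cv(n_tr),
      tr_vs(n_tr), tr_vsl(n_tr), tr_vp(n_tr), tr_B(n_tr);
  int tr_i = 0;

  std::string err = "";
  double err_time = NA_REAL;

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    const double B = std::sin(resp_phase);
    const double Bdot = std::cos(resp_phase) * omega;

    // current pressure and its analytic branch derivative
    double p, dpdt;
    double S_now = contractility(P, cc, cv, L_prev);
    if (systole) {
      const double x = (t - t_beat) / P.t_sys;
      const double kern = P.peaked ? x * std::exp(1.0 - x) : x * std::exp(x);
      const double dkern = P.peaked ? (1.0 - x) * std::exp(1.0 - x)
                                    : (1.0 + x) * std::exp(x);
      p = D_prev + S_now * kern + P.k_pB * B;
      dpdt = S_now * dkern / P.t_sys + P.k_pB * Bdot;
    } else {
      p = p_state;
      const double RC = P.r0c * (1.0 + P.k_Rv * cv);
      if (RC <= 0.05) { err = "non-positive Windkessel time constant"; err_time = t; break; }
      dpdt = -p / RC;
    }

    // afferent activities, recorded for delayed lookups
    const double vb = P.k1 * (p - P.p0) + P.k2 * dpdt;
    const double vbl = P.k1l * (p - P.p0l) + P.k2l * dpdt;
    const double vs_now = symp(P, vb, B, true);
    const double vsl_now = symp(P, vbl, B, false);
    const double vp_now = para(P, vb, B);
    hs[pad + k] = vs_now; hsl[pad + k] = vsl_now; hp[pad + k] = vp_now;
    const int hist_last = pad + k;

    if (p > cyc_max) cyc_max = p;
    if (p < cyc_min) cyc_min = p;

    if (record_traces && (k % trace_every == 0) && tr_i < n_tr) {
      tr_t[tr_i] = t; tr_p[tr_i] = p; tr_phi[tr_i] = phi;
      tr_cc[tr_i] = cc; tr_cv[tr_i] = cv;
      tr_vs[tr_i] = vs_now; tr_vsl[tr_i] = vsl_now; tr_vp[tr_i] = vp_now;
      tr_B[tr_i] = B;
      ++tr_i;
    }

    // RK4 over [t, t+dt] for (phi, cc, cv) and p during diastole
    const double inv_period = 1.0 / (P.t0 + xi);
    auto deriv = [&](double tt, double phi_, double cc_, double cv_, double p_,
                     double& dphi, double& dcc, double& dcv, double& dp) {
      const double vs_d = hlook(hs, tt - P.theta_c, dt, pad, hist_last);
      const double vsl_d = hlook(hsl, tt - P.theta_v, dt, pad, hist_last);
      const double vp_d = hlook(hp, tt - P.theta_p, dt, pad, hist_last);
      const double fs = P.denervated ? 1.0 : fs_fun(P, cc_);
      const double fp = P.denervated ? 1.0 : fp_fun(P, vp_d, phi_);
      dphi = fs * fp * inv_period;
      dcc = -cc_ / P.tau_c + P.k_cS * vs_d;
      dcv = -cv_ / P.tau_v + P.k_vS * (vsl_d + P.k_v);
      dp = systole ? 0.0 : -p_ / (P.r0c * (1.0 + P.k_Rv * cv_));
    };

    double k1phi, k1cc, k1cv, k1p, k2phi, k2cc, k2cv, k2p;
    double k3phi, k3cc, k3cv, k3p, k4phi, k4cc, k4cv, k4p;
    deriv(t, phi, cc, cv, p_state, k1phi, k1cc, k1cv, k1p);
    deriv(t + 0.5 * dt, phi + 0.5 * dt * k1phi, cc + 0.5 * dt * k1cc,
          cv + 0.5 * dt * k1cv, p_state + 0.5 * dt * k1p,
          k2phi, k2cc, k2cv, k2p);
    deriv(t + 0.5 * dt, phi + 0.5 * dt * k2phi, cc + 0.5 * dt * k2cc,
          cv + 0.5 * dt * k2cv, p_state + 0.5 * dt * k2p,
          k3phi, k3cc, k3cv, k3p);
    deriv(t + dt, phi + dt * k3phi, cc + dt * k3cc, cv + dt * k3cv,
          p_state + dt * k3p, k4phi, k4cc, k4cv, k4p);

    const double phi_old = phi;
    phi += dt / 6.0 * (k1phi + 2.0 * k2phi + 2.0 * k3phi + k4phi);
    cc += dt / 6.0 * (k1cc + 2.0 * k2cc + 2.0 * k3cc + k4cc);
    cv += dt / 6.0 * (k1cv + 2.0 * k2cv + 2.0 * k3cv + k4cv);
    if (!systole) p_state += dt / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);

    const double t_next = t + dt;

    // respiration: redraw the period jitter at each cycle boundary
    resp_phase += omega * dt;
    if (resp_phase >= 2.0 * M_PI) {
      resp_phase -= 2.0 * M_PI;
      T_resp = P.t_br + (zeta_idx < zeta_seq.size() ? zeta_seq[zeta_idx++] : 0.0);
      if (T_resp < 0.5) T_resp = 0.5;
      omega = 2.0 * M_PI / T_resp;
    }

    if (!std::isfinite(phi) || !std::isfinite(cc) || !std::isfinite(cv) ||
        !std::isfinite(p_state)) {
      err = "non-finite state"; err_time = t_next; break;
    }

    if (phi >= 1.0) {
      // beat: locate the crossing, close the cycle at the step boundary
      const double frac = (phi - phi_old) > 0.0 ? (1.0 - phi_old) / (phi - phi_old) : 1.0;
      const double tb = t + frac * dt;
      // pressure at the boundary (end of the closing cycle)
      double p_bound;
      const double B_next = std::sin(resp_phase);
      if (systole) {
        const double x = (t_next - t_beat) / P.t_sys;
        const double kern = P.peaked ? x * std::exp(1.0 - x) : x * std::exp(x);
        p_bound = D_prev + contractility(P, cc, cv, L_prev) * kern + P.k_pB * B_next;
      } else {
        p_bound = p_state;
      }
      beat_times.push_back(tb);
      sp_beats.push_back(cyc_max);
      dp_beats.push_back(cyc_min);
      cyc_max = cyc_min = p_bound;
      L_prev = tb - t_beat;
      t_beat = tb;
      D_prev = p_bound;
      phi -= 1.0;  // carry the overshoot: crossing times stay exact
      systole = true;
      if (xi_seq.size() > 0) {
        if (xi_idx >= xi_seq.size()) { err = "noise sequence exhausted"; err_time = t_next; break; }
        xi = xi_seq[xi_idx++];
        while (P.t0 + xi <= 0.2 && xi_idx < xi_seq.size()) xi = xi_seq[xi_idx++];
      }
    } else if (systole && (t_next - t_beat) >= P.t_sys) {
      // systole -> diastole: initialise the Windkessel at the systolic endpoint
      const double x = (t_next - t_beat) / P.t_sys;
      const double kern = P.peaked ? x * std::exp(1.0 - x) : x * std::exp(x);
      const double B_next = std::sin(resp_phase);
      p_state = D_prev + contractility(P, cc, cv, L_prev) * kern + P.k_pB * B_next;
      systole = false;
    }
  }

  List out = List::create(
    _["beat_times"] = wrap(beat_times),
    _["sp"] = wrap(sp_beats),
    _["dp"] = wrap(dp_beats),
    _["error"] = err, _["error_time"] = err_time);
  if (record_traces) {
    if (tr_i < n_tr) {
      tr_t = head(tr_t, tr_i); tr_p = head(tr_p, tr_i); tr_phi = head(tr_phi, tr_i);
      tr_cc = head(tr_cc, tr_i); tr_cv = head(tr_cv, tr_i);
      tr_vs = head(tr_vs, tr_i); tr_vsl = head(tr_vsl, tr_i);
      tr_vp = head(tr_vp, tr_i); tr_B = head(tr_B, tr_i);
    }
    out["trace"] = DataFrame::create(
      _["t"] = tr_t, _["p"] = tr_p, _["phi"] = tr_phi,
      _["c_c"] = tr_cc, _["c_v"] = tr_cv,
      _["v_s"] = tr_vs, _["v_sl"] = tr_vsl, _["v_p"] = tr_vp, _["B"] = tr_B);
  }
  return out;
}

// Mean log divergence of nearest-neighbour trajectories after delay
// embedding (Rosenstein estimator core). Returns the curve <ln L(k)> for
// k = 0..kmax and the pair counts contributing at each k.
// [[Rcpp::export]]
List rosenstein_divergence_cpp(NumericVector x, int dim, int delay,
                               int theiler, int kmax) {
  const int n = x.size();
  const int M = n - (dim - 1) * delay;
  if (M - kmax < dim + 1) stop("too few points for the requested embedding");
  const int nref = M - kmax;

  std::vector<int> nb(nref, -1);
  for (int i = 0; i < nref; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < nref; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        const double diff = x[i + d * delay] - x[j + d * delay];
        d2 += diff * diff;
        if (d2 >= best) break;
      }
      if (d2 < best) { best = d2; bj = j; }
    }
    nb[i] = bj;
  }

  NumericVector curve(kmax + 1);
  IntegerVector counts(kmax + 1);
  for (int k = 0; k <= kmax; ++k) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < nref; ++i) {
      const int j = nb[i];
      if (j < 0) continue;
      double d2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        const double diff = x[i + k + d * delay] - x[j + k + d * delay];
        d2 += diff * diff;
      }
      if (d2 > 0.0) { acc += 0.5 * std::log(d2); ++cnt; }
    }
    curve[k] = cnt > 0 ? acc / cnt : NA_REAL;
    counts[k] = cnt;
  }
  return List::create(_["log_dist"] = curve, _["counts"] = counts);
}
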