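// Fixed-step RK4 integrator for the two-compartment spine calcium model.
// State layout (all concentrations uM, time ms):
//   0  ca_psd          1  ca_spine
//   2..9  NMDAr occupancies (order given by the edge list passed from R)
//   10 m (T-type activation)   11 h (T-type inactivation)
//   12 cam_bound (uM)          13 cbp_bound (uM)
//   14..22 calbindin occupancy lattice x[high*3 + med]
//   23 serca_s2                24 ryr_open
//   25 cumulative transmembrane calcium (spine-volume uM; leak included)
//   26 cumulative calcium moved into the ER store (spine-volume uM)
// The last two make the mass-balance identity
//   ca_spine + (v_psd/v_spine) ca_psd + bound + cum_er - cum_in = const
// hold algebraically in the RHS, so the integrator preserves it to roundoff.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  // geometry / conversions
  double v_ratio;        // v_psd / v_spine
  double c_psd, c_spine; // pA -> uM/ms conversion per compartment
  double diff_spine, diff_psd; // D*a/d / volume
  // environment & constants
  double ca_out_um, mg, ln_na_ratio, vt; // vt = 1000 RT/F (mV)
  // NMDAr
  int n_edge;
  std::vector<int> e_from, e_to, e_glu;
  std::vector<double> e_rate;
  int open_idx;
  double g1, g2, alpha, k0, delta, n_rec, f_eff;
  // VDCC
  double g_vdcc, ghk_f;
  double am_a, am_v0, am_k, bm_a, bm_k, ah_a, ah_k, bh_v0, bh_k;
  // pumps
  double pm_imax, pm_K, pm_h, pm_Kh, nx_g, nx_K, nx_h, nx_Kh;
  // buffers
  double cam_T, cam_h, cam_kf, cam_kr;
  double cbp_T, cbp_kf, cbp_kr;
  double cb_T, cb_konh, cb_koffh, cb_konm, cb_koffm;
  // ER store
  bool er_on;
  double ca_er, se_k1, se_k2, se_rho, ry_ko, ry_kc, ry_nu;
  // drive
  double leak;
  double bap_peak, bap_tr, bap_td, bap_norm, v_rest;
  double glu_amp, glu_dur;
  // stiffness floor: fastest state-independent rate in the system
  double lam_base;
};

inline double efun(double x) {
  return std::fabs(x) < 1e-5 ? 1.0 - x / 2.0 : x / std::expm1(x);
}

// x^h, fast for small integer h (the Hill/cooperativity orders in use)
inline double powh(double x, double h) {
  int hi = (int)h;
  if (h == (double)hi && hi >= 0 && hi <= 6) {
    double r = 1.0;
    for (int i = 0; i < hi; ++i) r *= x;
    return r;
  }
  return std::pow(x, h);
}

// glutamate concentration at time t (square pulses per presynaptic event);
// only events in (t - glu_dur, t] can contribute
inline double glu_at(double t, const std::vector<double>& pre,
                     const Pars& p) {
  double g = 0.0;
  auto hi = std::upper_bound(pre.begin(), pre.end(), t);
  for (auto it = hi; it != pre.begin();) {
    --it;
    if (t - *it >= p.glu_dur) break;
    g += p.glu_amp;
  }
  return g;
}

// spine voltage: rest + superposed bAP waveforms (400 ms support each)
inline double v_at(double t, const std::vector<double>& post,
                   const Pars& p) {
  double v = p.v_rest;
  auto hi = std::upper_bound(post.begin(), post.end(), t);
  for (auto it = hi; it != post.begin();) {
    --it;
    double dt = t - *it;
    if (dt >= 400.0) break;
    v += p.bap_peak *
      (std::exp(-dt / p.bap_td) - std::exp(-dt / p.bap_tr)) / p.bap_norm;
  }
  return v;
}

struct Fluxes {
  double glu, v, open, g_nmda, i_nmda, i_vdcc, i_pmca, i_ncx, j_buf, j_er;
};

void rhs(double t, const double* y, double* dy,
         const std::vector<double>& pre, const std::vector<double>& post,
         const Pars& p, Fluxes* out) {
  const double ca_psd = std::max(y[0], 1e-9);
  const double ca = std::max(y[1], 1e-9);
  const double glu = glu_at(t, pre, p);
  const double v = v_at(t, post, p);

  // NMDAr kinetics
  for (int i = 0; i < 8; ++i) dy[2 + i] = 0.0;
  for (int i = 0; i < p.n_edge; ++i) {
    double k = p.e_rate[i] * (p.e_glu[i] ? glu : 1.0);
    double flux = k * y[2 + p.e_from[i]];
    dy[2 + p.e_from[i]] -= flux;
    dy[2 + p.e_to[i]] += flux;
  }
  const double open = y[2 + p.open_idx];

  // NMDAr calcium current (into PSD), pA, inward-negative
  const double g0 = p.g1 + (p.g2 - p.g1) / (1.0 + std::exp(p.alpha * v));
  const double gmax =
    g0 / (1.0 + (p.mg / p.k0) * std::exp(-p.delta * 2.0 * v / p.vt));
  const double g_nmda = gmax * open * p.n_rec;
  const double v_ca = -(p.vt / 2.0) * 0.4342944819032518 *
    std::log(p.ca_out_um / ca);
  const double i_nmda = 1e-3 * p.f_eff * g_nmda * v_ca;

  // T-type VDCC (into spine)
  const double am = p.am_a * p.am_k * efun((p.am_v0 - v) / p.am_k);
  const double bm = p.bm_a * std::exp(-v / p.bm_k);
  const double ah = p.ah_a * std::exp(-v / p.ah_k);
  const double bh = 1.0 / (std::exp((p.bh_v0 - v) / p.bh_k) + 1.0);
  dy[10] = am * (1.0 - y[10]) - bm * y[10];
  dy[11] = ah * (1.0 - y[11]) - bh * y[11];
  const double nu = v / p.ghk_f;
  const double drive =
    -p.ghk_f * (1.0 - (ca / p.ca_out_um) * std::exp(nu)) * efun(nu);
  const double i_vdcc = 1e-3 * p.g_vdcc * y[10] * y[10] * y[11] * drive;

  // pumps (efflux-positive)
  const double ca_pm = powh(ca, p.pm_h);
  const double i_pmca = p.pm_imax * ca_pm / (p.pm_Kh + ca_pm);
  const double v_naca =
    p.vt * (3.0 * p.ln_na_ratio - std::log(p.ca_out_um / ca));
  const double ca_nx = powh(ca, p.nx_h);
  const double i_ncx = 1e-3 * p.nx_g * std::fabs(v_naca) * ca_nx /
    (p.nx_Kh + ca_nx);

  // buffers
  const double d_cam =
    p.cam_kf * (p.cam_T - y[12]) * powh(ca, p.cam_h) - p.cam_kr * y[12];
  const double d_cbp = p.cbp_kf * (p.cbp_T - y[13]) * ca - p.cbp_kr * y[13];
  dy[12] = d_cam;
  dy[13] = d_cbp;
  double bind = 0.0;
  for (int i = 0; i < 9; ++i) dy[14 + i] = 0.0;
  for (int hi = 0; hi <= 2; ++hi) {
    for (int me = 0; me <= 2; ++me) {
      const int s = 14 + hi * 3 + me;
      const double x = y[s];
      const double fh = (2 - hi) * p.cb_konh * ca * x;
      const double bh2 = hi * p.cb_koffh * x;
      const double fm = (2 - me) * p.cb_konm * ca * x;
      const double bm2 = me * p.cb_koffm * x;
      dy[s] -= fh + bh2 + fm + bm2;
      if (hi < 2) dy[s + 3] += fh;
      if (hi > 0) dy[s - 3] += bh2;
      if (me < 2) dy[s + 1] += fm;
      if (me > 0) dy[s - 1] += bm2;
      bind += fh + fm - bh2 - bm2;
    }
  }
  const double j_buf = -(p.cam_h * d_cam + d_cbp + p.cb_T * bind);

  // ER store
  double j_serca = 0.0, j_ryr = 0.0;
  if (p.er_on) {
    const double f = p.se_k1 * ca * ca * (1.0 - y[23]);
    dy[23] = f - p.se_k2 * y[23];
    j_serca = -2.0 * p.se_rho * f;
    const double ca4 = (ca * ca) * (ca * ca);
    dy[24] = p.ry_ko * ca4 * (1.0 - y[24]) - p.ry_kc * y[24];
    j_ryr = p.ry_nu * y[24] * (p.ca_er - ca);
  } else {
    dy[23] = 0.0;
    dy[24] = 0.0;
  }
  const double j_er = j_serca + j_ryr;

  // compartments
  const double grad = ca_psd - ca;
  dy[0] = -i_nmda * p.c_psd - p.diff_psd * grad;
  dy[1] = p.diff_spine * grad -
    (i_vdcc + i_pmca + i_ncx) * p.c_spine + p.leak + j_buf + j_er;

  // bookkeeping (spine-volume uM)
  dy[25] = -(i_nmda + i_vdcc + i_pmca + i_ncx) * p.c_spine + p.leak;
  dy[26] = -j_er;

  if (out) {
    out->glu = glu; out->v = v; out->open = open; out->g_nmda = g_nmda;
    out->i_nmda = i_nmda; out->i_vdcc = i_vdcc; out->i_pmca = i_pmca;
    out->i_ncx = i_ncx; out->j_buf = j_buf; out->j_er = j_er;
  }
}

Pars build_pars(const List& pl) {
  Pars p;
  const List geom = pl["geometry"];
  const double v_spine = geom["v_spine"], v_psd = geom["v_psd"];
  const double a = geom["a"], d = geom["d"], D = geom["D"];
  p.v_ratio = v_psd / v_spine;
  const List k = pl["constants"];
  const double Fc = k["F"], Rc = k["R"], Tc = k["T"], zc = k["z"];
  p.c_psd = 1e6 / (zc * Fc * v_psd);
  p.c_spine = 1e6 / (zc * Fc * v_spine);
  p.vt = 1000.0 * Rc * Tc / Fc;
  p.diff_spine = D * a / d / v_spine;
  p.diff_psd = D * a / d / v_psd;
  const List env = pl["env"];
  p.ca_out_um = (double)env["ca_out"] * 1000.0;
  p.mg = env["mg_out"];
  p.ln_na_ratio = std::log((double)env["na_out"] / (double)env["na_in"]);
  const List nm = pl["nmdar"];
  const IntegerVector ef = nm["from"], et = nm["to"], eg = nm["glu"];
  const NumericVector er = nm["rate"];
  p.n_edge = ef.size();
  p.e_from.assign(ef.begin(), ef.end());
  p.e_to.assign(et.begin(), et.end());
  p.e_glu.assign(eg.begin(), eg.end());
  p.e_rate.assign(er.begin(), er.end());
  p.open_idx = nm["open_idx"];
  p.g1 = nm["g1"]; p.g2 = nm["g2"]; p.alpha = nm["alpha"];
  p.k0 = nm["k0"]; p.delta = nm["delta"]; p.n_rec = nm["n_receptors"];
  p.f_eff = (double)nm["f_ca"] * (double)nm["ca_scale"];
  const List vd = pl["vdcc"];
  p.g_vdcc = (double)vd["g_single"] * (double)vd["n_open"];
  p.ghk_f = 25.0 * (Tc / 293.15) / 2.0;
  p.am_a = vd["am_a"]; p.am_v0 = vd["am_v0"]; p.am_k = vd["am_k"];
  p.bm_a = vd["bm_a"]; p.bm_k = vd["bm_k"];
  p.ah_a = vd["ah_a"]; p.ah_k = vd["ah_k"];
  p.bh_v0 = vd["bh_v0"]; p.bh_k = vd["bh_k"];
  const List pm = pl["pmca"];
  p.pm_imax = pm["i_max"]; p.pm_K = pm["K"]; p.pm_h = pm["h_c"];
  p.pm_Kh = std::pow(p.pm_K, p.pm_h);
  const List nx = pl["ncx"];
  p.nx_g = nx["g_naca"]; p.nx_K = nx["K"]; p.nx_h = nx["h_c"];
  p.nx_Kh = std::pow(p.nx_K, p.nx_h);
  const List cam = pl["cam"];
  p.cam_T = cam["total"]; p.cam_h = cam["h_c"];
  p.cam_kf = cam["k_f"]; p.cam_kr = cam["k_r"];
  const List cbp = pl["cbp"];
  p.cbp_T = cbp["total"]; p.cbp_kf = cbp["k_f"]; p.cbp_kr = cbp["k_r"];
  const List cb = pl["calbindin"];
  p.cb_T = cb["total"];
  p.cb_konh = cb["kon_h"]; p.cb_koffh = cb["koff_h"];
  p.cb_konm = cb["kon_m"]; p.cb_koffm = cb["koff_m"];
  const List er2 = pl["er"];
  p.er_on = er2["enabled"];
  p.ca_er = er2["ca_er"];
  p.se_k1 = er2["serca_k1"]; p.se_k2 = er2["serca_k2"];
  p.se_rho = er2["serca_rho"];
  p.ry_ko = er2["ryr_ko"]; p.ry_kc = er2["ryr_kc"]; p.ry_nu = er2["ryr_nu"];
  p.leak = pl["leak"];
  const List bap = pl["bap"];
  const double tr = bap["tau_rise"], td = bap["tau_decay"];
  p.bap_tr = tr; p.bap_td = td;
  p.bap_peak = (double)bap["amp"] * (double)bap["atten"];
  const double tpk = std::log(td / tr) * tr * td / (td - tr);
  p.bap_norm = std::exp(-tpk / td) - std::exp(-tpk / tr);
  p.v_rest = bap["v_rest"];
  const List glu = pl["glu"];
  p.glu_amp = glu["amp"];
  p.glu_dur = glu["duration"];
  // fastest state-independent rates: CBP binding, PSD diffusion, glutamate
  // association at pulse amplitude
  double glu_assoc = 0.0;
  for (int i = 0; i < p.n_edge; ++i) {
    if (p.e_glu[i]) glu_assoc += p.e_rate[i] * p.glu_amp;
  }
  p.lam_base = std::max({p.cbp_kf * p.cbp_T + p.cbp_kr, p.diff_psd,
                         glu_assoc});
  return p;
}

} // namespace

// [[Rcpp::export(name = ".sim_spine_cpp")]]
List sim_spine_cpp(List pars, NumericVector y0, NumericVector pre_times,
                   NumericVector post_times, double t_max, double dt,
                   double record_dt, bool average) {
  const Pars p = build_pars(pars);
  const std::vector<double> pre(pre_times.begin(), pre_times.end());
  const std::vector<double> post(post_times.begin(), post_times.end());
  const int ny = 27;
  if (y0.size() != ny) stop("state vector must have length %d", ny);

  const long n_steps = (long)std::llround(t_max / dt);
  const int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  const long n_rec = n_steps / rec_every + 1;
  const int ncol = 16;
  NumericMatrix rec((int)n_rec, ncol);
  colnames(rec) = CharacterVector::create(
    "time", "ca_spine", "ca_psd", "v", "glu", "open", "g_nmda", "i_nmda",
    "i_vdcc", "i_pmca", "i_ncx", "j_buf", "j_er", "m", "cum_in", "cum_er");

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ny), k2(ny), k3(ny), k4(ny), yt(ny);
  Fluxes fx;
  long floor_hits = 0;
  int irec = 0;
  std::vector<double> acc(ncol, 0.0);
  int acc_n = 0;

  auto snapshot = [&](double t) {
    rhs(t, y.data(), k1.data(), pre, post, p, &fx);
    double row[ncol] = {t, y[1], y[0], fx.v, fx.glu, fx.open, fx.g_nmda,
                        fx.i_nmda, fx.i_vdcc, fx.i_pmca, fx.i_ncx, fx.j_buf,
                        fx.j_er, y[10], y[25], y[26]};
    if (average) {
      for (int c = 0; c < ncol; ++c) acc[c] += row[c];
      ++acc_n;
    } else {
      for (int c = 0; c < ncol; ++c) rec(irec, c) = row[c];
    }
  };

  // record initial sample
  snapshot(0.0);
  if (!average) ++irec;

  auto rk4 = [&](double t, double hstep) {
    rhs(t, y.data(), k1.data(), pre, post, p, nullptr);
    for (int i = 0; i < ny; ++i) yt[i] = y[i] + 0.5 * hstep * k1[i];
    rhs(t + 0.5 * hstep, yt.data(), k2.data(), pre, post, p, nullptr);
    for (int i = 0; i < ny; ++i) yt[i] = y[i] + 0.5 * hstep * k2[i];
    rhs(t + 0.5 * hstep, yt.data(), k3.data(), pre, post, p, nullptr);
    for (int i = 0; i < ny; ++i) yt[i] = y[i] + hstep * k3[i];
    rhs(t + hstep, yt.data(), k4.data(), pre, post, p, nullptr);
    for (int i = 0; i < ny; ++i) {
      y[i] += hstep / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
  };

  for (long s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    // fastest local relaxation rate: the cooperative (cubic) calmodulin
    // term and the 4th-power RyR activation grow with calcium, so large
    // transients need internal substeps to stay in the RK4 stability region
    const double ca_now = std::max(y[1], 0.0);
    double lam = p.lam_base;
    lam = std::max(lam, 3.0 * p.cam_kf * p.cam_T * ca_now * ca_now);
    if (p.er_on) {
      const double ca4 = (ca_now * ca_now) * (ca_now * ca_now);
      lam = std::max(lam, p.ry_ko * ca4 + p.ry_kc);
    }
    const int n_sub = 1 + (int)(dt * lam / 1.5);
    const double h = dt / n_sub;
    for (int ss = 0; ss < n_sub; ++ss) rk4(t + ss * h, h);
    for (int i = 0; i < 2; ++i) {
      if (y[i] < 1e-6) { y[i] = 1e-6; ++floor_hits; }
    }
    for (int i = 0; i < ny; ++i) {
      if (!std::isfinite(y[i])) {
        stop("non-finite state at t = %.3f ms (index %d); "
             "reduce `dt` or check parameters", t + dt, i);
      }
    }
    if (average) {
      snapshot(t + dt);
      if ((s + 1) % rec_every == 0) {
        for (int c = 0; c < ncol; ++c) rec(irec, c) = acc[c] / acc_n;
        std::fill(acc.begin(), acc.end(), 0.0);
        acc_n = 0;
        ++irec;
      }
    } else if ((s + 1) % rec_every == 0) {
      snapshot(t + dt);
      ++irec;
    }
    if (s % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(irec, ncol);
  for (int r = 0; r < irec; ++r) {
    for (int c = 0; c < ncol; ++c) out(r, c) = rec(r, c);
  }
  colnames(out) = colnames(rec);
  return List::create(_["record"] = out,
                      _["state"] = NumericVector(y.begin(), y.end()),
                      _["floor_hits"] = (double)floor_hits);
}
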