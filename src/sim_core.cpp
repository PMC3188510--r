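// Fixed-step RK4 integration of the two-ring EIF hypercolumn.
//
// Conductance channels per neuron (difference-of-exponentials state pairs,
// both components incremented by the peak-normalized weight at delivery):
//   0 recurrent fast excitation (AMPA)   1 recurrent slow excitation (NMDA)
//   2 recurrent inhibition (GABA)        3 thalamic (LGN) AMPA
//   4 background AMPA
// Kinetics and reversals are per (channel, target population).
//
// The per-step random draw schedule (one normal for the shared background
// rate, then two Poisson draws per neuron, plus one per neuron with a
// compensation stream) never depends on network state, so paired runs with
// the same seed see identical noise realizations even when a spike delivery
// is suppressed (single-spike perturbation experiment).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NCH = 5;

struct ChannelKin {
  double fd_full, fr_full;   // decay factors over dt
  double fd_half, fr_half;   // decay factors over dt/2
  double fd_sub, fr_sub;     // decay factors over sub-step
  double fd_subh, fr_subh;   // decay factors over sub-step/2
  double erev;
};

// exponential spike-initiation term, exponent clamped to keep RK4 finite
static inline double psi(double v, double vt, double dtl) {
  double x = (v - vt) / dtl;
  if (x > 30.0) x = 30.0;
  return dtl * std::exp(x);
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(
    int n, double dt, int n_warm, int n_rec,
    IntegerVector is_exc,            
    NumericVector inv_tau_m, NumericVector cap,
    NumericVector e_leak, NumericVector v_thresh, NumericVector slope,
    NumericVector v_reset, NumericVector v_cut,
    
    double a_vt1, double tau_vt1, double a_vt2, double tau_vt2,
    double a_dt, double tau_dt, double a_itm, double tau_itm,
    int refr_steps,                  
    
    NumericMatrix tau_r, NumericMatrix tau_d, NumericMatrix erev,
    
    IntegerVector edge_off, IntegerVector edge_tgt,
    NumericVector edge_wf, NumericVector edge_wn,
    IntegerVector edge_ch, IntegerVector edge_delay,
    
    NumericVector lgn_rate_on, NumericVector lgn_rate_off, 
    IntegerVector contrast_state,    
    NumericVector lgn_w, NumericVector bg_w,
    NumericVector comp_rate, NumericVector comp_w, bool has_comp,
    double ou_mu, double ou_sd, double ou_tau,
    NumericVector v_init,
    
    IntegerVector v_idx, int v_stride,
    IntegerVector lfp_off, IntegerVector lfp_idx,
    
    int perturb_neuron, int perturb_k,
    int n_sub) {

  const int n_tot = n_warm + n_rec;
  const double dt_s = dt * 1e-3;      // rates are in Hz, dt in ms
  const double sub = dt / n_sub;

  // per-population channel kinetics
  ChannelKin kin[2][NCH];
  for (int p = 0; p < 2; ++p)
    for (int c = 0; c < NCH; ++c) {
      ChannelKin &k = kin[p][c];
      double tr = tau_r(p, c), td = tau_d(p, c);
      k.fd_full = std::exp(-dt / td);      k.fr_full = std::exp(-dt / tr);
      k.fd_half = std::exp(-0.5 * dt / td); k.fr_half = std::exp(-0.5 * dt / tr);
      k.fd_sub  = std::exp(-sub / td);     k.fr_sub  = std::exp(-sub / tr);
      k.fd_subh = std::exp(-0.5 * sub / td); k.fr_subh = std::exp(-0.5 * sub / tr);
      k.erev = erev(p, c);
    }
  // soft-refractory offset decay factors
  const double f_vt1 = std::exp(-dt / tau_vt1), f_vt2 = std::exp(-dt / tau_vt2);
  const double f_dt = std::exp(-dt / tau_dt), f_itm = std::exp(-dt / tau_itm);
  const double fs_vt1 = std::exp(-sub / tau_vt1), fs_vt2 = std::exp(-sub / tau_vt2);
  const double fs_dt = std::exp(-sub / tau_dt), fs_itm = std::exp(-sub / tau_itm);

  // state
  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> Gd(n * NCH, 0.0), Gr(n * NCH, 0.0);
  std::vector<double> o_vt1(n, 0.0), o_vt2(n, 0.0), o_dt(n, 0.0), o_itm(n, 0.0);
  std::vector<int> refr_until(n, -1), spike_count(n, 0);

  // delivery ring buffers for recurrent channels 0..2
  int max_delay = 0;
  for (int e = 0; e < edge_delay.size(); ++e)
    if (edge_delay[e] > max_delay) max_delay = edge_delay[e];
  const int L = max_delay + 2;
  std::vector<double> buf(static_cast<size_t>(n) * 3 * L, 0.0);
  auto bidx = [&](int i, int ch, int slot) {
    return (static_cast<size_t>(i) * 3 + ch) * L + slot;
  };

  // recorders
  const int nv = v_idx.size();
  const int n_vsamp = (v_stride > 0 && nv > 0) ? n_rec / v_stride : 0;
  NumericMatrix v_rec(nv, n_vsamp);
  NumericVector v_times(n_vsamp);
  const int n_lfp = lfp_off.size() - 1;
  NumericMatrix lfp(n_lfp > 0 ? n_lfp : 0, n_lfp > 0 ? n_rec : 0);
  NumericVector bg_trace(n_rec);
  NumericVector acc_lgn(n), acc_rec(n), acc_bg(n), acc_gexc(n);
  std::vector<double> sp_id, sp_t;
  sp_id.reserve(1 << 16); sp_t.reserve(1 << 16);

  RNGScope rng;
  double Rbg = ou_mu;
  const double e_ou = std::exp(-dt / ou_tau);
  const double ou_noise = ou_sd * std::sqrt(1.0 - e_ou * e_ou);

  const double t0_rec = n_warm * dt;

  for (int step = 0; step < n_tot; ++step) {
    const int slot = step % L;
    const bool rec = step >= n_warm;
    const double t_step = step * dt;

    // 1. shared background rate (exact OU update)
    Rbg = ou_mu + (Rbg - ou_mu) * e_ou + ou_noise * norm_rand();
    const double bg_rate = Rbg > 0.0 ? Rbg : 0.0;
    const int cstate = contrast_state[step];

    // 2. external Poisson events + queued recurrent deliveries
    for (int i = 0; i < n; ++i) {
      const double lr = cstate ? lgn_rate_on[i] : lgn_rate_off[i];
      const double n_lgn = R::rpois(lr * dt_s);
      const double n_bg = R::rpois(bg_rate * dt_s);
      if (n_lgn > 0) {
        Gd[i * NCH + 3] += n_lgn * lgn_w[i];
        Gr[i * NCH + 3] += n_lgn * lgn_w[i];
      }
      if (n_bg > 0) {
        Gd[i * NCH + 4] += n_bg * bg_w[i];
        Gr[i * NCH + 4] += n_bg * bg_w[i];
      }
      if (has_comp) {
        const double n_c = R::rpois(comp_rate[i] * dt_s);
        if (n_c > 0) {
          Gd[i * NCH + 0] += n_c * comp_w[i];
          Gr[i * NCH + 0] += n_c * comp_w[i];
        }
      }
      for (int ch = 0; ch < 3; ++ch) {
        const size_t b = bidx(i, ch, slot);
        if (buf[b] != 0.0) {
          Gd[i * NCH + ch] += buf[b];
          Gr[i * NCH + ch] += buf[b];
          buf[b] = 0.0;
        }
      }
    }

    // 3. integrate each neuron over [t, t+dt]
    for (int i = 0; i < n; ++i) {
      const int p = is_exc[i] ? 0 : 1;
      const ChannelKin *K = kin[p];
      double *gd = &Gd[i * NCH], *gr = &Gr[i * NCH];

      if (!is_exc[i] && step < refr_until[i]) {
        V[i] = v_reset[i];
        continue;  // integration suspended (hard refractoriness)
      }

      const double el = e_leak[i], cm = cap[i];
      const double vt0 = v_thresh[i], dt0 = slope[i], itm0 = inv_tau_m[i];
      double ov1 = o_vt1[i], ov2 = o_vt2[i], od = o_dt[i], oi = o_itm[i];

      // conductance G_c and membrane rhs at intra-step offset, via the
      // supplied decay factors (fd, fr) relative to step-start states
      auto rhs = [&](double v, const double *fd, const double *fr,
                     double dv1, double dv2, double dd, double di) {
        double isyn = 0.0;
        for (int c = 0; c < NCH; ++c) {
          const double g = gd[c] * fd[c] - gr[c] * fr[c];
          isyn += g * (K[c].erev - v);
        }
        const double vt = vt0 + ov1 * dv1 + ov2 * dv2;
        const double dl = dt0 + od * dd;
        const double itm = itm0 + oi * di;
        return itm * (el - v + psi(v, vt, dl)) + isyn / cm;
      };

      double fd0[NCH], fr0[NCH], fdh[NCH], frh[NCH], fdf[NCH], frf[NCH];
      for (int c = 0; c < NCH; ++c) {
        fd0[c] = 1.0; fr0[c] = 1.0;
        fdh[c] = K[c].fd_half; frh[c] = K[c].fr_half;
        fdf[c] = K[c].fd_full; frf[c] = K[c].fr_full;
      }
      const double fvt1h = std::sqrt(f_vt1), fvt2h = std::sqrt(f_vt2);
      const double fdth = std::sqrt(f_dt), fitmh = std::sqrt(f_itm);

      double v0 = V[i];
      // plain full-step RK4
      double k1 = rhs(v0, fd0, fr0, 1.0, 1.0, 1.0, 1.0);
      double k2 = rhs(v0 + 0.5 * dt * k1, fdh, frh, fvt1h, fvt2h, fdth, fitmh);
      double k3 = rhs(v0 + 0.5 * dt * k2, fdh, frh, fvt1h, fvt2h, fdth, fitmh);
      double k4 = rhs(v0 + dt * k3, fdf, frf, f_vt1, f_vt2, f_dt, f_itm);
      double v1 = v0 + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);

      bool spiked = false;
      bool in_refr = false;
      const double vt_end = vt0 + ov1 * f_vt1 + ov2 * f_vt2;

      if (v1 >= vt_end || v0 >= vt0 + ov1 + ov2 || !std::isfinite(v1)) {
        // spike-initiation zone: redo the step with sub-steps, decaying the
        // channel states and parameter offsets locally.  After a reset the
        // remainder of the step is still integrated (excitatory cells), so
        // spike timing carries no step-size bias.
        double gdl[NCH], grl[NCH];
        for (int c = 0; c < NCH; ++c) { gdl[c] = gd[c]; grl[c] = gr[c]; }
        double v = v0;
        double lv1 = ov1, lv2 = ov2, ld = od, li = oi;
        const double fsv1h = std::sqrt(fs_vt1), fsv2h = std::sqrt(fs_vt2);
        const double fsdh = std::sqrt(fs_dt), fsih = std::sqrt(fs_itm);
        for (int s = 0; s < n_sub; ++s) {
          // rhs against local (already decayed) states: factors at offsets
          // 0, sub/2, sub within the sub-step
          double sd0[NCH], sr0[NCH], sdh[NCH], srh[NCH], sdf[NCH], srf[NCH];
          for (int c = 0; c < NCH; ++c) {
            sd0[c] = 1.0; sr0[c] = 1.0;
            sdh[c] = K[c].fd_subh; srh[c] = K[c].fr_subh;
            sdf[c] = K[c].fd_sub; srf[c] = K[c].fr_sub;
          }
          double *gds = gd, *grs = gr;
          gd = gdl; gr = grl;
          double sov1 = ov1, sov2 = ov2, sod = od, soi = oi;
          ov1 = lv1; ov2 = lv2; od = ld; oi = li;
          double q1 = rhs(v, sd0, sr0, 1.0, 1.0, 1.0, 1.0);
          double q2 = rhs(v + 0.5 * sub * q1, sdh, srh, fsv1h, fsv2h, fsdh, fsih);
          double q3 = rhs(v + 0.5 * sub * q2, sdh, srh, fsv1h, fsv2h, fsdh, fsih);
          double q4 = rhs(v + sub * q3, sdf, srf, fs_vt1, fs_vt2, fs_dt, fs_itm);
          double vn = v + sub / 6.0 * (q1 + 2.0 * q2 + 2.0 * q3 + q4);
          ov1 = sov1; ov2 = sov2; od = sod; oi = soi;
          gd = gds; gr = grs;
          // advance local states to end of sub-step
          for (int c = 0; c < NCH; ++c) {
            gdl[c] *= K[c].fd_sub; grl[c] *= K[c].fr_sub;
          }
          lv1 *= fs_vt1; lv2 *= fs_vt2; ld *= fs_dt; li *= fs_itm;
          const double vt_s = vt0 + lv1 + lv2;
          const double dl_s = dt0 + ld;
          const double itm_s = itm0 + li;
          // the divergence-dominance cutoff follows the effective
          // parameters so the extrapolation stays valid during the
          // post-spike relaxation
          const double cut_i = std::max(v_cut[i], vt_s + 10.0 * dl_s);
          if (!std::isfinite(vn)) vn = cut_i + 20.0 * dl_s;
          if (vn >= cut_i) {
            // analytic extrapolation of the divergence time
            double x = (vn - vt_s) / dl_s;
            if (x > 60.0) x = 60.0;
            const double t_spike = t_step + (s + 1) * sub +
              std::exp(-x) / itm_s;
            spiked = true;
            spike_count[i] += 1;
            sp_id.push_back(i + 1);
            sp_t.push_back(t_spike - t0_rec);
            const bool suppress = (i == perturb_neuron) &&
              (spike_count[i] == perturb_k);
            if (!suppress) {
              for (int e = edge_off[i]; e < edge_off[i + 1]; ++e) {
                const int j = edge_tgt[e];
                const int dslot = (step + edge_delay[e] + 1) % L;
                buf[bidx(j, edge_ch[e], dslot)] += edge_wf[e];
                if (edge_wn[e] != 0.0)
                  buf[bidx(j, 1, dslot)] += edge_wn[e];
              }
            }
            vn = v_reset[i];
            if (is_exc[i]) {
              // offsets accumulate: the jump adds to the decayed remainder,
              // so repeated firing builds up adaptation
              lv1 += a_vt1; lv2 += a_vt2; ld += a_dt; li += a_itm;
            } else {
              refr_until[i] = step + 1 + refr_steps;
              in_refr = true;
            }
          }
          v = vn;
          if (in_refr) break;  // hard refractoriness suspends integration
        }
        v1 = v;
        V[i] = v1;
        if (is_exc[i]) {
          o_vt1[i] = lv1; o_vt2[i] = lv2; o_dt[i] = ld; o_itm[i] = li;
        }
      } else {
        V[i] = v1;
        if (is_exc[i]) {
          o_vt1[i] *= f_vt1; o_vt2[i] *= f_vt2;
          o_dt[i] *= f_dt; o_itm[i] *= f_itm;
        }
      }
      (void)spiked;
    }

    // 4. decay channel states to the end of the step
    for (int i = 0; i < n; ++i) {
      const ChannelKin *K = kin[is_exc[i] ? 0 : 1];
      double *gd = &Gd[i * NCH], *gr = &Gr[i * NCH];
      for (int c = 0; c < NCH; ++c) {
        gd[c] *= K[c].fd_full;
        gr[c] *= K[c].fr_full;
      }
    }

    // 5. recorders (end-of-step values)
    if (rec) {
      const int rstep = step - n_warm;
      bg_trace[rstep] = Rbg;
      for (int i = 0; i < n; ++i) {
        const ChannelKin *K = kin[is_exc[i] ? 0 : 1];
        const double *gd = &Gd[i * NCH], *gr = &Gr[i * NCH];
        const double v = V[i];
        double g[NCH];
        for (int c = 0; c < NCH; ++c) g[c] = gd[c] - gr[c];
        acc_lgn[i] += std::fabs(g[3] * (K[3].erev - v));
        acc_rec[i] += std::fabs(g[0] * (K[0].erev - v)) +
                      std::fabs(g[1] * (K[1].erev - v)) +
                      std::fabs(g[2] * (K[2].erev - v));
        acc_bg[i] += std::fabs(g[4] * (K[4].erev - v));
        acc_gexc[i] += g[0] + g[1];
      }
      if (n_lfp > 0) {
        for (int ch = 0; ch < n_lfp; ++ch) {
          double s = 0.0;
          int m = 0;
          for (int q = lfp_off[ch]; q < lfp_off[ch + 1]; ++q) {
            const int i = lfp_idx[q];
            const ChannelKin *K = kin[is_exc[i] ? 0 : 1];
            const double *gd = &Gd[i * NCH], *gr = &Gr[i * NCH];
            double isyn = 0.0;
            for (int c = 0; c < NCH; ++c)
              isyn += (gd[c] - gr[c]) * (K[c].erev - V[i]);
            s += isyn;
            ++m;
          }
          lfp(ch, rstep) = m > 0 ? s / m : NA_REAL;
        }
      }
      if (n_vsamp > 0 && (rstep + 1) % v_stride == 0) {
        const int col = (rstep + 1) / v_stride - 1;
        if (col < n_vsamp) {
          for (int q = 0; q < nv; ++q) v_rec(q, col) = V[v_idx[q]];
          v_times[col] = (rstep + 1) * dt;
        }
      }
    }
  }

  return List::create(
    _["spike_id"] = NumericVector(sp_id.begin(), sp_id.end()),
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["n_spikes"] = IntegerVector(spike_count.begin(), spike_count.end()),
    _["v"] = v_rec, _["v_times"] = v_times,
    _["lfp"] = lfp, _["bg_rate"] = bg_trace,
    _["acc_lgn"] = acc_lgn, _["acc_rec"] = acc_rec, _["acc_bg"] = acc_bg,
    _["acc_gexc"] = acc_gexc, _["n_rec_steps"] = n_rec,
    _["v_final"] = NumericVector(V.begin(), V.end()));
}
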