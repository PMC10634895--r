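#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Reduced laminar column integrator.
//
// Populations: 0 = L2/3 pyramidal, 1 = L5 pyramidal, 2 = L2/3 basket, 3 = L5 basket.
// Pyramidal cells have four collinear compartments along the apical axis
// (0 basal-proximal, 1 soma, 2 apical-trunk, 3 apical-tuft); baskets are points.
// Synaptic conductances are population-shared double-exponential states (all-to-all
// uniform weights), per (population, compartment, receptor). Receptors:
// 0 AMPA, 1 NMDA (sigmoidal Mg block), 2 GABAa, 3 GABAb.
// Dipole convention: upward axial current (lower -> upper compartment) is positive.

static const int N_POP = 4;
static const int N_COMP = 4;
static const int N_REC = 4;

static inline int chan_index(int pop, int comp, int rec) {
  return pop * N_COMP * N_REC + comp * N_REC + rec;
}

static inline double mg_block(double v) {
  // sigmoidal NMDA voltage dependence (Jahr-Stevens form)
  return 1.0 / (1.0 + 0.28 * std::exp(-0.062 * v));
}

// [[Rcpp::export(name = ".simulate_trial_cpp")]]
List simulate_trial_cpp(List net, List events, NumericVector init_v, double dt,
                        double t_start, int n_steps) {
  // network scalars
  const int n_l2 = as<int>(net["n_l2pyr"]);
  const int n_l5 = as<int>(net["n_l5pyr"]);
  const int n_b2 = as<int>(net["n_l2basket"]);
  const int n_b5 = as<int>(net["n_l5basket"]);
  const int n_pyr[2] = { n_l2, n_l5 };
  const int n_bas[2] = { n_b2, n_b5 };

  const double EL = as<double>(net["e_leak"]);
  const double gL = as<double>(net["g_leak"]);
  const double Cm = as<double>(net["capacitance"]);
  const double v_thr = as<double>(net["spike_threshold"]);
  const double v_reset = as<double>(net["spike_reset"]);
  const double refrac_pyr = as<double>(net["refractory_pyr"]);
  const double refrac_bas = as<double>(net["refractory_basket"]);
  const double bas_thr = as<double>(net["basket_threshold"]);

  // geometry: per layer, axial conductance and signed length of the 3 adjacent pairs
  NumericMatrix g_ax = as<NumericMatrix>(net["axial_g"]);     // 2 x 3
  NumericMatrix seg_len = as<NumericMatrix>(net["seg_len"]);  // 2 x 3

  // backprop pulse (per compartment: soma, trunk, tuft), shared kinetics per comp
  NumericVector bp_amp = as<NumericVector>(net["bp_amp"]);     // length 3
  NumericVector bp_taur = as<NumericVector>(net["bp_tau_rise"]);
  NumericVector bp_taud = as<NumericVector>(net["bp_tau_decay"]);

  // L5 tuft regenerative (calcium-like) current
  const double ca_thr = as<double>(net["ca_threshold"]);
  const double ca_amp = as<double>(net["ca_amp"]);
  const double ca_taur = as<double>(net["ca_tau_rise"]);
  const double ca_taud = as<double>(net["ca_tau_decay"]);
  const double ca_refrac = as<double>(net["ca_refractory"]);

  // receptor kinetics
  NumericVector rec_taur = as<NumericVector>(net["rec_tau_rise"]);   // length 4
  NumericVector rec_taud = as<NumericVector>(net["rec_tau_decay"]);
  NumericVector rec_erev = as<NumericVector>(net["rec_erev"]);

  // local connections: src_pop, chan (0-based), weight, delay_ms
  IntegerVector con_src = as<IntegerVector>(net["con_src"]);
  IntegerVector con_chan = as<IntegerVector>(net["con_chan"]);
  NumericVector con_w = as<NumericVector>(net["con_w"]);
  NumericVector con_delay = as<NumericVector>(net["con_delay"]);
  const int n_con = con_src.size();

  // exogenous events: step index (0-based), chan, weight (already includes any delay)
  IntegerVector ev_step = as<IntegerVector>(events["step"]);
  IntegerVector ev_chan = as<IntegerVector>(events["chan"]);
  NumericVector ev_w = as<NumericVector>(events["w"]);

  const int n_chan = N_POP * N_COMP * N_REC;

  // precomputed decays and normalization per receptor
  std::vector<double> dec_r(N_REC), dec_d(N_REC), norm(N_REC);
  for (int r = 0; r < N_REC; ++r) {
    dec_r[r] = std::exp(-dt / rec_taur[r]);
    dec_d[r] = std::exp(-dt / rec_taud[r]);
    double tp = rec_taur[r] * rec_taud[r] / (rec_taud[r] - rec_taur[r]) *
      std::log(rec_taud[r] / rec_taur[r]);
    norm[r] = 1.0 / (std::exp(-tp / rec_taud[r]) - std::exp(-tp / rec_taur[r]));
  }
  std::vector<double> bp_dec_r(3), bp_dec_d(3), bp_norm(3);
  for (int c = 0; c < 3; ++c) {
    bp_dec_r[c] = std::exp(-dt / bp_taur[c]);
    bp_dec_d[c] = std::exp(-dt / bp_taud[c]);
    double tp = bp_taur[c] * bp_taud[c] / (bp_taud[c] - bp_taur[c]) *
      std::log(bp_taud[c] / bp_taur[c]);
    bp_norm[c] = 1.0 / (std::exp(-tp / bp_taud[c]) - std::exp(-tp / bp_taur[c]));
  }
  const double ca_dec_r = std::exp(-dt / ca_taur);
  const double ca_dec_d = std::exp(-dt / ca_taud);
  double ca_tp = ca_taur * ca_taud / (ca_taud - ca_taur) * std::log(ca_taud / ca_taur);
  const double ca_norm = 1.0 / (std::exp(-ca_tp / ca_taud) - std::exp(-ca_tp / ca_taur));

  // pending synaptic increments, ring-free: full schedule matrix [n_steps][n_chan]
  std::vector<double> sched((size_t)n_steps * n_chan, 0.0);
  for (int i = 0; i < ev_step.size(); ++i) {
    int s = ev_step[i];
    if (s >= 0 && s < n_steps) sched[(size_t)s * n_chan + ev_chan[i]] += ev_w[i];
  }

  // state: channel A/B
  std::vector<double> A(n_chan, 0.0), B(n_chan, 0.0);

  // pyramidal state
  std::vector<std::vector<double> > Vp(2);
  Vp[0].resize((size_t)n_l2 * N_COMP);
  Vp[1].resize((size_t)n_l5 * N_COMP);
  // basket state
  std::vector<std::vector<double> > Vb(2);
  Vb[0].resize(n_b2);
  Vb[1].resize(n_b5);

  int k = 0;
  for (int L = 0; L < 2; ++L)
    for (int i = 0; i < n_pyr[L] * N_COMP; ++i) Vp[L][i] = init_v[k++];
  for (int L = 0; L < 2; ++L)
    for (int i = 0; i < n_bas[L]; ++i) Vb[L][i] = init_v[k++];

  // per-cell backprop pulse states (soma/trunk/tuft) and ca state (L5)
  std::vector<std::vector<double> > bpA(2), bpB(2);
  for (int L = 0; L < 2; ++L) { bpA[L].assign((size_t)n_pyr[L] * 3, 0.0);
                                bpB[L].assign((size_t)n_pyr[L] * 3, 0.0); }
  std::vector<double> caA(n_l5, 0.0), caB(n_l5, 0.0);
  std::vector<double> ca_next(n_l5, -1e30);
  std::vector<std::vector<double> > next_spike(4);
  next_spike[0].assign(n_l2, -1e30); next_spike[1].assign(n_l5, -1e30);
  next_spike[2].assign(n_b2, -1e30); next_spike[3].assign(n_b5, -1e30);

  // outputs
  NumericVector time_ms(n_steps), dip_l2(n_steps), dip_l5(n_steps);
  NumericMatrix comp_mean(n_steps, 8); // L2 comps 0..3, L5 comps 0..3
  std::vector<int> sp_pop, sp_cell; std::vector<double> sp_t;

  bool diverged = false; double div_t = 0; int div_pop = 0, div_cell = 0;

  std::vector<double> newV; // scratch
  for (int s = 0; s < n_steps; ++s) {
    double t = t_start + (s + 1) * dt;

    // apply scheduled increments, decay channels
    const double* inc = &sched[(size_t)s * n_chan];
    for (int c = 0; c < n_chan; ++c) {
      int r = c % N_REC;
      A[c] = A[c] * dec_r[r] + inc[c];
      B[c] = B[c] * dec_d[r] + inc[c];
    }

    int spike_count[4] = {0, 0, 0, 0};

    // pyramidal populations
    for (int L = 0; L < 2; ++L) {
      int n = n_pyr[L];
      int pop = L; // 0, 1
      // shared channel conductances for this pop, per comp per receptor
      double g[N_COMP][N_REC];
      for (int cmp = 0; cmp < N_COMP; ++cmp)
        for (int r = 0; r < N_REC; ++r) {
          int c = chan_index(pop, cmp, r);
          g[cmp][r] = (B[c] - A[c]) * norm[r];
          if (g[cmp][r] < 0) g[cmp][r] = 0;
        }
      newV.assign((size_t)n * N_COMP, 0.0);
      double csum[N_COMP] = {0, 0, 0, 0};
      for (int i = 0; i < n; ++i) {
        double* V = &Vp[L][(size_t)i * N_COMP];
        for (int cmp = 0; cmp < N_COMP; ++cmp) {
          double v = V[cmp];
          double Gtot = gL, Isum = gL * EL;
          for (int r = 0; r < N_REC; ++r) {
            double grc = g[cmp][r];
            if (grc <= 0) continue;
            if (r == 1) grc *= mg_block(v);
            Gtot += grc; Isum += grc * rec_erev[r];
          }
          // axial coupling to neighbors (pairs: (0,1),(1,2),(2,3))
          if (cmp > 0)  { double ga = g_ax(L, cmp - 1); Gtot += ga; Isum += ga * V[cmp - 1]; }
          if (cmp < 3)  { double ga = g_ax(L, cmp);     Gtot += ga; Isum += ga * V[cmp + 1]; }
          // injected currents: backprop (comps 1..3), ca (L5 tuft)
          double Iinj = 0.0;
          if (cmp >= 1) {
            int b = cmp - 1;
            Iinj += bp_amp[b] * (bpB[L][(size_t)i * 3 + b] - bpA[L][(size_t)i * 3 + b]) * bp_norm[b];
          }
          if (L == 1 && cmp == 3)
            Iinj += ca_amp * (caB[i] - caA[i]) * ca_norm;
          double Vinf = (Isum + Iinj) / Gtot;
          double vnew = Vinf + (v - Vinf) * std::exp(-Gtot * dt / Cm);
          newV[(size_t)i * N_COMP + cmp] = vnew;
        }
      }
      // commit, detect spikes / ca, decay per-cell pulses
      for (int i = 0; i < n; ++i) {
        double* V = &Vp[L][(size_t)i * N_COMP];
        for (int cmp = 0; cmp < N_COMP; ++cmp) V[cmp] = newV[(size_t)i * N_COMP + cmp];
        for (int b = 0; b < 3; ++b) {
          bpA[L][(size_t)i * 3 + b] *= bp_dec_r[b];
          bpB[L][(size_t)i * 3 + b] *= bp_dec_d[b];
        }
        if (L == 1) { caA[i] *= ca_dec_r; caB[i] *= ca_dec_d; }
        if (V[1] >= v_thr && t >= next_spike[pop][i]) {
          V[1] = v_reset;
          next_spike[pop][i] = t + refrac_pyr;
          ++spike_count[pop];
          sp_pop.push_back(pop); sp_cell.push_back(i); sp_t.push_back(t);
          for (int b = 0; b < 3; ++b) {
            bpA[L][(size_t)i * 3 + b] += 1.0; bpB[L][(size_t)i * 3 + b] += 1.0;
          }
        }
        if (L == 1 && V[3] >= ca_thr && t >= ca_next[i]) {
          caA[i] += 1.0; caB[i] += 1.0;
          ca_next[i] = t + ca_refrac;
        }
        if (!(std::fabs(V[1]) <= 500.0) || !(std::fabs(V[3]) <= 500.0)) {
          diverged = true; div_t = t; div_pop = pop; div_cell = i;
        }
        for (int cmp = 0; cmp < N_COMP; ++cmp) csum[cmp] += V[cmp];
      }
      // dipole and compartment means
      double dip = 0.0;
      for (int p = 0; p < 3; ++p)
        dip += g_ax(L, p) * seg_len(L, p) * (csum[p] - csum[p + 1]);
      if (L == 0) dip_l2[s] = dip; else dip_l5[s] = dip;
      for (int cmp = 0; cmp < N_COMP; ++cmp)
        comp_mean(s, L * N_COMP + cmp) = csum[cmp] / n;
    }

    // basket populations
    for (int L = 0; L < 2; ++L) {
      int pop = 2 + L;
      int n = n_bas[L];
      double g[N_REC];
      for (int r = 0; r < N_REC; ++r) {
        int c = chan_index(pop, 0, r);
        g[r] = (B[c] - A[c]) * norm[r];
        if (g[r] < 0) g[r] = 0;
      }
      for (int i = 0; i < n; ++i) {
        double v = Vb[L][i];
        double Gtot = gL, Isum = gL * EL;
        for (int r = 0; r < N_REC; ++r) {
          double grc = g[r];
          if (grc <= 0) continue;
          if (r == 1) grc *= mg_block(v);
          Gtot += grc; Isum += grc * rec_erev[r];
        }
        double Vinf = Isum / Gtot;
        double vnew = Vinf + (v - Vinf) * std::exp(-Gtot * dt / Cm);
        if (vnew >= bas_thr && t >= next_spike[pop][i]) {
          vnew = v_reset;
          next_spike[pop][i] = t + refrac_bas;
          ++spike_count[pop];
          sp_pop.push_back(pop); sp_cell.push_back(i); sp_t.push_back(t);
        }
        if (!(std::fabs(vnew) <= 500.0)) { diverged = true; div_t = t; div_pop = pop; div_cell = i; }
        Vb[L][i] = vnew;
      }
    }

    // route this step's spikes through local connections
    for (int cn = 0; cn < n_con; ++cn) {
      int sp = con_src[cn];
      if (spike_count[sp] == 0) continue;
      int ds = s + 1 + (int)std::floor(con_delay[cn] / dt + 0.5);
      if (ds < n_steps)
        sched[(size_t)ds * n_chan + con_chan[cn]] += con_w[cn] * spike_count[sp];
    }

    time_ms[s] = t;
    if (diverged) break;
  }

  if (diverged) {
    stop("membrane potential diverged at t = %.2f ms (population %d, cell %d)",
         div_t, div_pop, div_cell);
  }

  return List::create(
    _["time_ms"] = time_ms,
    _["dip_l2"] = dip_l2,
    _["dip_l5"] = dip_l5,
    _["comp_mean"] = comp_mean,
    _["spike_pop"] = IntegerVector(sp_pop.begin(), sp_pop.end()),
    _["spike_cell"] = IntegerVector(sp_cell.begin(), sp_cell.end()),
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()));
}
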