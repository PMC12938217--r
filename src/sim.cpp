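// Synchronous Euler stepper for the six-area spiking network.
//
// One call advances the network state (held in the R environment `net`,
// mutated in place) by up to `max_steps` steps under one of four stop
// modes: fixed step count, n completed ignition episodes, n ignition
// onsets, or return-to-baseline (inter-stimulus interval). All inputs at
// step t use outputs from step t-1; plasticity uses the step-t values of
// the presynaptic slow rate estimate and the postsynaptic membrane
// potential, gated on a pre- or postsynaptic spike at t. Noise is drawn
// from R's RNG, one uniform per excitatory cell per step in cell order, so
// that the pure-R reference stepper consumes an identical stream.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int N_AREAS = 6;

// [[Rcpp::export]]
List sim_run_cpp(Environment net, List ctl) {
  List par = net["par"];
  const double dt       = par["dt"];
  const double tau_e    = par["tau_exc"];
  const double tau_i    = par["tau_inh"];
  const double tau_S    = par["tau_S"];
  const double tau_A    = par["tau_A"];
  const double tau_F    = par["tau_Favg"];
  const double k1       = par["k1"];
  const double k2e      = par["k2_exc"];
  const double k2i      = par["k2_inh"];
  const double Vb       = par["Vb"];
  const double k_ffb    = par["k_ffb"];
  const double k_rec    = par["k_rec"];
  const double k_inh    = par["k_inh"];
  const double k_G      = par["k_G"];
  const double thresh   = par["thresh"];
  const double alpha    = par["alpha"];
  const double th_pre   = par["theta_pre"];
  const double th_minus = par["theta_minus"];
  const double thp_min  = par["theta_plus_min"];
  const double thp_max  = par["theta_plus_max"];
  const double w_cap    = par["w_cap"];
  const double act_floor = par["activity_floor"];
  const double ign_thr   = par["ignition_threshold"];
  const double base_tol  = par["baseline_tol"];
  const bool through_k1  = par["drive_through_k1"];
  const bool noise_k1    = par["noise_through_k1"];
  // the noise term shares the input scaling of every other drive source
  const double k2e_eff = noise_k1 ? k1 * k2e : k2e;
  const double k2i_eff = noise_k1 ? k1 * k2i : k2i;

  List conn = net["conn"];
  List ee = conn["ee"];
  IntegerVector ee_post = ee["post"], ee_rowptr = ee["row_ptr"];
  IntegerVector ee_csc = ee["csc_order"], ee_csc_pre = ee["csc_pre"], ee_colptr = ee["col_ptr"];
  NumericVector ee_w = ee["w"];
  LogicalVector ee_between = ee["between"];
  List ie = conn["ie"];
  IntegerVector ie_post = ie["post"], ie_rowptr = ie["row_ptr"];
  NumericVector ie_w = ie["w"];
  const double w_ei = par["w_ei"];

  NumericVector V_e = net["V_e"], V_i = net["V_i"];
  NumericVector phi_i = net["phi_i"], omega = net["omega"], omega_E = net["omega_E"];
  NumericVector omega_G = net["omega_G"];
  IntegerVector phi_e = net["phi_e"];
  const int n_exc = V_e.size();
  const int cells_per_area = n_exc / N_AREAS;

  // control
  const int  mode        = as<int>(ctl["mode"]);       // 0 fixed, 1 episodes, 2 ignitions, 3 isi
  const int  max_steps   = as<int>(ctl["max_steps"]);
  const int  n_target    = as<int>(ctl["n_target"]);
  const bool learn       = as<bool>(ctl["learn"]);
  const double dw_base   = as<double>(ctl["dw_base"]);
  const double dw_multi  = as<double>(ctl["dw_multi"]);
  IntegerVector stim     = ctl["stim"];                // global exc indices, 1-based
  const double stim_amp  = as<double>(ctl["stim_amp"]);
  List ca_members        = ctl["ca_members"];          // list of 1-based index vectors
  IntegerVector rewarded = ctl["rewarded"];            // 1-based CA ids gating reward
  const bool rec_act     = as<bool>(ctl["record_activity"]);
  const bool rec_reward  = as<bool>(ctl["record_reward"]);
  const bool rec_spikes  = as<bool>(ctl["record_spikes"]);
  const bool rec_peak    = as<bool>(ctl["record_peak_omega_e"]);
  const int quiet_steps  = as<int>(ctl["quiet_steps"]);

  const int n_ca = ca_members.size();
  std::vector< std::vector<int> > members(n_ca);
  for (int c = 0; c < n_ca; ++c) {
    IntegerVector m = ca_members[c];
    members[c].assign(m.begin(), m.end());
  }
  std::vector<bool> is_rewarded(n_ca, false);
  for (int k = 0; k < rewarded.size(); ++k) is_rewarded[rewarded[k] - 1] = true;
  const bool reward_on = rewarded.size() > 0;

  std::vector<double> drive(n_exc, 0.0);
  for (int k = 0; k < stim.size(); ++k) drive[stim[k] - 1] = stim_amp;
  const bool has_stim = stim.size() > 0;

  std::vector<double> Vin_e(n_exc), Vin_i(n_exc);
  std::vector<int> spk;  spk.reserve(n_exc);
  std::vector<double> peak_omE(rec_peak ? n_exc : 0, 0.0);
  // per-cell plasticity codes: pre code = (spiked << 1) | (omega_E >= theta_pre),
  // post code = (spiked << 2) | membrane class (0 below theta-, 1 mid, 2 at/above theta+)
  std::vector<unsigned char> pc(n_exc), qc(n_exc);
  signed char dtab[4 * 8];

  // CA ignition bookkeeping
  std::vector<bool> above(n_ca, false);
  std::vector<int> ev_open_start(n_ca, -1);
  std::vector<int> ev_ca, ev_start, ev_end;
  std::vector<double> act_log;
  std::vector<int> reward_log, spike_log;
  bool in_episode = false;
  int episodes_done = 0, ignition_count = 0;
  int quiet_run = 0;
  long ltp_r0 = 0, ltp_r1 = 0, ltd_r0 = 0, ltd_r1 = 0;
  double reward_steps = 0.0;

  // previous-step spike list
  spk.clear();
  for (int i = 0; i < n_exc; ++i) if (phi_e[i]) spk.push_back(i);

  int steps = 0;
  bool reached = (mode == 0);
  double R = 0.0;
  std::vector<int> area_spikes(N_AREAS, 0);

  for (int t = 0; t < max_steps; ++t) {
    // --- net input from step t-1 outputs ---
    for (int i = 0; i < n_exc; ++i) { Vin_e[i] = Vb; }
    {
      const int* postp = INTEGER(ee_post);
      const int* rowp = INTEGER(ee_rowptr);
      const int* betp = LOGICAL(ee_between);
      const double* wp = REAL(ee_w);
      for (size_t s = 0; s < spk.size(); ++s) {
        const int x = spk[s];
        for (int k = rowp[x]; k < rowp[x + 1]; ++k) {
          const double g = betp[k] ? k_ffb : k_rec;
          Vin_e[postp[k] - 1] += g * wp[k];
        }
      }
    }
    // local inhibitory surround: graded outputs of the 5 x 5 neighbourhood
    {
      const int* postp = INTEGER(ie_post);
      const int* rowp = INTEGER(ie_rowptr);
      const double* wp = REAL(ie_w);
      for (int j = 0; j < n_exc; ++j) {
        const double pj = phi_i[j];
        if (pj == 0.0) continue;
        for (int k = rowp[j]; k < rowp[j + 1]; ++k)
          Vin_e[postp[k] - 1] -= k_inh * wp[k] * pj;
      }
    }
    for (int i = 0; i < n_exc; ++i) {
      const int a = i / cells_per_area;
      Vin_e[i] -= k_G * omega_G[a];
      if (has_stim && through_k1) Vin_e[i] += drive[i];
      // column pairing: each inhibitory cell is driven by its own
      // excitatory twin's output
      Vin_i[i] = k_rec * w_ei * phi_e[i];
    }

    // --- membrane updates (one uniform per excitatory cell, cell order) ---
    for (int i = 0; i < n_exc; ++i) {
      const double eta = unif_rand() - 0.5;
      double ext = (has_stim && !through_k1) ? drive[i] : 0.0;
      V_e[i] += (dt / tau_e) * (-V_e[i] + k1 * Vin_e[i] + k2e_eff * eta + ext);
    }
    if (k2i != 0.0) {
      for (int i = 0; i < n_exc; ++i) {
        const double eta = unif_rand() - 0.5;
        V_i[i] += (dt / tau_i) * (-V_i[i] + k1 * Vin_i[i] + k2i_eff * eta);
      }
    } else {
      for (int i = 0; i < n_exc; ++i)
        V_i[i] += (dt / tau_i) * (-V_i[i] + k1 * Vin_i[i]);
    }

    // --- outputs ---
    spk.clear();
    for (int a = 0; a < N_AREAS; ++a) area_spikes[a] = 0;
    for (int i = 0; i < n_exc; ++i) {
      const int f = (V_e[i] - alpha * omega[i] > thresh) ? 1 : 0;
      phi_e[i] = f;
      if (f) { spk.push_back(i); ++area_spikes[i / cells_per_area]; }
      phi_i[i] = (V_i[i] < 0.0) ? 0.0 : V_i[i];
    }

    // --- rate estimates and global inhibition ---
    for (int i = 0; i < n_exc; ++i) {
      omega[i]   += (dt / tau_A) * (-omega[i]   + phi_e[i]);
      omega_E[i] += (dt / tau_F) * (-omega_E[i] + phi_e[i]);
      if (rec_peak && omega_E[i] > peak_omE[i]) peak_omE[i] = omega_E[i];
    }
    for (int a = 0; a < N_AREAS; ++a)
      omega_G[a] += (dt / tau_S) * (-omega_G[a] + area_spikes[a]);

    // --- CA activity, ignition events, reward gate ---
    bool any_above = false, any_rewarded_above = false;
    for (int c = 0; c < n_ca; ++c) {
      int n_act = 0;
      const std::vector<int>& m = members[c];
      for (size_t k = 0; k < m.size(); ++k)
        if (omega[m[k] - 1] > act_floor) ++n_act;
      const double act = m.empty() ? 0.0 : (double)n_act / (double)m.size();
      if (rec_act) act_log.push_back(act);
      const bool ab = act >= ign_thr;
      if (ab && !above[c]) { ev_open_start[c] = t; ++ignition_count; }
      if (!ab && above[c]) {
        ev_ca.push_back(c + 1); ev_start.push_back(ev_open_start[c]); ev_end.push_back(t);
        ev_open_start[c] = -1;
      }
      above[c] = ab;
      if (ab) { any_above = true; if (is_rewarded[c]) any_rewarded_above = true; }
    }
    if (any_above && !in_episode) in_episode = true;
    if (!any_above && in_episode) { in_episode = false; ++episodes_done; }
    R = (reward_on && any_rewarded_above) ? 1.0 : 0.0;
    if (R == 1.0) reward_steps += 1.0;
    if (rec_reward) reward_log.push_back((int)R);
    if (rec_spikes) for (int a = 0; a < N_AREAS; ++a) spike_log.push_back(area_spikes[a]);

    // --- plasticity: one sequential sweep over all synapses ---
    // The ABS branch for a synapse depends only on small per-cell codes
    // (presynaptic slow-rate gate + spike, postsynaptic membrane class +
    // spike), so the rule reduces to a 4 x 8 lookup table rebuilt each
    // step (the LTP threshold moves with the reward signal). The sweep
    // touches the weight array only where a change applies, keeping the
    // cost independent of how synchronized the firing is.
    if (learn && dw_base > 0.0) {
      const double dw = dw_base * (1.0 + dw_multi * R);
      const double th_plus = thp_max - (thp_max - thp_min) * R;
      for (int i = 0; i < n_exc; ++i) {
        pc[i] = (unsigned char)((phi_e[i] << 1) | (omega_E[i] >= th_pre ? 1 : 0));
        const int v = (V_e[i] >= th_plus) ? 2 : (V_e[i] >= th_minus ? 1 : 0);
        qc[i] = (unsigned char)((phi_e[i] << 2) | v);
      }
      for (int p = 0; p < 4; ++p) for (int q = 0; q < 8; ++q) {
        const int pre_on = p & 1, pre_spk = p >> 1;
        const int v = q & 3, post_spk = q >> 2;
        int del = 0;
        if (pre_spk || post_spk) {
          if (pre_on) del = (v == 2) ? 1 : ((v == 1) ? -1 : 0);
          else        del = (v == 2) ? -1 : 0;
        }
        dtab[p * 8 + q] = (signed char)del;
      }
      long nltp = 0, nltd = 0;
      const int* postp = INTEGER(ee_post);
      const int* rowp = INTEGER(ee_rowptr);
      const int* colp = INTEGER(ee_colptr);
      const int* cscp = INTEGER(ee_csc);
      const int* cscpre = INTEGER(ee_csc_pre);
      double* wp = REAL(ee_w);
      // eligible synapses are exactly the rows of spiking presynaptic
      // cells plus the columns of spiking postsynaptic cells
      for (size_t s = 0; s < spk.size(); ++s) {
        const int y = spk[s];
        const int qy = qc[y];
        for (int k = colp[y]; k < colp[y + 1]; ++k) {
          const int d = dtab[pc[cscpre[k] - 1] * 8 + qy];
          if (d == 0) continue;
          const int j = cscp[k] - 1;
          double w = wp[j] + d * dw;
          w = (w < 0.0) ? 0.0 : ((w > w_cap) ? w_cap : w);
          wp[j] = w;
          if (d > 0) ++nltp; else ++nltd;
        }
      }
      for (size_t s = 0; s < spk.size(); ++s) {
        const int x = spk[s];
        const signed char* drow = dtab + pc[x] * 8;
        for (int k = rowp[x]; k < rowp[x + 1]; ++k) {
          const int yq = qc[postp[k] - 1];
          if (yq >= 4) continue;  // spiking post: handled in the column pass
          const int d = drow[yq];
          if (d == 0) continue;
          double w = wp[k] + d * dw;
          w = (w < 0.0) ? 0.0 : ((w > w_cap) ? w_cap : w);
          wp[k] = w;
          if (d > 0) ++nltp; else ++nltd;
        }
      }
      if (R == 1.0) { ltp_r1 += nltp; ltd_r1 += nltd; }
      else          { ltp_r0 += nltp; ltd_r0 += nltd; }
    }

    ++steps;

    // --- stop conditions ---
    if (mode == 1 && episodes_done >= n_target) { reached = true; break; }
    if (mode == 2 && ignition_count >= n_target) { reached = true; break; }
    if (mode == 3) {
      bool quiet = true;
      for (int a = 0; a < N_AREAS; ++a) if (area_spikes[a] >= base_tol) { quiet = false; break; }
      quiet_run = quiet ? quiet_run + 1 : 0;
      if (quiet_run >= quiet_steps) { reached = true; break; }
    }
  }

  // close any events still open at the end of the run
  for (int c = 0; c < n_ca; ++c) {
    if (above[c]) { ev_ca.push_back(c + 1); ev_start.push_back(ev_open_start[c]); ev_end.push_back(steps); }
  }

  net["R_signal"] = R;
  net["t"] = as<int>(net["t"]) + steps;

  List out = List::create(
    _["steps"] = steps,
    _["reached"] = reached,
    _["ignitions"] = ignition_count,
    _["episodes"] = episodes_done,
    _["ev_ca"] = wrap(ev_ca), _["ev_start"] = wrap(ev_start), _["ev_end"] = wrap(ev_end),
    _["ltp_r0"] = (double)ltp_r0, _["ltp_r1"] = (double)ltp_r1,
    _["ltd_r0"] = (double)ltd_r0, _["ltd_r1"] = (double)ltd_r1,
    _["reward_steps"] = reward_steps
  );
  if (rec_act && n_ca > 0) {
    NumericMatrix A(n_ca, steps);
    std::copy(act_log.begin(), act_log.end(), A.begin());
    out["activity"] = transpose(A);  // steps x n_ca
  }
  if (rec_reward) out["reward_trace"] = wrap(reward_log);
  if (rec_spikes) {
    IntegerMatrix S(N_AREAS, steps);
    std::copy(spike_log.begin(), spike_log.end(), S.begin());
    out["area_spikes"] = transpose(S);  // steps x 6
  }
  if (rec_peak) out["peak_omega_e"] = wrap(peak_omE);
  return out;
}
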