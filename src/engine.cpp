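#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Time-stepped network engine: Izhikevich membrane dynamics driven by
// noise + current-based synapses + external stimuli, with pair/triplet
// STDP under multiplicative soft bounds and activity-dependent forgetting.
//
// Update order within one step of length dt (documented contract):
//   1. assemble I_i = noise + sum_j g_j w_ji y_j + I_stml(t) using the
//      synaptic traces as of the end of the previous step
//   2. advance (v, u) by forward Euler (v in two half-steps)
//   3. detect threshold crossings
//   4. decay every trace by exp(-dt/tau)
//   5. plasticity, reading the decayed but *pre-increment* traces:
//      LTD at presynaptic spikes, then LTP at postsynaptic spikes, then
//      the continuous forgetting decay
//   6. increment the traces of neurons that spiked this step
//   7. reset spiked neurons: v <- c_reset, u <- u + d_jump
// A spike therefore never interacts with the trace increment it causes;
// the delta terms of the learning rules pair a spike only with traces
// left by earlier spikes.

// synapse rule codes
static const int RULE_FIXED = 0;
static const int RULE_PAIR = 1;
static const int RULE_TRIPLET = 2;
static const int RULE_TRIPLET_FORGET = 3;

// [[Rcpp::export]]
List cpp_simulate(NumericVector a, NumericVector b, NumericVector c_reset,
                  NumericVector d_jump, NumericVector D_noise,
                  NumericVector g_scale, NumericVector v_thresh,
                  NumericVector v0, NumericVector u0,
                  IntegerVector syn_pre, IntegerVector syn_post,
                  NumericVector w0, IntegerVector syn_rule,
                  NumericVector syn_lambda, NumericVector syn_alpha,
                  NumericVector syn_tauf,
                  double tau_syn, double tau1, double tau2, double tau_o,
                  IntegerVector pulse_neuron, NumericVector pulse_onset,
                  NumericVector pulse_dur, NumericVector pulse_amp,
                  IntegerVector cont_neuron, NumericMatrix cont_current,
                  double cont_fs,
                  double duration, double dt, bool learning,
                  double snapshot_every) {
  const int n = a.size();
  const int ns = syn_pre.size();
  const long n_steps = (long)std::llround(duration / dt);

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> y_syn(n, 0.0), y1(n, 0.0), y2(n, 0.0), yo(n, 0.0);
  std::vector<int> spiked(n, 0);
  // Euler-Maruyama white-noise scaling: the per-step current sample has
  // sd sqrt(D/dt), so the integrated noise is dt-invariant
  std::vector<double> noise_sd(n);
  for (int i = 0; i < n; ++i) noise_sd[i] = std::sqrt(D_noise[i] / dt);

  const double dec_syn = std::exp(-dt / tau_syn);
  const double dec_1 = std::exp(-dt / tau1);
  const double dec_2 = std::exp(-dt / tau2);
  const double dec_o = std::exp(-dt / tau_o);

  // per-neuron pulse schedules (inputs sorted by neuron then onset)
  const int np = pulse_neuron.size();
  std::vector<int> p_begin(n + 1, 0);
  {
    std::vector<int> cnt(n, 0);
    for (int k = 0; k < np; ++k) cnt[pulse_neuron[k]]++;
    for (int i = 0; i < n; ++i) p_begin[i + 1] = p_begin[i] + cnt[i];
  }
  std::vector<int> p_ptr(p_begin.begin(), p_begin.end() - 1);

  const int n_cont = cont_neuron.size();
  const int n_cont_samples = n_cont > 0 ? cont_current.nrow() : 0;

  // weight snapshots
  std::vector<double> snap_times;
  std::vector<double> snap_w;
  bool do_snap = snapshot_every > 0 && ns > 0;
  double next_snap = 0.0;
  if (do_snap) {
    snap_times.push_back(0.0);
    for (int s = 0; s < ns; ++s) snap_w.push_back(w[s]);
    next_snap = snapshot_every;
  }

  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  std::vector<double> I(n, 0.0);

  for (long step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // 1. driving currents
    for (int i = 0; i < n; ++i) {
      double cur = 0.0;
      if (noise_sd[i] > 0.0) cur += norm_rand() * noise_sd[i];
      I[i] = cur;
    }
    for (int s = 0; s < ns; ++s)
      I[syn_post[s]] += g_scale[syn_pre[s]] * w[s] * y_syn[syn_pre[s]];
    for (int i = 0; i < n; ++i) {
      int p = p_ptr[i];
      // drop pulses that ended; sum active ones (overlap allowed)
      while (p < p_begin[i + 1] && pulse_onset[p] + pulse_dur[p] <= t) ++p;
      p_ptr[i] = p;
      for (int q = p; q < p_begin[i + 1] && pulse_onset[q] <= t; ++q)
        if (pulse_onset[q] + pulse_dur[q] > t) I[i] += pulse_amp[q];
    }
    if (n_cont > 0) {
      long idx = (long)std::floor(t * cont_fs / 1000.0);
      if (idx >= n_cont_samples) idx = n_cont_samples - 1;
      for (int k = 0; k < n_cont; ++k)
        I[cont_neuron[k]] += cont_current(idx, k);
    }

    // 2-3. membrane update (v in two half-steps) and spike detection
    for (int i = 0; i < n; ++i) {
      double vi = v[i], ui = u[i];
      // membrane advanced in four quarter-steps (clamped at the spike
      // peak) for accuracy of the fast upstroke; recovery at full dt.
      // Upward excursions are spikes (reset below); only non-finite
      // values or runaway hyperpolarization abort the run.
      for (int q = 0; q < 4; ++q) {
        vi += 0.25 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I[i]);
        if (!std::isfinite(vi) || vi < -1e3)
          stop("membrane potential diverged (v < -1000 mV or non-finite) at t = %.2f ms, neuron %d; reduce dt or stimulus amplitude",
               t, i + 1);
        if (vi > v_thresh[i]) vi = v_thresh[i];
      }
      ui += dt * a[i] * (b[i] * vi - ui);
      spiked[i] = vi >= v_thresh[i] ? 1 : 0;
      v[i] = vi;
      u[i] = ui;
    }

    // 4. trace decay
    for (int i = 0; i < n; ++i) {
      y_syn[i] *= dec_syn;
      y1[i] *= dec_1;
      y2[i] *= dec_2;
      yo[i] *= dec_o;
    }

    // 5. plasticity on pre-increment traces
    if (learning) {
      for (int s = 0; s < ns; ++s) {
        const int rule = syn_rule[s];
        if (rule == RULE_FIXED) continue;
        const int pre = syn_pre[s], post = syn_post[s];
        double ws = w[s];
        if (spiked[pre])  // LTD
          ws -= syn_lambda[s] * syn_alpha[s] * ws * y1[post];
        if (spiked[post]) {  // LTP
          double dw = syn_lambda[s] * (1.0 - ws) * y1[pre];
          if (rule >= RULE_TRIPLET) dw *= y2[post];
          ws += dw;
        }
        if (rule == RULE_TRIPLET_FORGET && yo[post] > 0.0)
          ws *= std::exp(-yo[post] * dt / syn_tauf[s]);
        if (ws < 0.0) ws = 0.0;
        if (ws > 1.0) ws = 1.0;
        w[s] = ws;
      }
    }

    // 6-7. trace increments and resets
    for (int i = 0; i < n; ++i) {
      if (spiked[i]) {
        y_syn[i] += 1.0;
        y1[i] += 1.0;
        y2[i] += 1.0;
        yo[i] += 1.0;
        v[i] = c_reset[i];
        u[i] += d_jump[i];
        sp_neuron.push_back(i + 1);
        sp_time.push_back(t + dt);
      }
    }

    if (do_snap && (step + 1) * dt >= next_snap - 1e-9) {
      snap_times.push_back((step + 1) * dt);
      for (int s = 0; s < ns; ++s) snap_w.push_back(w[s]);
      next_snap += snapshot_every;
    }
  }

  NumericMatrix snaps(ns > 0 ? (int)snap_times.size() : 0, ns);
  if (do_snap)
    for (size_t r = 0; r < snap_times.size(); ++r)
      for (int s = 0; s < ns; ++s)
        snaps(r, s) = snap_w[r * ns + s];

  return List::create(
      _["spike_neuron"] = wrap(sp_neuron), _["spike_time"] = wrap(sp_time),
      _["w_final"] = wrap(w), _["snapshot_times"] = wrap(snap_times),
      _["snapshots"] = snaps, _["v_final"] = wrap(v),
      _["u_final"] = wrap(u), _["y_syn_final"] = wrap(y_syn));
}
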