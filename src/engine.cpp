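// Event-driven spiking network engine on a 1 ms grid.
//
// Neurons are current-based LIF, Poisson sources or scripted spike sources.
// Static synapses deposit their weight into a delay ring buffer whenever the
// pre neuron spikes. Plastic synapses are grouped into per-pre-neuron rows
// and updated lazily: when the pre neuron spikes, the row replays the
// post-synaptic event histories (post spikes + dopaminergic arrivals) over
// (t_old, t] using closed-form integration of the inter-event dynamics.
// Dopaminergic synapses bypass the ring buffer and write straight into the
// target's history.
//
// Phase order within a timestep: ring-buffer consumption and neuron update
// (spike detection), dopaminergic deliveries, post-spike history recording,
// then row processing; so dopamine entries precede post entries at equal
// times and the pre-spike depression is applied last.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct History {
  std::vector<int> time;
  std::vector<double> s;   // post trace after the entry's own update
  std::vector<double> d;   // dopamine concentration after the entry's own update
  std::vector<unsigned char> type; // 0 = post spike, 1 = dopamine
};

struct Row {
  double t_old = 0.0;
  double s_i = 0.0;
  int mode = 0; // 0 = neuromod, 1 = pair
  std::vector<int> post;
  std::vector<double> w;
  std::vector<double> c;
  std::vector<int> delay;
};

struct StaticSyn {
  int post;
  double w;
  int delay;
  bool inhibitory;
};

struct DopaSyn {
  int post;
  double d_c;
};

struct PlastCfg {
  double a_plus, a_minus, tau_plus, tau_minus, tau_c, tau_d, w_min, w_max;
  double inv; // 1/tau_c + 1/tau_d
};

inline double clampw(double w, const PlastCfg& cfg) {
  return std::min(std::max(w, cfg.w_min), cfg.w_max);
}

inline void record_post(History& h, int t, const PlastCfg& cfg) {
  if (h.time.empty()) {
    h.time.push_back(t); h.s.push_back(1.0); h.d.push_back(0.0); h.type.push_back(0);
  } else {
    double dt = t - h.time.back();
    h.s.push_back(h.s.back() * std::exp(-dt / cfg.tau_minus) + 1.0);
    h.d.push_back(h.d.back() * std::exp(-dt / cfg.tau_d));
    h.time.push_back(t); h.type.push_back(0);
  }
}

inline void record_dopamine(History& h, int t, double d_c, const PlastCfg& cfg) {
  if (h.time.empty()) {
    h.time.push_back(t); h.s.push_back(0.0); h.d.push_back(d_c); h.type.push_back(1);
  } else {
    double dt = t - h.time.back();
    h.s.push_back(h.s.back() * std::exp(-dt / cfg.tau_minus));
    h.d.push_back(h.d.back() * std::exp(-dt / cfg.tau_d) + d_c);
    h.time.push_back(t); h.type.push_back(1);
  }
}

// Post trace sampled at t; a post entry at exactly t contributes without its
// own +1 increment (simultaneous spikes never pair).
inline double post_trace_at(const History& h, int t, const PlastCfg& cfg) {
  if (h.time.empty()) return 0.0;
  size_t last = std::upper_bound(h.time.begin(), h.time.end(), t) - h.time.begin();
  if (last == 0) return 0.0;
  --last;
  double s = h.s[last];
  if (h.time[last] == t && h.type[last] == 0) s -= 1.0;
  return s * std::exp(-(double)(t - h.time[last]) / cfg.tau_minus);
}

// Advance one synapse's (w, C) from t_old to t by walking the target history.
inline void walk_neuromod(double& w, double& c, const History& h, double t_old,
                          double t, double s_i, const PlastCfg& cfg) {
  size_t lo = std::upper_bound(h.time.begin(), h.time.end(), t_old) - h.time.begin();
  size_t hi = std::upper_bound(h.time.begin(), h.time.end(), t) - h.time.begin();
  double t_c = t_old;
  double d_c = 0.0;
  if (lo > 0)
    d_c = h.d[lo - 1] * std::exp(-(t_old - h.time[lo - 1]) / cfg.tau_d);
  for (size_t k = lo; k < hi; ++k) {
    double tj = h.time[k];
    w += c * d_c / (-cfg.inv) * (std::exp(-(tj - t_c) * cfg.inv) - 1.0);
    c *= std::exp(-(tj - t_c) / cfg.tau_c);
    if (h.type[k] == 0)
      c += cfg.a_plus * s_i * std::exp(-(tj - t_old) / cfg.tau_plus);
    d_c = h.d[k];
    t_c = tj;
  }
  w += c * d_c / (-cfg.inv) * (std::exp(-(t - t_c) * cfg.inv) - 1.0);
  c *= std::exp(-(t - t_c) / cfg.tau_c);
}

void process_row(Row& row, int t, std::vector<History>& hist,
                 const PlastCfg& cfg, std::vector<double>& ring_exc,
                 int ring_size, int n_neurons) {
  for (size_t s = 0; s < row.post.size(); ++s) {
    const History& h = hist[row.post[s]];
    double w = row.w[s];
    if (row.mode == 0) { // three-factor
      double c = row.c[s];
      walk_neuromod(w, c, h, row.t_old, (double)t, row.s_i, cfg);
      c -= cfg.a_minus * post_trace_at(h, t, cfg);
      row.c[s] = c;
    } else { // plain pair STDP acting on the weight
      size_t lo = std::upper_bound(h.time.begin(), h.time.end(), row.t_old) - h.time.begin();
      size_t hi = std::upper_bound(h.time.begin(), h.time.end(), (double)t) - h.time.begin();
      for (size_t k = lo; k < hi; ++k)
        if (h.type[k] == 0)
          w += cfg.a_plus * row.s_i * std::exp(-(h.time[k] - row.t_old) / cfg.tau_plus);
      w -= cfg.a_minus * post_trace_at(h, t, cfg);
    }
    w = clampw(w, cfg);
    row.w[s] = w;
    int slot = (t + row.delay[s]) % ring_size;
    ring_exc[(size_t)slot * n_neurons + row.post[s]] += w;
  }
  row.s_i = row.s_i * std::exp(-((double)t - row.t_old) / cfg.tau_plus) + 1.0;
  row.t_old = t;
}

// Apply pending updates up to t without a pre spike (lazy split; exact).
void flush_row(Row& row, double t, std::vector<History>& hist, const PlastCfg& cfg) {
  if (t <= row.t_old) return;
  if (row.mode == 0) {
    for (size_t s = 0; s < row.post.size(); ++s) {
      double w = row.w[s], c = row.c[s];
      walk_neuromod(w, c, hist[row.post[s]], row.t_old, t, row.s_i, cfg);
      row.w[s] = clampw(w, cfg);
      row.c[s] = c;
    }
  }
  row.s_i *= std::exp(-(t - row.t_old) / cfg.tau_plus);
  row.t_old = t;
}

} // namespace

// [[Rcpp::export(name = ".run_network_cpp")]]
List run_network_cpp(int n_neurons,
                     IntegerVector neuron_type,   // 0 lif, 1 poisson, 2 scripted
                     NumericMatrix lif_params,    // n x 9
                     NumericVector v_init,
                     NumericVector poisson_rate,  // Hz, per neuron
                     List scripted_spikes,        // per neuron, sorted int times
                     IntegerVector syn_pre, IntegerVector syn_post,
                     NumericVector syn_weight, IntegerVector syn_delay,
                     IntegerVector syn_kind,      // 0 exc, 1 inh, 2 neuromod, 3 pair, 4 dopaminergic
                     List plast_cfg,
                     NumericMatrix stim,          // time, neuron (1-based), amplitude; sorted by time
                     int duration, int max_delay,
                     IntegerVector snapshot_times, // sorted, ascending
                     bool flush_at_end, bool record_spikes) {
  PlastCfg cfg;
  cfg.a_plus = as<double>(plast_cfg["a_plus"]);
  cfg.a_minus = as<double>(plast_cfg["a_minus"]);
  cfg.tau_plus = as<double>(plast_cfg["tau_plus"]);
  cfg.tau_minus = as<double>(plast_cfg["tau_minus"]);
  cfg.tau_c = as<double>(plast_cfg["tau_c"]);
  cfg.tau_d = as<double>(plast_cfg["tau_d"]);
  cfg.w_min = as<double>(plast_cfg["w_min"]);
  cfg.w_max = as<double>(plast_cfg["w_max"]);
  cfg.inv = 1.0 / cfg.tau_c + 1.0 / cfg.tau_d;

  const int n_syn = syn_pre.size();
  std::vector<std::vector<StaticSyn> > static_out(n_neurons);
  std::vector<std::vector<DopaSyn> > dopa_out(n_neurons);
  std::vector<Row> rows(n_neurons);
  std::vector<bool> has_row(n_neurons, false);
  std::vector<bool> is_target(n_neurons, false);
  std::vector<int> plastic_orig; // original 1-based synapse indices, row-grouped order
  std::vector<std::pair<int, int> > plastic_loc; // (pre, slot) per plastic synapse

  for (int i = 0; i < n_syn; ++i) {
    int pre = syn_pre[i] - 1, post = syn_post[i] - 1;
    if (pre < 0 || pre >= n_neurons || post < 0 || post >= n_neurons)
      stop("synapse endpoint out of range");
    int kind = syn_kind[i];
    if (kind == 0 || kind == 1) {
      StaticSyn s;
      s.post = post; s.w = syn_weight[i]; s.delay = syn_delay[i];
      s.inhibitory = (kind == 1);
      if (s.delay < 1 || s.delay > max_delay) stop("static synapse delay out of range");
      static_out[pre].push_back(s);
    } else if (kind == 4) {
      DopaSyn d;
      d.post = post; d.d_c = syn_weight[i];
      dopa_out[pre].push_back(d);
      is_target[post] = true; // dopamine entries require a history
    } else if (kind == 2 || kind == 3) {
      Row& r = rows[pre];
      int mode = (kind == 2) ? 0 : 1;
      if (!has_row[pre]) {
        r.mode = mode;
        has_row[pre] = true;
      } else if (r.mode != mode) {
        stop("a pre neuron cannot mix three-factor and pair-STDP synapses");
      }
      if (syn_delay[i] < 1 || syn_delay[i] > max_delay)
        stop("plastic synapse delay out of range");
      r.post.push_back(post);
      r.w.push_back(syn_weight[i]);
      r.c.push_back(0.0);
      r.delay.push_back(syn_delay[i]);
      plastic_orig.push_back(i + 1);
      plastic_loc.push_back(std::make_pair(pre, (int)r.post.size() - 1));
      is_target[post] = true;
    } else {
      stop("unknown synapse kind");
    }
  }
  const int n_plastic = (int)plastic_orig.size();

  std::vector<History> hist(n_neurons);

  // ring buffer: (max_delay + 1) slots x n_neurons, exc and inh separately
  const int ring_size = max_delay + 1;
  std::vector<double> ring_exc((size_t)ring_size * n_neurons, 0.0);
  std::vector<double> ring_inh((size_t)ring_size * n_neurons, 0.0);

  // neuron state + per-neuron precomputed factors
  std::vector<double> v(n_neurons), ise(n_neurons, 0.0), isi(n_neurons, 0.0);
  std::vector<double> refrac(n_neurons, 0.0);
  std::vector<double> e_m(n_neurons), e_se(n_neurons), e_si(n_neurons),
      r_m(n_neurons), p_spike(n_neurons);
  for (int i = 0; i < n_neurons; ++i) {
    v[i] = v_init[i];
    if (neuron_type[i] == 0) {
      e_m[i] = std::exp(-1.0 / lif_params(i, 2));
      e_se[i] = std::exp(-1.0 / lif_params(i, 4));
      e_si[i] = std::exp(-1.0 / lif_params(i, 5));
      r_m[i] = lif_params(i, 2) / lif_params(i, 0);
    } else if (neuron_type[i] == 1) {
      p_spike[i] = -std::expm1(-poisson_rate[i] / 1000.0);
    }
  }
  std::vector<int> script_ptr(n_neurons, 0);

  std::vector<int> spike_t, spike_n;
  std::vector<int> spiking;
  spiking.reserve(n_neurons);

  std::vector<double> i_ext(n_neurons, 0.0);
  int stim_ptr = 0;
  const int n_stim = stim.nrow();

  const int n_snap = snapshot_times.size();
  NumericMatrix snapshots(n_snap, n_plastic);
  int snap_ptr = 0;

  for (int t = 1; t <= duration; ++t) {
    // external pulse currents active this step
    std::vector<int> ext_touched;
    while (stim_ptr < n_stim && stim(stim_ptr, 0) == t) {
      int nrn = (int)stim(stim_ptr, 1) - 1;
      i_ext[nrn] += stim(stim_ptr, 2);
      ext_touched.push_back(nrn);
      ++stim_ptr;
    }
    if (stim_ptr < n_stim && stim(stim_ptr, 0) < t)
      stop("stimulus rows must be sorted by time");

    int slot = t % ring_size;
    double* dep_e = &ring_exc[(size_t)slot * n_neurons];
    double* dep_i = &ring_inh[(size_t)slot * n_neurons];

    spiking.clear();
    for (int i = 0; i < n_neurons; ++i) {
      bool spiked = false;
      if (neuron_type[i] == 0) {
        ise[i] += dep_e[i];
        isi[i] += dep_i[i];
        double itot = ise[i] + isi[i] + lif_params(i, 1) + i_ext[i];
        if (refrac[i] > 0) {
          refrac[i] -= 1.0;
          v[i] = lif_params(i, 6);
        } else {
          double vinf = lif_params(i, 7) + r_m[i] * itot;
          v[i] = vinf + (v[i] - vinf) * e_m[i];
          if (v[i] >= lif_params(i, 8)) {
            spiked = true;
            v[i] = lif_params(i, 6);
            refrac[i] = lif_params(i, 3);
          }
        }
        ise[i] *= e_se[i];
        isi[i] *= e_si[i];
      } else if (neuron_type[i] == 1) {
        spiked = (unif_rand() < p_spike[i]);
      } else {
        IntegerVector sched = scripted_spikes[i];
        if (script_ptr[i] < sched.size() && sched[script_ptr[i]] == t) {
          spiked = true;
          ++script_ptr[i];
        }
      }
      if (spiked) spiking.push_back(i);
      dep_e[i] = 0.0;
      dep_i[i] = 0.0;
    }
    for (size_t k = 0; k < ext_touched.size(); ++k) i_ext[ext_touched[k]] = 0.0;

    if (record_spikes)
      for (size_t k = 0; k < spiking.size(); ++k) {
        spike_t.push_back(t);
        spike_n.push_back(spiking[k] + 1);
      }

    // dopaminergic deliveries first (ties: dopamine before post spikes)
    for (size_t k = 0; k < spiking.size(); ++k) {
      const std::vector<DopaSyn>& ds = dopa_out[spiking[k]];
      for (size_t m = 0; m < ds.size(); ++m)
        record_dopamine(hist[ds[m].post], t, ds[m].d_c, cfg);
    }
    // post-spike history recording
    for (size_t k = 0; k < spiking.size(); ++k)
      if (is_target[spiking[k]])
        record_post(hist[spiking[k]], t, cfg);
    // static deliveries and plastic row processing
    for (size_t k = 0; k < spiking.size(); ++k) {
      int i = spiking[k];
      const std::vector<StaticSyn>& ss = static_out[i];
      for (size_t m = 0; m < ss.size(); ++m) {
        int dslot = (t + ss[m].delay) % ring_size;
        double* dep = ss[m].inhibitory ? &ring_inh[(size_t)dslot * n_neurons]
                                       : &ring_exc[(size_t)dslot * n_neurons];
        dep[ss[m].post] += ss[m].w;
      }
      if (has_row[i])
        process_row(rows[i], t, hist, cfg, ring_exc, ring_size, n_neurons);
    }

    while (snap_ptr < n_snap && snapshot_times[snap_ptr] == t) {
      for (int i = 0; i < n_neurons; ++i)
        if (has_row[i]) flush_row(rows[i], (double)t, hist, cfg);
      for (int p = 0; p < n_plastic; ++p)
        snapshots(snap_ptr, p) = rows[plastic_loc[p].first].w[plastic_loc[p].second];
      ++snap_ptr;
    }
  }

  if (flush_at_end)
    for (int i = 0; i < n_neurons; ++i)
      if (has_row[i]) flush_row(rows[i], (double)duration, hist, cfg);

  NumericVector w_out(n_plastic), c_out(n_plastic);
  for (int p = 0; p < n_plastic; ++p) {
    w_out[p] = rows[plastic_loc[p].first].w[plastic_loc[p].second];
    c_out[p] = rows[plastic_loc[p].first].c[plastic_loc[p].second];
  }

  return List::create(
      _["spike_time"] = wrap(spike_t),
      _["spike_neuron"] = wrap(spike_n),
      _["plastic_index"] = wrap(plastic_orig),
      _["weights"] = w_out,
      _["eligibility"] = c_out,
      _["snapshots"] = snapshots,
      _["snapshot_times"] = snapshot_times);
}
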