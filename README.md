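# tristdp

Event-driven simulation of spiking neural networks with a three-factor
(dopamine-modulated) STDP learning rule.

## The problem

Pair-based STDP strengthens a synapse whenever its pre-synaptic neuron fires
shortly before its post-synaptic neuron. That rule alone cannot learn from a
*delayed* reward: by the time a reinforcement signal arrives — hundreds of
milliseconds to a second after the causal activity, with unrelated activity
in between — the spike pairing that earned it is long gone. This is the
distal-reward (credit-assignment) problem.

The three-factor rule solves it with two slow variables. STDP no longer
writes to the weight but to a per-synapse **eligibility trace** `C`, which
decays with time constant `τ_c`:

    dC/dt = −C/τ_c + STDP(Δt) · δ(t − t_pre/post)

A global **dopamine concentration** `D` is incremented by `D_c` at each
dopaminergic spike (negative `D_c` encodes punishment) and is re-absorbed
with time constant `τ_d`:

    dD/dt = −D/τ_d + D_c · Σ δ(t − t_d)

The weight drifts only where both are non-zero:

    dW/dt = C · D

A synapse that was active shortly before a reward is still "tagged"
(`C ≠ 0`) when the dopamine wave arrives, and only such synapses change.

Simulating this efficiently is the second half of the problem. Updating
every synapse every millisecond is wasteful, so synapses are updated
**lazily**: a synaptic row (all outgoing synapses of one neuron) is touched
only when that neuron spikes. Between events the dynamics are linear, so the
interval since the last update is replayed in closed form — post-synaptic
spikes and dopaminergic arrivals are read back from a per-neuron event
history, and the weight drift over each event-free segment is the exact
integral

    Δw = C·D / −(1/τ_c + 1/τ_d) · (e^{−Δt/τ_c} e^{−Δt/τ_d} − 1)

Dopaminergic spikes are a special synapse type: they never depolarise the
target; they are written straight into its event history.

The package is aimed at computational-neuroscience users who want a small,
fully deterministic, testable implementation of this algorithm: every
closed-form path is verified against a dense clock-driven integrator of the
same equations (`simulate_dense()`), to ~1e−12 absolute.

## What is in the box

* `decay_trace()`, `apply_post_spike()`, `apply_pre_spike()`,
  `weight_delta()`, `weight_delta_general()` — the plasticity mathematics.
* `post_history()`, `synaptic_row()`, `process_row_neuromod()`,
  `process_row_pair_stdp()`, `ring_buffer()` — the event-driven machinery in
  plain R, plus a compiled engine (`run_network()`) used by the experiment
  runners.
* `lif_params()`, `lif_step()`, `poisson_step()`, `inject_pulse()` —
  current-based leaky integrate-and-fire neurons with exponential synaptic
  currents, Poisson sources, pulse stimuli.
* Experiments: `run_single_synapse_protocol()` / `sweep_dopamine_delay()`
  (delayed reinforcement of one synapse), `run_reward_punishment()` (ten
  Poisson-driven neurons, rewarded then punished), and
  `build_conditioning_network()` / `run_conditioning()` (Pavlovian
  conditioning in a recurrent network of LIF neurons).
* `load_config()` / `run_experiment()` and a thin CLI (`exec/tristdp`) for
  YAML-configured runs.

## Worked example

A single pre-synaptic spike at 1 ms makes two post-synaptic neurons fire at
3 ms, tagging the synapses with eligibility `e^{−2/10}`. A dopaminergic
spike (`D_c = 0.1`) arrives later; the earlier it comes, the larger the
weight change:

```r
library(tristdp)
run_single_synapse_protocol(4, 0.1)     # 13.6319
run_single_synapse_protocol(1000, 0.1)  #  5.0350
run_single_synapse_protocol(4, -0.1)    # -13.6319  (punishment mirrors reward)
```

13.63 is `e^{−2/10} · e^{−1/1000} · 0.1 · τ_c τ_d/(τ_c+τ_d)` with
`τ_c = 1000 ms`, `τ_d = 200 ms`: the tag, decayed to the dopamine arrival,
times the integrated dopamine transient.

Ten neurons driven by 50 Hz Poisson sources through plastic synapses;
dopamine rewards at 2, 3, 4 s and punishments at 8, 9, 10 s:

```r
r <- run_reward_punishment(seed = 2)
r$rate(0, 2000)       # 10.95 Hz  baseline
r$rate(5000, 8000)    # 39.90 Hz  after the rewards
r$rate(11000, 14000)  # 15.97 Hz  after the punishments
```

Pavlovian conditioning at desk scale (200 neurons, ~4,000 synapses,
10 simulated minutes): stimulus groups are presented every 100–300 ms, and
every presentation of group `S_1` is followed, up to 1 s later, by a
dopamine reward. Synapses leaving `S_1` end up stronger than the network
average:

```r
net <- build_conditioning_network(200, seed = 1)   # 3,979 synapses, 100 groups
r <- run_conditioning(net, duration = 600000, seed = 101)
tail(r$summary, 1)
#     time_ms group_mean_nA global_mean_nA
# 600  600000      2.171026       1.728989
```

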