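---
title: "Three-factor STDP: model, event-driven evaluation, and experiment design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-factor STDP: model, event-driven evaluation, and experiment design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tristdp)
```

## The model

Each neuron carries exponentially decaying spike traces: the pre-synaptic
trace $s_i$ (time constant $\tau_+$) and the post-synaptic trace $s_j$
($\tau_-$), each incremented by one at its neuron's spikes. Sampling the
partner's trace at spike times realises the exponential STDP window
$A_\pm e^{-|\Delta t|/\tau_\pm}$ implicitly, with all-to-all spike pairing
and additive weight dependence: there is no windowed pair search, and traces
accumulate without saturation.

In the three-factor rule these STDP increments are applied not to the weight
but to a per-synapse eligibility trace $C$,

$$\frac{dC}{dt} = -\frac{C}{\tau_c} + \mathrm{STDP}(\Delta t)\,
  \delta(t - t_{pre/post}),$$

while dopaminergic spikes increment a per-neuron dopamine concentration $D$
(by $D_c$, negative for punishment) that is re-absorbed with time constant
$\tau_d$. The weight obeys $dW/dt = C\,D$: plasticity is expressed only
while dopamine is present, and only at synapses still tagged by recent
pre/post coincidences. With $\tau_c \gg \tau_d$ the eligibility trace acts
as a synaptic memory that lets a reward delayed by up to a second credit the
activity that caused it.

## Event-driven evaluation

Between events all three quantities decay exponentially, so the simulator
touches a synapse only when its pre-synaptic neuron spikes. Each
plasticity-target neuron keeps an event history — post spikes and
dopaminergic arrivals, each entry storing the trace values valid at its time
— and each synaptic row stores the time `t_old` of its last processing.
Processing a row at a pre-spike time $t$ walks the target's history over
$(t_{old}, t]$, alternating closed-form weight drift over event-free
segments,

$$\Delta w = \frac{C D}{-(1/\tau_c + 1/\tau_d)}
  \left(e^{-\Delta t/\tau_c} e^{-\Delta t/\tau_d} - 1\right),$$

with the instantaneous updates at each event (decay $C$; potentiation at
post entries; dopamine re-reference at dopaminergic entries). The pre-spike
depression is applied last, the weight is clamped to $[w_{min}, w_{max}]$
once per completed row processing, and the result is deposited into a delay
ring buffer that delivers it to the target's synaptic current `delay` steps
later. Dopaminergic spikes never enter the ring buffer; they are written
directly into the target's history and do not depolarise it.

Because the segments compose exactly (the exponentials satisfy the
semigroup property), a row may be flushed to any intermediate time — for
weight snapshots, checkpoints, or the end-of-run report — without changing
the final result beyond floating-point rounding. Rows whose pre-neuron
never spikes are never processed; the end-of-run flush makes reported
weights include the pending dopamine-gated drift.

### Numerical choices and tie-breaking

* Double-precision floating point throughout; traces are not flushed to
  zero, so unlike fixed-point hardware implementations the eligibility
  trace only reaches zero asymptotically.
* Time is a 1 ms integer grid for spikes, dopamine and neuron updates.
* At equal timestamps, dopamine entries are recorded before post-spike
  entries, and the pre-spike depression is always applied after the history
  walk.
* Simultaneous pre/post spikes do not pair: traces are sampled before being
  incremented at the same timestamp. Concretely, when the pre-spike
  depression samples the post trace at time $t$ and the latest history
  entry is a post spike at exactly $t$, that entry's own $+1$ increment is
  subtracted before decay.
* The eligibility trace is not clamped; only the weight is, per completed
  row processing (not per history entry), with defaults $w_{min} = 0$ and a
  per-experiment $w_{max}$. The single-synapse protocol uses unbounded
  weights so its delay sweep is the pure closed form.

### The dense reference integrator

`simulate_dense()` advances every synapse every 1 ms, using the same
closed form *within* each step, so it is step-size-exact rather than an
Euler approximation and shares the tie rules above. Disagreements with the
event-driven path therefore isolate implementation bugs, not
discretisation. The test-suite holds the compiled engine, the plain-R event
engine and this integrator together to a relative $10^{-9}$ (absolute
$10^{-12}$ for values at the noise floor) over randomised driven networks,
and the closed-form weight update to adaptive quadrature at relative
$10^{-6}$ over $10^4$ random parameter draws. The quadrature oracle
integrates on a shifted variable so its integrand starts at unity;
otherwise the quadrature itself becomes the dominant error source.

## Neurons and inputs

Neurons are current-based leaky integrate-and-fire with exponential
synaptic currents. Parameters (defaults): membrane capacitance 0.3 nF,
$\tau_m$ = 10 ms, rest −65 mV, reset −70 mV; the excitatory (regular
spiking) cell has threshold −55.4 mV, refractory period 4 ms, offset
current 0.005 nA; the inhibitory (fast spiking) cell threshold −56.4 mV,
refractory 2 ms, no offset. Integration is the exact exponential update on
the 1 ms grid with piecewise-constant input, so neuron dynamics are
deterministic and reproducible to the bit. Initial membrane potentials are
uniform at rest. Poisson sources spike with probability
$1 - e^{-r\,dt/1000}$ per step under R's seeded RNG. Stimulus pulses inject
a 1 ms current computed as 1.2× the minimum that lifts a resting excitatory
cell across threshold in one step (≈3.63 nA); inhibitory weights are
negative quantities accumulated into a separate synaptic current.

## The experiments and their free parameters

**Single-synapse delayed reinforcement.** One pre neuron, two post neurons;
pre spike at 1 ms, post spikes at 3 ms, one dopaminergic spike at
$t_d \in [4, 3000]$ ms with $D_c = \pm 0.1$; STDP parameters $A_\pm = 1$,
$\tau_+ = 10$ ms, $\tau_- = 12$ ms, $\tau_c = 1000$ ms, $\tau_d = 200$ ms.
The final weight is $e^{-2/10} e^{-(t_d - 3)/\tau_c} D_c\,
\tau_c\tau_d/(\tau_c + \tau_d)$: monotonically shrinking in the delay, with
punishment the exact mirror of reward.

**Reward/punishment of ten Poisson-driven neurons.** Ten LIF cells, each
driven by an independent 50 Hz Poisson source through a plastic synapse
initialised at 1.5 nA; $\tau_c = 100$ ms, $\tau_d = 5$ ms; single
dopaminergic spikes with $D_c = +0.01$ at 2, 3, 4 s and $D_c = -0.002$ at
8, 9, 10 s. The experiment's intended regime is qualitative: rewards raise
the population rate well above baseline, and punishments — five times
smaller in $|D_c|$ but arriving while rates, and hence eligibility traces,
are high — bring it back down, silencing some neurons. The STDP amplitudes
are free parameters of this protocol; the default $A_\pm = 60$ was chosen
(once) as the scale at which three reward spikes produce a clearly visible
rate increase and the punishment spikes a clearly visible decrease across
seeds. With $A_\pm$ of order one the drift per dopaminergic spike,
$C D_c \tau_c\tau_d/(\tau_c+\tau_d) \approx 0.05\,C$ nA, is far too small
to move 1.5 nA weights perceptibly. Weights are clamped to $[0, 6]$ nA.

**Pavlovian conditioning.** A pool of $N_T$ neurons (80% excitatory, 20%
inhibitory), all-to-all Bernoulli connectivity at 10% without
self-connections; plastic three-factor synapses from excitatory neurons,
static inhibitory synapses from the rest; one dopaminergic source projecting
to every neuron; 10 Hz Poisson noise to every neuron. 100 stimulus groups of
$N_T/20$ neurons are drawn with overlap (the group count is held at 100
across network sizes so each neuron belongs to ~5 groups and the global mean
weight is a fair baseline for any single group). Stimuli are presented every
100–300 ms in random order by a 1 ms super-threshold pulse to the group;
every presentation of $S_1$ is followed by one dopaminergic spike after a
uniform delay of up to 1 s.

The defaults of `build_conditioning_network()` were set, once, by an
explicit regime search at $N_T = 200$ and are documented here because the
experiment only works in a specific dynamical regime:

* *Initial plastic weight 1.5 nA.* A stimulated group's spikes must be able
  to fire some of their targets, otherwise no causal (pre-before-post)
  pairing follows a presentation and the group's outgoing synapses are
  never tagged. Measured directly: 20 ms after a presentation, mean
  outgoing eligibility is ≈0.9 at 1.5 nA versus ≈0 at 0.5 nA.
* *Noise weight 0.7 nA (sub-threshold) and inhibitory weight −10 nA.*
  Together these hold background activity at ~2–3 Hz, sparse and irregular.
  At ~10 Hz background, eligibility fluctuations from recurrent activity
  (sd ≈ 2) swamp the stimulus tag and reward credit becomes seed noise.
* *$w_{max} = 3$ nA, reward $D_c = 0.002$ (single spike).* Small rewards
  bound the global upward drift of the mean weight (which is expected — the
  reward is global and distractor stimuli fall inside the dopamine
  transient — but must not saturate the network within the run).

With these defaults, ten simulated minutes at $N_T = 200$ separate the
rewarded group's mean outgoing weight from the global mean by ≈+0.4 to
+0.9 nA in five of five seeds, while a control in which the reward follows
a random presentation (same rate, no contingency) shows only seed-level
scatter around zero.

## What the synthetic protocols do and do not show

All inputs are generated: Poisson drivers, scripted stimulus pulses, and
scheduled dopaminergic spikes. The generators emulate the *protocols* of
the three experiments — their timing structure, rates and reinforcement
contingencies — not biological realism: there are no conductance synapses,
no axonal delay distributions (all delays default to 1 ms), no
heterogeneous neuron parameters, and dopamine is wired, not
volume-transmitted. Passing tests therefore demonstrate that the
implementation integrates the stated dynamics exactly and that the
credit-assignment mechanism operates at desk scale; they do not calibrate
the model against physiological data. The conditioning run at $N_T = 200$
for 10 minutes is a scaled-down qualitative reproduction of the full
1,000-neuron, one-hour protocol; problem sizes in the test-suite (driven
networks of ≤20 neurons for 10 s; 50 equivalence networks; $10^4$
quadrature draws) were chosen as the smallest instances that still exercise
every code path with dense event collisions.

## Known limitations

* Histories are unbounded in memory; pruning entries older than the oldest
  `t_old` of any incoming row would be safe but is not implemented.
* In pair-STDP (two-factor) mode, lazy semantics mean post spikes after a
  row's final pre spike are not reflected in its reported weight; the
  three-factor mode's end-of-run flush has no such caveat.
* The compiled engine supports one plasticity mode per pre-neuron row.
* Weight snapshots flush all rows, which is exact but makes snapshot
  cadence a (tiny) perturbation of floating-point rounding order, not of
  results.
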