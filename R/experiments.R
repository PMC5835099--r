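# Ready-made experiments: single-synapse delayed reinforcement, population
# reward/punishment, and the Pavlovian-conditioning (credit-assignment)
# network.

#' Single-synapse delayed reward/punishment protocol
#'
#' One pre-synaptic neuron connected to two post-synaptic neurons. A single
#' pre spike at 1 ms makes both post neurons fire at 3 ms, tagging the
#' synapses with a positive eligibility trace; a single dopaminergic spike
#' with increment `d_c` arrives at `dopamine_delay` ms. The later the
#' dopaminergic spike, the more the eligibility trace has decayed and the
#' smaller the resulting weight change; reward (`d_c > 0`) and punishment
#' (`d_c < 0`) produce mirror-image curves. Weight bounds default to
#' unbounded here so the sweep shows the pure closed-form response.
#'
#' @param dopamine_delay Arrival time of the dopaminergic spike in ms.
#' @param d_c Dopamine increment (positive reward, negative punishment).
#' @param pair_cfg A [pair_stdp_config()].
#' @param nm_cfg A [neuromod_config()]; defaults to tau_c = 1000 ms,
#'   tau_d = 200 ms and unbounded weights.
#' @param initial_weight Starting weight (nA).
#' @param settle Extra simulated time after the dopaminergic spike so the
#'   weight drift integral converges (ms).
#' @return The final weight of the first synapse after a closing flush.
#' @export
run_single_synapse_protocol <- function(dopamine_delay, d_c = 0.1,
                                        pair_cfg = pair_stdp_config(),
                                        nm_cfg = neuromod_config(w_min = -Inf, w_max = Inf),
                                        initial_weight = 0,
                                        settle = 6000) {
  synapses <- data.frame(pre = 1L, post = c(2L, 3L),
                         weight = initial_weight, delay = 1L)
  res <- simulate_event_driven(
    synapses,
    pre_spikes = list(`1` = 1L),
    post_spikes = list(NULL, 3L, 3L),
    dopamine_events = data.frame(time = dopamine_delay,
                                 target = c(2L, 3L), d_c = d_c),
    duration = dopamine_delay + settle,
    pair_cfg = pair_cfg, nm_cfg = nm_cfg, mode = "neuromod")
  res$weights[1]
}

#' Sweep the dopamine delay of the single-synapse protocol
#'
#' @param delays Vector of dopaminergic spike times in ms.
#' @param d_c Dopamine increment per spike.
#' @param ... Passed to [run_single_synapse_protocol()].
#' @return A data frame with columns `delay` and `delta_w`.
#' @export
sweep_dopamine_delay <- function(delays = seq(4, 3000, by = 100), d_c = 0.1, ...) {
  dw <- vapply(delays, function(d) run_single_synapse_protocol(d, d_c, ...),
               numeric(1))
  data.frame(delay = delays, delta_w = dw)
}

#' Reward-then-punishment of ten Poisson-driven neurons
#'
#' Ten LIF neurons each receive input from an independent 50 Hz Poisson
#' source through a plastic three-factor synapse initialised at 1.5 nA.
#' Reward dopamine spikes (`D_c = 0.01`) arrive at 2, 3 and 4 s and
#' potentiate recently active synapses, raising the firing rate; punishment
#' spikes (`D_c = -0.002`) at 8, 9 and 10 s depress them again. Short trace
#' time constants (tau_c = 100 ms, tau_d = 5 ms) keep the credit window
#' tight.
#'
#' @param duration Simulated duration in ms.
#' @param seed RNG seed for the Poisson input.
#' @param n_neurons Number of neuron/source pairs.
#' @param input_rate Poisson source rate in Hz.
#' @param initial_weight Initial plastic weight in nA.
#' @param reward_times,punishment_times Dopaminergic spike times in ms.
#' @param d_c_reward,d_c_punishment Dopamine increments.
#' @param pair_cfg A [pair_stdp_config()]; defaults to amplitudes of 60,
#'   which place the experiment in its intended regime: three reward spikes
#'   visibly potentiate, and the punishment spikes — five times smaller in
#'   `|D_c|` but arriving while post-synaptic rates (and hence eligibility
#'   traces) are high — visibly depress, silencing some neurons.
#' @param nm_cfg A [neuromod_config()]; defaults to tau_c = 100 ms,
#'   tau_d = 5 ms, weights clamped to [0, 6] nA.
#' @param dopamine_enabled Set `FALSE` to silence both dopaminergic sources
#'   (control: weights must then stay exactly at their initial values).
#' @return A list with `spikes` (raster of the ten neurons), `weights`
#'   (final plastic weights), `eligibility`, and `rate()`, a helper
#'   `function(from, to)` returning the population mean firing rate in Hz
#'   over `(from, to]` ms.
#' @export
run_reward_punishment <- function(duration = 14000, seed = 1,
                                  n_neurons = 10, input_rate = 50,
                                  initial_weight = 1.5,
                                  reward_times = c(2000, 3000, 4000),
                                  punishment_times = c(8000, 9000, 10000),
                                  d_c_reward = 0.01, d_c_punishment = -0.002,
                                  pair_cfg = pair_stdp_config(a_plus = 60, a_minus = 60),
                                  nm_cfg = neuromod_config(tau_c = 100, tau_d = 5,
                                                           w_min = 0, w_max = 6),
                                  dopamine_enabled = TRUE) {
  # layout: 1..n LIF, n+1..2n Poisson sources, 2n+1 reward source,
  # 2n+2 punishment source
  n <- n_neurons
  neurons <- data.frame(
    type = c(rep("lif", n), rep("poisson", n), "scripted", "scripted"),
    rate = c(rep(0, n), rep(input_rate, n), 0, 0))
  scripted <- c(rep(list(integer(0)), 2 * n),
                if (dopamine_enabled) list(as.integer(reward_times),
                                           as.integer(punishment_times))
                else list(integer(0), integer(0)))
  synapses <- rbind(
    data.frame(pre = n + seq_len(n), post = seq_len(n),
               weight = initial_weight, delay = 1L, kind = "neuromod"),
    data.frame(pre = 2L * n + 1L, post = seq_len(n),
               weight = d_c_reward, delay = 1L, kind = "dopaminergic"),
    data.frame(pre = 2L * n + 2L, post = seq_len(n),
               weight = d_c_punishment, delay = 1L, kind = "dopaminergic"))
  set.seed(seed)
  res <- run_network(neurons, lif_params_rs(), scripted, synapses,
                     pair_cfg, nm_cfg, stim = NULL, duration = duration)
  spikes <- res$spikes[res$spikes$neuron <= n, , drop = FALSE]
  rate <- function(from, to)
    sum(spikes$time > from & spikes$time <= to) / n / ((to - from) / 1000)
  list(spikes = spikes, weights = res$weights, eligibility = res$eligibility,
       rate = rate)
}

#' Build the Pavlovian-conditioning network
#'
#' A pool of `n_total` LIF neurons, 80% regular-spiking excitatory and 20%
#' fast-spiking inhibitory, connected all-to-all with probability
#' `connection_probability` (no self-connections). Connections originating
#' from excitatory neurons are plastic under the three-factor rule;
#' inhibitory neurons project through fixed negative-weight synapses.
#' `n_groups` stimulus groups of `n_total / 20` neurons are drawn randomly
#' (groups may overlap; no repeats within a group). The group count is held
#' at 100 across network sizes, as in the scaling ladder this network
#' belongs to, so that nearly every neuron participates in several groups
#' and the global mean weight is a fair baseline for any single group.
#'
#' @param n_total Total neuron count; must be a multiple of 20 and >= 40.
#' @param seed Connectivity seed (connectivity and group membership).
#' @param n_groups Number of stimulus groups.
#' @param connection_probability Bernoulli connection probability.
#' @param initial_weight Initial plastic weight in nA.
#' @param inhibitory_weight Magnitude of the static inhibitory weight in nA
#'   (stored negative).
#' @param w_max Upper plastic-weight bound in nA (`w_min` is 0).
#' @param noise_weight Weight of the per-neuron 10 Hz Poisson noise synapse
#'   in nA.
#' @param noise_rate Noise rate in Hz.
#' @param d_c Dopamine increment per reward spike.
#' @return An object of class `conditioning_network`: a list with the
#'   realised `synapses` table, `groups`, population sizes and all
#'   parameters.
#' @export
build_conditioning_network <- function(n_total = 200, seed = 1,
                                       n_groups = 100L,
                                       connection_probability = 0.1,
                                       initial_weight = 1.5,
                                       inhibitory_weight = 10.0,
                                       w_max = 3.0,
                                       noise_weight = 0.7,
                                       noise_rate = 10,
                                       d_c = 0.002) {
  if (!is.numeric(n_total) || n_total < 40 || n_total %% 20 != 0)
    stop("'n_total' must be a multiple of 20, at least 40")
  n_total <- as.integer(n_total)
  n_exc <- as.integer(round(0.8 * n_total))
  n_groups <- as.integer(n_groups)
  group_size <- n_total %/% 20L
  set.seed(seed)
  pre <- integer(0); post <- integer(0)
  for (i in seq_len(n_total)) {
    tgt <- which(stats::runif(n_total) < connection_probability)
    tgt <- tgt[tgt != i]
    pre <- c(pre, rep.int(i, length(tgt)))
    post <- c(post, tgt)
  }
  plastic <- pre <= n_exc
  synapses <- data.frame(
    pre = pre, post = post,
    weight = ifelse(plastic, initial_weight, -inhibitory_weight),
    delay = 1L,
    kind = ifelse(plastic, "neuromod", "inhibitory"))
  groups <- lapply(seq_len(n_groups), function(g) sort(sample(n_total, group_size)))
  structure(list(n_total = n_total, n_exc = n_exc, n_groups = n_groups,
                 group_size = group_size, synapses = synapses, groups = groups,
                 connection_probability = connection_probability,
                 initial_weight = initial_weight,
                 inhibitory_weight = inhibitory_weight, w_max = w_max,
                 noise_weight = noise_weight, noise_rate = noise_rate,
                 d_c = d_c, seed = seed),
            class = "conditioning_network")
}

#' Generate the conditioning stimulus/reward schedule
#'
#' A continuous stream of stimuli: at each event one of the `n_groups`
#' stimulus groups is chosen uniformly at random, with inter-stimulus
#' intervals uniform in [100, 300] ms. Every presentation of the rewarded
#' group (`S_1` by default) is followed by exactly one dopamine reward at a
#' delay uniform in (0, 1000] ms — long enough for a few distractor stimuli
#' to intervene. Setting `reward_group = NA` decorrelates the reward from
#' the stimulus stream (each presentation rewarded with probability
#' `1 / n_groups`), the control in which no group should separate.
#'
#' @param n_groups Number of stimulus groups.
#' @param duration Schedule duration in ms.
#' @param seed RNG seed.
#' @param min_interval,max_interval Inter-stimulus interval bounds in ms.
#' @param reward_max_delay Maximum reward delay in ms.
#' @param reward_group Index of the rewarded group, or `NA` for the
#'   decorrelated control.
#' @return A list with `stimuli` (data frame `time`, `group`) and `rewards`
#'   (data frame `time`).
#' @export
stimulus_schedule <- function(n_groups, duration, seed = 1,
                              min_interval = 100, max_interval = 300,
                              reward_max_delay = 1000, reward_group = 1L) {
  set.seed(seed)
  times <- integer(0); groups <- integer(0); rewards <- integer(0)
  t <- 0
  repeat {
    t <- t + floor(stats::runif(1, min_interval, max_interval + 1))
    if (t > duration) break
    g <- sample.int(n_groups, 1L)
    times <- c(times, t); groups <- c(groups, g)
    rewarded <- if (is.na(reward_group)) stats::runif(1) < 1 / n_groups
                else g == reward_group
    if (rewarded)
      rewards <- c(rewards, t + ceiling(stats::runif(1, 0, reward_max_delay)))
  }
  list(stimuli = data.frame(time = times, group = groups),
       rewards = data.frame(time = rewards))
}

#' Run the Pavlovian-conditioning experiment
#'
#' Streams random group stimuli into the network built by
#' [build_conditioning_network()], rewards presentations of `S_1` with a
#' delayed dopaminergic spike, and logs the mean plastic weight of synapses
#' originating in the `S_1` group against the mean over all plastic
#' synapses. Eligibility traces tag the synapses active around each
#' stimulus; because `S_1`-outgoing synapses are tagged at every rewarded
#' presentation while other groups are tagged only by coincidence, their
#' mean weight separates upward.
#'
#' @param network A [build_conditioning_network()] result.
#' @param duration Simulated duration in ms.
#' @param seed Seed for the stimulus stream; the noise stream uses
#'   `seed + 1`.
#' @param reward_group Rewarded group index, or `NA` for the decorrelated
#'   control schedule.
#' @param snapshot_interval Weight-logging cadence in ms.
#' @param pair_cfg A [pair_stdp_config()].
#' @param stimulus_amplitude Pulse current in nA; defaults to 1.2x the
#'   minimum super-threshold amplitude for the excitatory cell.
#' @return A list with `summary` (data frame `time_ms`, `group_mean_nA`,
#'   `global_mean_nA`), `spikes`, final `weights`, the `schedule` and the
#'   `network`.
#' @export
run_conditioning <- function(network, duration = 60000, seed = 1,
                             reward_group = 1L, snapshot_interval = 1000,
                             pair_cfg = pair_stdp_config(),
                             stimulus_amplitude = NULL) {
  stopifnot(inherits(network, "conditioning_network"))
  n <- network$n_total
  rs <- lif_params_rs()
  fs <- lif_params_fs()
  if (is.null(stimulus_amplitude))
    stimulus_amplitude <- super_threshold_amplitude(rs)
  nm_cfg <- neuromod_config(tau_c = 1000, tau_d = 200, w_min = 0,
                            w_max = network$w_max)
  schedule <- stimulus_schedule(network$n_groups, duration, seed = seed,
                                reward_group = reward_group)

  # layout: 1..n LIF pool, n+1..2n Poisson noise, 2n+1 dopamine source
  neurons <- data.frame(
    type = c(rep("lif", n), rep("poisson", n), "scripted"),
    rate = c(rep(0, n), rep(network$noise_rate, n), 0))
  lifs <- c(lapply(seq_len(n), function(i) if (i <= network$n_exc) rs else fs),
            rep(list(rs), n + 1L))
  reward_times <- sort(unique(schedule$rewards$time))
  reward_times <- reward_times[reward_times <= duration]
  scripted <- c(rep(list(integer(0)), 2L * n), list(as.integer(reward_times)))

  synapses <- rbind(
    network$synapses,
    data.frame(pre = n + seq_len(n), post = seq_len(n),
               weight = network$noise_weight, delay = 1L, kind = "excitatory"),
    data.frame(pre = 2L * n + 1L, post = seq_len(n),
               weight = network$d_c, delay = 1L, kind = "dopaminergic"))

  stim <- do.call(rbind, lapply(seq_len(nrow(schedule$stimuli)), function(k)
    inject_pulse(network$groups[[schedule$stimuli$group[k]]],
                 schedule$stimuli$time[k], stimulus_amplitude)))

  snapshot_times <- seq(snapshot_interval, duration, by = snapshot_interval)
  set.seed(seed + 1L)
  res <- run_network(neurons, lifs, scripted, synapses, pair_cfg, nm_cfg,
                     stim = stim, duration = duration,
                     snapshot_times = snapshot_times)

  plastic_rows <- res$plastic_index        # rows of `synapses` that are plastic
  pre_of_plastic <- synapses$pre[plastic_rows]
  in_group <- pre_of_plastic %in% network$groups[[if (is.na(reward_group)) 1L else reward_group]]
  summary <- data.frame(
    time_ms = res$snapshot_times,
    group_mean_nA = apply(res$snapshots, 1, function(w) mean(w[in_group])),
    global_mean_nA = rowMeans(res$snapshots))
  spikes <- res$spikes[res$spikes$neuron <= n, , drop = FALSE]
  list(summary = summary, spikes = spikes, weights = res$weights,
       eligibility = res$eligibility, plastic_pre = pre_of_plastic,
       schedule = schedule, network = network)
}

#' Summarise plastic weights by stimulus-group membership
#'
#' @param network A [build_conditioning_network()] result.
#' @param weights Plastic weight vector, aligned with `plastic_pre`.
#' @param plastic_pre Pre-neuron index of each plastic synapse.
#' @param group Stimulus-group index.
#' @return A list with `group_mean`, `global_mean` and the per-synapse
#'   `snapshot` (weights of the group's outgoing synapses).
#' @export
summarize_weights <- function(network, weights, plastic_pre, group = 1L) {
  sel <- plastic_pre %in% network$groups[[group]]
  list(group_mean = mean(weights[sel]), global_mean = mean(weights),
       snapshot = weights[sel])
}
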