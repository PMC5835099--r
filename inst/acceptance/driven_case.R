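# Random driven networks where all pre-, post- and dopaminergic spike
# trains are prescribed, plus runners for the three implementations
# (compiled engine, R event engine, dense clock-driven oracle). Shared by
# the test-suite and scripts/acceptance.R.

random_driven_case <- function(seed, n_pre = 5, n_post = 5, duration = 2000,
                               pre_rate = 20, post_rate = 15, n_dopamine = 10,
                               d_c_range = c(-0.1, 0.1),
                               tau_c = 300, tau_d = 50,
                               w_min = -Inf, w_max = Inf) {
  set.seed(seed)
  post_ids <- n_pre + seq_len(n_post)
  syn <- expand.grid(pre = seq_len(n_pre), post = post_ids)
  syn <- syn[stats::runif(nrow(syn)) < 0.7, , drop = FALSE]
  syn$weight <- stats::runif(nrow(syn), 0.5, 2)
  syn$delay <- 1L
  rownames(syn) <- NULL
  rspk <- function(rate) {
    n <- stats::rpois(1, rate * duration / 1000)
    sort(sample.int(duration, min(n, duration)))
  }
  pre_spikes <- lapply(seq_len(n_pre), function(i) rspk(pre_rate))
  post_spikes <- c(rep(list(integer(0)), n_pre),
                   lapply(seq_len(n_post), function(i) rspk(post_rate)))
  dopamine <- data.frame(
    time = sort(sample.int(duration, n_dopamine)),
    target = sample(post_ids, n_dopamine, replace = TRUE),
    d_c = stats::runif(n_dopamine, d_c_range[1], d_c_range[2]))
  list(synapses = syn, pre_spikes = pre_spikes, post_spikes = post_spikes,
       dopamine = dopamine, duration = duration,
       pair_cfg = pair_stdp_config(),
       nm_cfg = neuromod_config(tau_c = tau_c, tau_d = tau_d,
                                w_min = w_min, w_max = w_max))
}

# Run a driven case through the compiled engine: pre and post neurons are
# scripted spike sources, and each dopaminergic event gets its own scripted
# source so arbitrary per-event increments are representable.
run_driven_compiled <- function(case) {
  n_pp <- length(case$post_spikes)
  n_ev <- nrow(case$dopamine)
  neurons <- data.frame(type = rep("scripted", n_pp + n_ev))
  scripted <- c(lapply(seq_len(n_pp), function(i) {
    pre <- if (i <= length(case$pre_spikes)) case$pre_spikes[[i]] else integer(0)
    sort(unique(c(pre, case$post_spikes[[i]])))
  }), lapply(seq_len(n_ev), function(k) case$dopamine$time[k]))
  syn <- case$synapses
  syn$kind <- "neuromod"
  allsyn <- syn[, c("pre", "post", "weight", "delay", "kind")]
  if (n_ev > 0) {
    dopa <- data.frame(pre = n_pp + seq_len(n_ev), post = case$dopamine$target,
                       weight = case$dopamine$d_c, delay = 1L,
                       kind = "dopaminergic")
    allsyn <- rbind(allsyn, dopa)
  }
  run_network(neurons, lif_params_rs(), scripted, allsyn,
              case$pair_cfg, case$nm_cfg, duration = case$duration,
              record_spikes = FALSE)
}

run_driven_r <- function(case, ...) {
  simulate_event_driven(case$synapses, case$pre_spikes, case$post_spikes,
                        case$dopamine, case$duration, case$pair_cfg,
                        case$nm_cfg, ...)
}

run_driven_dense <- function(case, ...) {
  simulate_dense(case$synapses, case$pre_spikes, case$post_spikes,
                 case$dopamine, case$duration, case$pair_cfg, case$nm_cfg, ...)
}

# Relative error with an absolute floor: quantities here (weights in nA,
# dimensionless traces) are O(1), so for |reference| below `floor` the
# comparison degrades gracefully to an absolute one instead of dividing by
# a value at the numerical noise level.
rel_err <- function(x, y, floor = 1e-3) {
  abs(x - y) / pmax(abs(y), floor)
}
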