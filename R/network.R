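# R-facing wrapper around the compiled network engine.

SYN_KINDS <- c(excitatory = 0L, inhibitory = 1L, neuromod = 2L, pair = 3L,
               dopaminergic = 4L)

#' Run a spiking network through the compiled event-driven engine
#'
#' Low-level entry point used by the experiment runners and the
#' equivalence test-suite. Neurons live in one index space and are LIF,
#' Poisson sources or scripted spike sources; synapses are static
#' (excitatory/inhibitory, delivered through the delay ring buffer), plastic
#' (`"neuromod"` three-factor or `"pair"` two-factor, processed lazily at
#' pre-spike times), or `"dopaminergic"` (the weight is the per-spike
#' dopamine increment `D_c`, written directly into the target's history).
#'
#' Poisson draws use R's RNG: call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param neurons Data frame with columns `type` (`"lif"`, `"poisson"`,
#'   `"scripted"`) and optionally `rate` (Hz, Poisson sources) and `v`
#'   (initial membrane potential, LIF).
#' @param lif_params_list List of [lif_params()], one per neuron (entries for
#'   non-LIF neurons are ignored); a single `lif_params` is recycled.
#' @param scripted List mapping neuron index to sorted integer spike times.
#' @param synapses Data frame with columns `pre`, `post`, `weight`, `kind`
#'   and optionally `delay` (default 1). Inhibitory weights are negative.
#' @param pair_cfg A [pair_stdp_config()].
#' @param nm_cfg A [neuromod_config()] (also carries the weight bounds used
#'   for per-row clamping).
#' @param stim Data frame with columns `time`, `neuron`, `amplitude`
#'   (external pulse currents), or `NULL`.
#' @param duration Simulated duration in ms.
#' @param max_delay Ring-buffer capacity in ms.
#' @param snapshot_times Integer times at which plastic weights are
#'   snapshotted (rows are flushed first, which is exact).
#' @param flush_at_end Flush all plastic rows to `duration` before reporting
#'   final weights (default `TRUE`).
#' @param record_spikes Record the spike raster (default `TRUE`).
#' @return A list: `spikes` (data frame `time`, `neuron`), `weights` and
#'   `eligibility` (aligned with the plastic rows of `synapses`, see
#'   `plastic_index`), `snapshots` (matrix, one row per snapshot time) and
#'   `snapshot_times`.
#' @export
run_network <- function(neurons, lif_params_list = lif_params_rs(),
                        scripted = list(), synapses,
                        pair_cfg = pair_stdp_config(),
                        nm_cfg = neuromod_config(), stim = NULL,
                        duration, max_delay = 16L,
                        snapshot_times = integer(0), flush_at_end = TRUE,
                        record_spikes = TRUE) {
  n <- nrow(neurons)
  type_code <- match(neurons$type, c("lif", "poisson", "scripted")) - 1L
  if (anyNA(type_code)) stop("neuron types must be 'lif', 'poisson' or 'scripted'")
  if (inherits(lif_params_list, "lif_params"))
    lif_params_list <- rep(list(lif_params_list), n)
  pm <- matrix(0, nrow = n, ncol = 9)
  for (i in seq_len(n)) {
    p <- lif_params_list[[min(i, length(lif_params_list))]]
    pm[i, ] <- c(p$c_m, p$i_offset, p$tau_m, p$tau_refrac, p$tau_syn_e,
                 p$tau_syn_i, p$v_reset, p$v_rest, p$v_thresh)
  }
  v_init <- if (!is.null(neurons$v)) as.numeric(neurons$v) else pm[, 8]
  rate <- if (!is.null(neurons$rate)) as.numeric(neurons$rate) else numeric(n)
  rate[is.na(rate)] <- 0
  scr <- lapply(seq_len(n), function(i)
    if (i <= length(scripted) && length(scripted[[i]]))
      as.integer(sort(scripted[[i]])) else integer(0))

  if (is.null(synapses$delay)) synapses$delay <- 1L
  kind <- SYN_KINDS[synapses$kind]
  if (anyNA(kind)) stop("unknown synapse kind")

  if (is.null(stim) || nrow(stim) == 0) {
    stim_m <- matrix(numeric(0), ncol = 3)
  } else {
    stim <- stim[stim$time >= 1 & stim$time <= duration, , drop = FALSE]
    stim <- stim[order(stim$time), , drop = FALSE]
    stim_m <- cbind(stim$time, stim$neuron, stim$amplitude)
  }
  snapshot_times <- sort(as.integer(snapshot_times))
  snapshot_times <- snapshot_times[snapshot_times >= 1 & snapshot_times <= duration]

  res <- .run_network_cpp(
    n, type_code, pm, v_init, rate, scr,
    as.integer(synapses$pre), as.integer(synapses$post),
    as.numeric(synapses$weight), as.integer(synapses$delay),
    as.integer(unname(kind)),
    list(a_plus = pair_cfg$a_plus, a_minus = pair_cfg$a_minus,
         tau_plus = pair_cfg$tau_plus, tau_minus = pair_cfg$tau_minus,
         tau_c = nm_cfg$tau_c, tau_d = nm_cfg$tau_d,
         w_min = nm_cfg$w_min, w_max = nm_cfg$w_max),
    stim_m, as.integer(duration), as.integer(max_delay),
    snapshot_times, flush_at_end, record_spikes)

  list(spikes = data.frame(time = res$spike_time, neuron = res$spike_neuron),
       plastic_index = res$plastic_index,
       weights = res$weights, eligibility = res$eligibility,
       snapshots = res$snapshots, snapshot_times = res$snapshot_times)
}
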