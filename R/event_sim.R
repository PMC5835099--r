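# Transparent R driver for the event-driven plasticity machinery: all spike
# trains are prescribed, and the simulator touches a synapse only at its
# pre-synaptic spike times (plus a final flush). This is the reference-grade
# counterpart of the compiled network engine and is convenient for
# single-synapse protocols and equivalence testing.

#' Run the event-driven plasticity engine on prescribed spike trains
#'
#' Pre-synaptic, post-synaptic and dopaminergic spike times are all given;
#' the engine maintains post-synaptic histories and processes each
#' pre-neuron's synaptic row lazily at its spike times. Within a timestep
#' the order is: dopaminergic deliveries, post-spike recordings, then row
#' processing; this makes dopamine entries precede post-spike entries at
#' equal times and applies the pre-spike depression last.
#'
#' @param synapses Data frame with columns `pre`, `post`, `weight` and
#'   optionally `delay` (default 1): the plastic synapses.
#' @param pre_spikes List mapping pre-neuron index to an integer vector of
#'   spike times (ms).
#' @param post_spikes List mapping post-neuron index to an integer vector of
#'   spike times (ms).
#' @param dopamine_events Data frame with columns `time`, `target`, `d_c`
#'   (one row per dopaminergic spike arrival), or `NULL` for none.
#' @param duration Simulated duration in ms; events beyond it are ignored.
#' @param pair_cfg A [pair_stdp_config()].
#' @param nm_cfg A [neuromod_config()].
#' @param mode `"neuromod"` (three-factor, default) or `"pair"`
#'   (weight-writing two-factor STDP).
#' @param flush_at_end Apply the pending dopamine-gated drift up to
#'   `duration` before reporting weights (default `TRUE`).
#' @return A list with `weights` and `eligibility` (in the row order of
#'   `synapses`), `t_old` per pre neuron, and the internal `rows` and
#'   `histories` for inspection or resumption.
#' @export
simulate_event_driven <- function(synapses, pre_spikes, post_spikes,
                                  dopamine_events = NULL, duration,
                                  pair_cfg = pair_stdp_config(),
                                  nm_cfg = neuromod_config(),
                                  mode = c("neuromod", "pair"),
                                  flush_at_end = TRUE) {
  mode <- match.arg(mode)
  if (is.null(synapses$delay)) synapses$delay <- 1L
  n_neurons <- max(synapses$pre, synapses$post, length(pre_spikes),
                   length(post_spikes),
                   if (!is.null(dopamine_events)) dopamine_events$target else 0L)
  histories <- lapply(seq_len(n_neurons), function(i)
    post_history(tau_post = pair_cfg$tau_minus, tau_d = nm_cfg$tau_d))

  pre_ids <- sort(unique(synapses$pre))
  rows <- lapply(pre_ids, function(i) {
    sel <- synapses$pre == i
    synaptic_row(i, synapses$post[sel], synapses$weight[sel], synapses$delay[sel])
  })
  names(rows) <- as.character(pre_ids)

  clip <- function(x) x[x >= 1 & x <= duration]
  events <- list()
  if (!is.null(dopamine_events) && nrow(dopamine_events) > 0) {
    keep <- dopamine_events$time >= 1 & dopamine_events$time <= duration
    da <- dopamine_events[keep, , drop = FALSE]
  } else {
    da <- data.frame(time = numeric(0), target = integer(0), d_c = numeric(0))
  }
  post_t <- lapply(seq_len(n_neurons), function(i)
    if (i <= length(post_spikes) && length(post_spikes[[i]])) clip(sort(post_spikes[[i]])) else numeric(0))
  pre_t <- lapply(seq_len(n_neurons), function(i)
    if (i <= length(pre_spikes) && length(pre_spikes[[i]])) clip(sort(pre_spikes[[i]])) else numeric(0))

  times <- sort(unique(c(da$time, unlist(post_t), unlist(pre_t))))
  process <- if (mode == "neuromod") process_row_neuromod else process_row_pair_stdp

  for (t in times) {
    hit <- which(da$time == t)
    for (k in hit)
      record_dopamine_spike(histories[[da$target[k]]], t, da$d_c[k])
    for (j in seq_len(n_neurons))
      if (length(post_t[[j]]) && any(post_t[[j]] == t))
        record_post_spike(histories[[j]], t)
    for (i in pre_ids)
      if (length(pre_t[[i]]) && any(pre_t[[i]] == t))
        process(rows[[as.character(i)]], t, histories, pair_cfg, nm_cfg)
  }
  if (flush_at_end && mode == "neuromod")
    for (r in rows) flush_row(r, duration, histories, pair_cfg, nm_cfg)

  # report in the input synapse order
  weights <- numeric(nrow(synapses))
  elig <- numeric(nrow(synapses))
  for (i in pre_ids) {
    sel <- which(synapses$pre == i)
    weights[sel] <- rows[[as.character(i)]]$weight
    elig[sel] <- rows[[as.character(i)]]$eligibility
  }
  list(weights = weights, eligibility = elig,
       t_old = vapply(rows, function(r) r$t_old, numeric(1)),
       rows = rows, histories = histories)
}
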