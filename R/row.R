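# Synaptic rows and lazy row processing. A row holds all outgoing synapses
# of one pre-synaptic neuron, the time t_old at which it was last processed
# and the pre trace s_i referenced at t_old. When the pre neuron spikes at t,
# the row replays everything that happened to its targets in (t_old, t] from
# the post-synaptic histories.

#' Create a synaptic row
#'
#' @param pre_index Index of the pre-synaptic neuron.
#' @param targets Integer vector of post-neuron indices.
#' @param weights Numeric vector of initial weights (nA).
#' @param delays Integer vector of delays in ms (>= 1); recycled.
#' @return An object of class `synaptic_row` (mutable reference object).
#' @export
synaptic_row <- function(pre_index, targets, weights, delays = 1L) {
  n <- length(targets)
  delays <- rep_len(as.integer(delays), n)
  if (n > 0 && any(delays < 1L)) stop("delays must be integer ms >= 1")
  row <- new.env(parent = emptyenv())
  row$pre_index <- pre_index
  row$t_old <- 0
  row$s_i <- 0
  row$target <- as.integer(targets)
  row$weight <- as.numeric(rep_len(weights, n))
  row$eligibility <- numeric(n)
  row$delay <- delays
  class(row) <- "synaptic_row"
  row
}

# Shared guts of neuromodulated row processing: advance one synapse's weight
# and eligibility from row$t_old to t by walking its target's history.
# Returns c(weight, eligibility) referenced at t (pre-spike depression not
# yet applied).
walk_neuromod <- function(w, C, h, t_old, t, pair_cfg, nm_cfg, s_i) {
  win <- get_history_entries(h, t_old, t)
  t_c <- t_old
  d_c <- if (is.null(win$preceding)) 0 else
    decay_trace(win$preceding$d, t_old - win$preceding$time, nm_cfg$tau_d)
  entries <- win$entries
  n <- nrow(entries)
  if (n > 0) {
    for (k in seq_len(n)) {
      t_j <- entries$time[k]
      w <- w + weight_delta(C, d_c, t_c, t_j, nm_cfg)
      C <- decay_trace(C, t_j - t_c, nm_cfg$tau_c)
      if (entries$type[k] != "dopamine") {
        C <- apply_post_spike(C, t_j, trace_state(s_i, t_old), pair_cfg)
      }
      d_c <- entries$d[k]
      t_c <- t_j
    }
  }
  w <- w + weight_delta(C, d_c, t_c, t, nm_cfg)
  C <- decay_trace(C, t - t_c, nm_cfg$tau_c)
  c(w, C)
}

#' Process a synaptic row under the three-factor rule
#'
#' Called when the row's pre-synaptic neuron spikes at time `t`. For each
#' synapse, walks the target's history entries in `(t_old, t]` maintaining a
#' running reference time and the dopamine concentration decayed to it:
#' at each entry the weight is advanced by the closed-form integral of
#' `C * D`, the eligibility trace is decayed, post spikes potentiate the
#' eligibility by sampling the pre trace, and dopamine entries update the
#' running concentration. After the final segment up to `t` the pre spike's
#' depression is applied to the eligibility, the weight is clamped and
#' deposited into the ring buffer, and finally the pre trace is incremented
#' and `t_old` set to `t`.
#'
#' @param row A [synaptic_row()].
#' @param t Pre-spike time in ms, strictly greater than `row$t_old`.
#' @param histories List of [post_history()] objects indexed by neuron.
#' @param pair_cfg A [pair_stdp_config()].
#' @param nm_cfg A [neuromod_config()].
#' @param rb Optional [ring_buffer()] to receive the updated weights.
#' @return `row`, invisibly (modified in place).
#' @export
process_row_neuromod <- function(row, t, histories, pair_cfg, nm_cfg, rb = NULL) {
  if (t <= row$t_old) stop("row already processed at or after 't'")
  for (s in seq_along(row$target)) {
    h <- histories[[row$target[s]]]
    wc <- walk_neuromod(row$weight[s], row$eligibility[s], h,
                        row$t_old, t, pair_cfg, nm_cfg, row$s_i)
    w <- wc[1]
    C <- apply_pre_spike(wc[2], t, trace_state(post_trace_at(h, t), t), pair_cfg)
    w <- clamp_weight(w, nm_cfg)
    if (!is.null(rb))
      add_weight_to_ring_buffer(rb, w, row$target[s], row$delay[s], t)
    row$weight[s] <- w
    row$eligibility[s] <- C
  }
  row$s_i <- decay_trace(row$s_i, t - row$t_old, pair_cfg$tau_plus) + 1
  row$t_old <- t
  invisible(row)
}

#' Process a synaptic row under plain pair-based STDP
#'
#' Two-factor mode: potentiation and depression act directly on the synaptic
#' weight. Every post-spike entry in `(t_old, t]` potentiates the weight by
#' sampling the pre trace; the pre spike at `t` then depresses it by
#' sampling the post trace; the weight is clamped and deposited into the
#' ring buffer. Dopamine entries, if any, are ignored in this mode.
#'
#' @inheritParams process_row_neuromod
#' @return `row`, invisibly (modified in place).
#' @export
process_row_pair_stdp <- function(row, t, histories, pair_cfg, nm_cfg, rb = NULL) {
  if (t <= row$t_old) stop("row already processed at or after 't'")
  for (s in seq_along(row$target)) {
    h <- histories[[row$target[s]]]
    win <- get_history_entries(h, row$t_old, t)
    w <- row$weight[s]
    entries <- win$entries
    if (nrow(entries) > 0) {
      for (k in seq_len(nrow(entries))) {
        if (entries$type[k] != "dopamine")
          w <- apply_post_spike(w, entries$time[k],
                                trace_state(row$s_i, row$t_old), pair_cfg)
      }
    }
    w <- apply_pre_spike(w, t, trace_state(post_trace_at(h, t), t), pair_cfg)
    w <- clamp_weight(w, nm_cfg)
    if (!is.null(rb))
      add_weight_to_ring_buffer(rb, w, row$target[s], row$delay[s], t)
    row$weight[s] <- w
  }
  row$s_i <- decay_trace(row$s_i, t - row$t_old, pair_cfg$tau_plus) + 1
  row$t_old <- t
  invisible(row)
}

#' Flush a synaptic row to a common time without a pre spike
#'
#' Applies the pending dopamine-gated weight drift and eligibility decay of
#' [process_row_neuromod()] up to time `t`, but without the pre-spike
#' depression, pre-trace increment or ring-buffer deposit. Because the
#' closed-form segments compose exactly, flushing at an intermediate time
#' and continuing later is equivalent to processing the whole interval at
#' once. Used to report weights at checkpoints and at simulation end.
#'
#' @param row A [synaptic_row()].
#' @param t Flush time in ms, `t >= row$t_old` (equal is a no-op).
#' @param histories List of [post_history()] objects indexed by neuron.
#' @param pair_cfg A [pair_stdp_config()].
#' @param nm_cfg A [neuromod_config()].
#' @return `row`, invisibly (modified in place).
#' @export
flush_row <- function(row, t, histories, pair_cfg, nm_cfg) {
  if (t < row$t_old) stop("cannot flush a row backwards in time")
  if (t == row$t_old) return(invisible(row))
  for (s in seq_along(row$target)) {
    h <- histories[[row$target[s]]]
    wc <- walk_neuromod(row$weight[s], row$eligibility[s], h,
                        row$t_old, t, pair_cfg, nm_cfg, row$s_i)
    row$weight[s] <- clamp_weight(wc[1], nm_cfg)
    row$eligibility[s] <- wc[2]
  }
  row$s_i <- decay_trace(row$s_i, t - row$t_old, pair_cfg$tau_plus)
  row$t_old <- t
  invisible(row)
}
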