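# Delay ring buffer: circular per-neuron input accumulators indexed by
# (timestep mod (max_delay + 1)). Weights deposited during row processing at
# time t with delay d are consumed as input current at step t + d.
# Excitatory and inhibitory contributions are kept separate because they
# feed synaptic currents with distinct decay constants.

#' Create a delay ring buffer
#'
#' @param n_neurons Number of neurons receiving input.
#' @param max_delay Largest supported synaptic delay in ms.
#' @return An object of class `ring_buffer` (mutable reference object with
#'   the current time initialised to 0).
#' @export
ring_buffer <- function(n_neurons, max_delay = 16) {
  if (max_delay < 1) stop("'max_delay' must be at least 1")
  rb <- new.env(parent = emptyenv())
  rb$n_neurons <- as.integer(n_neurons)
  rb$max_delay <- as.integer(max_delay)
  rb$size <- as.integer(max_delay + 1L)
  rb$exc <- matrix(0, nrow = n_neurons, ncol = max_delay + 1L)
  rb$inh <- matrix(0, nrow = n_neurons, ncol = max_delay + 1L)
  rb$t <- 0L
  class(rb) <- "ring_buffer"
  rb
}

#' Deposit a synaptic weight into the ring buffer
#'
#' Accumulates `w` into `target`'s input slot for step `t + delay`.
#' Dopaminergic spikes never pass through this operation; they are written
#' directly into the post-synaptic history instead.
#'
#' @param rb A [ring_buffer()].
#' @param w Weight in nA (sign as stored; inhibitory projections use
#'   `inhibitory = TRUE`).
#' @param target Post-neuron index (1-based).
#' @param delay Integer delay in ms, `1 <= delay <= max_delay`.
#' @param t Current time in ms (the processing time of the row).
#' @param inhibitory Route into the inhibitory accumulator.
#' @return `rb`, invisibly (modified in place).
#' @export
add_weight_to_ring_buffer <- function(rb, w, target, delay, t, inhibitory = FALSE) {
  if (delay < 1 || delay > rb$max_delay)
    stop(sprintf("'delay' must be in [1, %d]", rb$max_delay))
  slot <- ((t + delay) %% rb$size) + 1L
  if (inhibitory) {
    rb$inh[target, slot] <- rb$inh[target, slot] + w
  } else {
    rb$exc[target, slot] <- rb$exc[target, slot] + w
  }
  invisible(rb)
}

#' Advance the ring buffer by one timestep
#'
#' Moves the buffer's clock from `t` to `t + 1` and returns the accumulated
#' input for step `t + 1`, zeroing the slot so it can be reused
#' `max_delay + 1` steps later.
#'
#' @param rb A [ring_buffer()].
#' @return A list with numeric vectors `exc` and `inh` (per-neuron input for
#'   the new timestep, nA) and the new time `t`.
#' @export
advance_timestep <- function(rb) {
  rb$t <- rb$t + 1L
  slot <- (rb$t %% rb$size) + 1L
  out <- list(exc = rb$exc[, slot], inh = rb$inh[, slot], t = rb$t)
  rb$exc[, slot] <- 0
  rb$inh[, slot] <- 0
  out
}
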