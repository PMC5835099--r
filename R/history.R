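# Post-synaptic event histories. Each plasticity-target neuron keeps a
# time-ordered record of its post-synaptic spikes and of incoming
# dopaminergic spikes; every entry stores the post trace s_j and the dopamine
# concentration D_j valid at its time, so a synaptic row processed long after
# the fact can replay the interval exactly.

#' Create an empty post-synaptic event history
#'
#' Holds timestamped entries of two kinds: `post_spike` (the neuron fired;
#' its post trace is decayed and incremented by one, dopamine carried forward
#' decayed) and `dopamine` (a dopaminergic spike arrived; the dopamine
#' concentration is decayed and incremented by `d_c`, the post trace carried
#' forward decayed). Dopaminergic spikes bypass the ring buffer entirely and
#' are written straight into this structure. The history is a mutable
#' reference object: the `record_*` functions update it in place and return
#' it invisibly.
#'
#' @param tau_post Decay time constant of the post trace `s_j` in ms
#'   (the STDP `tau_minus`).
#' @param tau_d Dopamine re-absorption time constant in ms.
#' @return An object of class `post_history`.
#' @export
post_history <- function(tau_post = 12, tau_d = 200) {
  h <- new.env(parent = emptyenv())
  h$time <- numeric(0)
  h$s <- numeric(0)
  h$d <- numeric(0)
  h$type <- character(0)
  h$tau_post <- tau_post
  h$tau_d <- tau_d
  class(h) <- "post_history"
  h
}

history_last_time <- function(h) {
  n <- length(h$time)
  if (n == 0L) -Inf else h$time[n]
}

#' Record a post-synaptic spike in a history
#'
#' Appends an entry at time `t` with the post trace decayed to `t` and
#' incremented by one, and the dopamine concentration decayed to `t`.
#' Entries must be appended in time order; at equal times a dopamine entry
#' must precede the post-spike entry, so recording a post spike at the time
#' of an existing post spike, or before the latest entry, is an error.
#'
#' @param h A [post_history()].
#' @param t Spike time in ms.
#' @return `h`, invisibly (modified in place).
#' @export
record_post_spike <- function(h, t) {
  n <- length(h$time)
  if (n > 0L) {
    if (t < h$time[n])
      stop("out-of-order insertion: post spike earlier than latest history entry")
    if (t == h$time[n] && h$type[n] == "post_spike")
      stop("duplicate post spike at the same timestamp")
  }
  if (n == 0L) {
    s <- 1
    d <- 0
  } else {
    dt <- t - h$time[n]
    s <- decay_trace(h$s[n], dt, h$tau_post) + 1
    d <- decay_trace(h$d[n], dt, h$tau_d)
  }
  h$time <- c(h$time, t)
  h$s <- c(h$s, s)
  h$d <- c(h$d, d)
  h$type <- c(h$type, "post_spike")
  invisible(h)
}

#' Record an incoming dopaminergic spike in a history
#'
#' Appends an entry at time `t` with the dopamine concentration decayed to
#' `t` and incremented by `d_c` (negative `d_c` encodes punishment), and the
#' post trace carried forward decayed. At equal times dopamine entries must
#' precede post-spike entries, so appending after a post spike at the same
#' `t` is an error; several dopamine entries may share a timestamp.
#'
#' @param h A [post_history()].
#' @param t Arrival time in ms.
#' @param d_c Dopamine increment per spike (may be negative).
#' @return `h`, invisibly (modified in place).
#' @export
record_dopamine_spike <- function(h, t, d_c) {
  n <- length(h$time)
  if (n > 0L) {
    if (t < h$time[n])
      stop("out-of-order insertion: dopamine spike earlier than latest history entry")
    if (t == h$time[n] && h$type[n] == "post_spike")
      stop("tie-order violation: dopamine entries precede post spikes at equal times")
  }
  if (n == 0L) {
    s <- 0
    d <- d_c
  } else {
    dt <- t - h$time[n]
    s <- decay_trace(h$s[n], dt, h$tau_post)
    d <- decay_trace(h$d[n], dt, h$tau_d) + d_c
  }
  h$time <- c(h$time, t)
  h$s <- c(h$s, s)
  h$d <- c(h$d, d)
  h$type <- c(h$type, "dopamine")
  invisible(h)
}

#' Retrieve history entries in a processing window
#'
#' Returns the entries with `t_old < time <= t` (half-open left, closed
#' right), in order, together with the entry immediately at or before
#' `t_old` (the "preceding" entry) from which the dopamine level at the
#' window start can be reconstructed.
#'
#' @param h A [post_history()].
#' @param t_old,t Window bounds in ms, `t_old <= t`.
#' @return A list with `entries` (a data frame with columns `time`, `s`,
#'   `d`, `type`; zero rows if none fall in the window) and `preceding`
#'   (a one-row data frame, or `NULL` if no entry exists at or before
#'   `t_old`).
#' @export
get_history_entries <- function(h, t_old, t) {
  if (t_old > t) stop("'t_old' must not exceed 't'")
  idx <- which(h$time > t_old & h$time <= t)
  entries <- data.frame(time = h$time[idx], s = h$s[idx], d = h$d[idx],
                        type = h$type[idx], stringsAsFactors = FALSE)
  prev <- which(h$time <= t_old)
  preceding <- if (length(prev) == 0L) NULL else {
    i <- prev[length(prev)]
    data.frame(time = h$time[i], s = h$s[i], d = h$d[i], type = h$type[i],
               stringsAsFactors = FALSE)
  }
  list(entries = entries, preceding = preceding)
}

# Post trace value at time t, honouring the simultaneity rule: a spike never
# pairs with a simultaneous partner spike, so a post-spike entry at exactly t
# contributes its trace value minus its own +1 increment.
post_trace_at <- function(h, t) {
  idx <- which(h$time <= t)
  if (length(idx) == 0L) return(0)
  i <- idx[length(idx)]
  s <- h$s[i]
  if (h$time[i] == t && h$type[i] == "post_spike") s <- s - 1
  decay_trace(s, t - h$time[i], h$tau_post)
}

# Dopamine concentration at time t (after any dopaminergic events <= t).
dopamine_at <- function(h, t) {
  idx <- which(h$time <= t)
  if (length(idx) == 0L) return(0)
  i <- idx[length(idx)]
  decay_trace(h$d[i], t - h$time[i], h$tau_d)
}
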