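# Pure plasticity mathematics: exponential traces, pair-based STDP applied to
# the eligibility trace, and the closed-form integrated weight update for the
# dopamine-gated rule dW/dt = C * D.

#' Pair-based STDP configuration
#'
#' Amplitudes and time constants of the exponential STDP window. A causal
#' pre-before-post pair separated by `dt` potentiates by
#' `a_plus * exp(-dt / tau_plus)`; an anti-causal pair depresses by
#' `a_minus * exp(-dt / tau_minus)`. Defaults are the parameter set used by
#' the bundled experiments (A+ = A- = 1, tau+ = 10 ms, tau- = 12 ms).
#'
#' @param a_plus,a_minus Dimensionless potentiation / depression amplitudes.
#' @param tau_plus,tau_minus Trace decay time constants in ms. `tau_plus`
#'   governs the pre-synaptic trace (sampled at post-spike times),
#'   `tau_minus` the post-synaptic trace (sampled at pre-spike times).
#' @return An object of class `pair_stdp_config`.
#' @export
pair_stdp_config <- function(a_plus = 1, a_minus = 1, tau_plus = 10, tau_minus = 12) {
  for (nm in c("a_plus", "a_minus", "tau_plus", "tau_minus")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single strictly positive number", nm))
  }
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus),
            class = "pair_stdp_config")
}

#' Neuromodulation configuration
#'
#' Time constants of the eligibility trace and of dopamine re-absorption,
#' plus the weight bounds applied after each row processing. The additive
#' weight rule needs explicit bounds; `w_min = 0` keeps excitatory weights
#' non-negative and `w_max` defaults to `Inf` (unbounded) so that single-pair
#' protocols show the pure closed-form response. Network experiments set a
#' finite `w_max` per projection.
#'
#' @param tau_c Eligibility-trace decay time constant in ms.
#' @param tau_d Dopamine re-absorption time constant in ms.
#' @param w_min,w_max Weight bounds (nA for current-based synapses).
#' @return An object of class `neuromod_config`.
#' @export
neuromod_config <- function(tau_c = 1000, tau_d = 200, w_min = 0, w_max = Inf) {
  if (!is.numeric(tau_c) || length(tau_c) != 1L || !is.finite(tau_c) || tau_c <= 0)
    stop("'tau_c' must be a single strictly positive number")
  if (!is.numeric(tau_d) || length(tau_d) != 1L || !is.finite(tau_d) || tau_d <= 0)
    stop("'tau_d' must be a single strictly positive number")
  if (!is.numeric(w_min) || !is.numeric(w_max) || length(w_min) != 1L ||
      length(w_max) != 1L || is.na(w_min) || is.na(w_max) || w_min >= w_max)
    stop("weight bounds must satisfy w_min < w_max")
  structure(list(tau_c = tau_c, tau_d = tau_d, w_min = w_min, w_max = w_max),
            class = "neuromod_config")
}

#' Exponentially decaying trace state
#'
#' A trace is a value together with the time at which that value was last
#' referenced; between events it decays as `value * exp(-elapsed / tau)`.
#'
#' @param value Trace level (dimensionless).
#' @param last_update Time in ms at which `value` is referenced.
#' @return An object of class `trace_state`.
#' @export
trace_state <- function(value = 0, last_update = 0) {
  structure(list(value = value, last_update = last_update), class = "trace_state")
}

#' Decay a trace value over an elapsed interval
#'
#' @param value Trace level at the start of the interval.
#' @param elapsed Interval length in ms (non-negative).
#' @param tau Decay time constant in ms (strictly positive).
#' @return `value * exp(-elapsed / tau)`. Vectorised over all arguments.
#' @export
decay_trace <- function(value, elapsed, tau) {
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("'tau' must be strictly positive")
  if (any(is.na(elapsed)) || any(elapsed < 0))
    stop("'elapsed' must be non-negative")
  value * exp(-elapsed / tau)
}

#' Apply the effect of a post-synaptic spike to an eligibility trace
#'
#' Potentiation: at a post-spike time the pre-synaptic trace is sampled
#' (decayed to `t_post`) and added to the eligibility trace scaled by
#' `a_plus`. The pre trace itself is not modified.
#'
#' @param eligibility Current eligibility trace value `C`.
#' @param t_post Post-spike time in ms; must not precede the pre trace's
#'   reference time.
#' @param pre_trace A [trace_state()] holding the pre-synaptic trace `s_i`.
#' @param cfg A [pair_stdp_config()].
#' @return The updated eligibility value.
#' @export
apply_post_spike <- function(eligibility, t_post, pre_trace, cfg) {
  if (t_post < pre_trace$last_update)
    stop("'t_post' precedes the pre trace's reference time")
  eligibility + cfg$a_plus *
    decay_trace(pre_trace$value, t_post - pre_trace$last_update, cfg$tau_plus)
}

#' Apply the effect of a pre-synaptic spike to an eligibility trace
#'
#' Depression: at a pre-spike time the post-synaptic trace is sampled
#' (decayed to `t_pre`) and subtracted from the eligibility trace scaled by
#' `a_minus`. The post trace itself is not modified.
#'
#' @param eligibility Current eligibility trace value `C`.
#' @param t_pre Pre-spike time in ms; must not precede the post trace's
#'   reference time.
#' @param post_trace A [trace_state()] holding the post-synaptic trace `s_j`.
#' @param cfg A [pair_stdp_config()].
#' @return The updated eligibility value.
#' @export
apply_pre_spike <- function(eligibility, t_pre, post_trace, cfg) {
  if (t_pre < post_trace$last_update)
    stop("'t_pre' precedes the post trace's reference time")
  eligibility - cfg$a_minus *
    decay_trace(post_trace$value, t_pre - post_trace$last_update, cfg$tau_minus)
}

#' Closed-form weight change over an event-free interval
#'
#' Integrates `dW/dt = C(t) * D(t)` from `t_ref` to `t` where both the
#' eligibility trace and the dopamine concentration decay exponentially from
#' their values at the common reference time `t_ref`:
#' \deqn{\Delta w = \frac{C D}{-(1/\tau_c + 1/\tau_d)}
#'   \left(e^{-(t - t_{ref})/\tau_c} e^{-(t - t_{ref})/\tau_d} - 1\right).}
#' No spike or dopaminergic event may occur inside the interval.
#'
#' @param c_ref Eligibility trace value at `t_ref`.
#' @param d_ref Dopamine concentration at `t_ref` (may be negative).
#' @param t_ref,t Interval bounds in ms, `t >= t_ref`.
#' @param cfg A [neuromod_config()].
#' @return The weight change over `[t_ref, t]`.
#' @export
weight_delta <- function(c_ref, d_ref, t_ref, t, cfg) {
  if (any(t < t_ref)) stop("'t' must not precede 't_ref'")
  inv <- 1 / cfg$tau_c + 1 / cfg$tau_d
  c_ref * d_ref / (-inv) * (exp(-(t - t_ref) * inv) - 1)
}

#' Closed-form weight change with staggered trace reference times
#'
#' General form of [weight_delta()] in which the eligibility trace is
#' referenced at `t_c_last` and the dopamine concentration at `t_d_last`,
#' both at or before the start of the integration interval `t_last`:
#' \deqn{\Delta w = \frac{C(t_c^{last}) D(t_d^{last})}{-(1/\tau_c + 1/\tau_d)}
#'   \left(e^{-(t - t_c^{last})/\tau_c} e^{-(t - t_d^{last})/\tau_d}
#'       - e^{-(t_{last} - t_c^{last})/\tau_c}
#'         e^{-(t_{last} - t_d^{last})/\tau_d}\right).}
#' Reduces exactly to [weight_delta()] when
#' `t_c_last == t_d_last == t_last`.
#'
#' @param c_val Eligibility trace value at `t_c_last`.
#' @param t_c_last Reference time of the eligibility trace (ms).
#' @param d_val Dopamine concentration at `t_d_last`.
#' @param t_d_last Reference time of the dopamine trace (ms).
#' @param t_last,t Integration interval bounds in ms.
#' @param cfg A [neuromod_config()].
#' @return The weight change over `[t_last, t]`.
#' @export
weight_delta_general <- function(c_val, t_c_last, d_val, t_d_last, t_last, t, cfg) {
  if (any(t < t_last)) stop("'t' must not precede 't_last'")
  if (any(t_c_last > t_last) || any(t_d_last > t_last))
    stop("trace reference times must not exceed 't_last'")
  inv <- 1 / cfg$tau_c + 1 / cfg$tau_d
  c_val * d_val / (-inv) *
    (exp(-(t - t_c_last) / cfg$tau_c - (t - t_d_last) / cfg$tau_d) -
     exp(-(t_last - t_c_last) / cfg$tau_c - (t_last - t_d_last) / cfg$tau_d))
}

#' Clamp a weight to the configured bounds
#'
#' @param w Weight value(s).
#' @param cfg A [neuromod_config()] supplying `w_min` and `w_max`.
#' @return `min(max(w, w_min), w_max)`, vectorised.
#' @export
clamp_weight <- function(w, cfg) {
  pmin(pmax(w, cfg$w_min), cfg$w_max)
}
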