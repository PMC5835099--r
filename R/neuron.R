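# Current-based leaky integrate-and-fire neurons with exponential synaptic
# currents, plus Poisson spike sources and scripted pulse-current stimuli.
# Integration is exact per-step (exponential update on the 1 ms grid with
# piecewise-constant input), which keeps the dynamics deterministic and
# oracle-friendly.

#' Leaky integrate-and-fire parameters
#'
#' Current-based LIF with exponentially decaying synaptic currents.
#' `lif_params_rs()` and `lif_params_fs()` give the regular-spiking
#' (excitatory) and fast-spiking (inhibitory) parameter sets used by the
#' bundled network experiments; the two differ in offset current, refractory
#' period and threshold.
#'
#' @param c_m Membrane capacitance (nF).
#' @param i_offset Constant bias current (nA).
#' @param tau_m Membrane time constant (ms).
#' @param tau_refrac Refractory period (ms).
#' @param tau_syn_e,tau_syn_i Excitatory / inhibitory synaptic current decay
#'   constants (ms).
#' @param v_reset,v_rest,v_thresh Reset, resting and threshold potentials
#'   (mV); must satisfy `v_reset <= v_rest < v_thresh`.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(c_m = 0.3, i_offset = 0.005, tau_m = 10, tau_refrac = 4,
                       tau_syn_e = 1, tau_syn_i = 1, v_reset = -70,
                       v_rest = -65, v_thresh = -55.4) {
  if (tau_m <= 0 || c_m <= 0) stop("'tau_m' and 'c_m' must be strictly positive")
  if (!(v_reset <= v_rest && v_rest < v_thresh))
    stop("must have v_reset <= v_rest < v_thresh")
  structure(list(c_m = c_m, i_offset = i_offset, tau_m = tau_m,
                 tau_refrac = tau_refrac, tau_syn_e = tau_syn_e,
                 tau_syn_i = tau_syn_i, v_reset = v_reset, v_rest = v_rest,
                 v_thresh = v_thresh),
            class = "lif_params")
}

#' @rdname lif_params
#' @export
lif_params_rs <- function() lif_params()

#' @rdname lif_params
#' @export
lif_params_fs <- function() {
  lif_params(c_m = 0.3, i_offset = 0, tau_m = 10, tau_refrac = 2,
             tau_syn_e = 1, tau_syn_i = 1, v_reset = -70, v_rest = -65,
             v_thresh = -56.4)
}

#' Leaky integrate-and-fire dynamic state
#'
#' @param params A [lif_params()].
#' @param v Initial membrane potential (mV); defaults to `v_rest`.
#' @return A list with `v`, synaptic currents `i_syn_e`, `i_syn_i` (nA) and
#'   `refrac_remaining` (ms).
#' @export
lif_state <- function(params, v = params$v_rest) {
  list(v = v, i_syn_e = 0, i_syn_i = 0, refrac_remaining = 0)
}

#' Advance a LIF neuron by one 1 ms step
#'
#' Ring-buffer deposits are added to the respective synaptic currents, the
#' membrane is advanced by the exact exponential update for the
#' piecewise-constant total current
#' `i_syn_e + i_syn_i + i_offset + i_ext`, and the synaptic currents decay.
#' Crossing threshold emits a spike, resets the membrane to `v_reset` and
#' starts the refractory countdown, during which the membrane is held at
#' `v_reset` while synaptic currents keep accumulating and decaying.
#'
#' @param state A [lif_state()].
#' @param params A [lif_params()].
#' @param input_e Excitatory deposit for this step (nA, >= 0 by convention).
#' @param input_i Inhibitory deposit for this step (nA, negative values).
#' @param i_ext External (pulse) current applied this step only (nA).
#' @return A list with the updated `state` and logical `spiked`.
#' @export
lif_step <- function(state, params, input_e = 0, input_i = 0, i_ext = 0) {
  state$i_syn_e <- state$i_syn_e + input_e
  state$i_syn_i <- state$i_syn_i + input_i
  i_total <- state$i_syn_e + state$i_syn_i + params$i_offset + i_ext
  spiked <- FALSE
  if (state$refrac_remaining > 0) {
    state$refrac_remaining <- state$refrac_remaining - 1
    state$v <- params$v_reset
  } else {
    r_m <- params$tau_m / params$c_m
    v_inf <- params$v_rest + r_m * i_total
    state$v <- v_inf + (state$v - v_inf) * exp(-1 / params$tau_m)
    if (state$v >= params$v_thresh) {
      spiked <- TRUE
      state$v <- params$v_reset
      state$refrac_remaining <- params$tau_refrac
    }
  }
  state$i_syn_e <- state$i_syn_e * exp(-1 / params$tau_syn_e)
  state$i_syn_i <- state$i_syn_i * exp(-1 / params$tau_syn_i)
  list(state = state, spiked = spiked)
}

#' One step of a Poisson spike source
#'
#' Emits a spike with probability `1 - exp(-rate * dt / 1000)`; reproducible
#' under R's seeded RNG.
#'
#' @param rate Firing rate in Hz (non-negative).
#' @param dt Step length in ms.
#' @return Logical: did the source spike this step?
#' @export
poisson_step <- function(rate, dt = 1) {
  if (!is.numeric(rate) || any(rate < 0)) stop("'rate' must be non-negative")
  stats::runif(length(rate)) < -expm1(-rate * dt / 1000)
}

#' Minimum one-step super-threshold pulse amplitude
#'
#' Smallest constant current that lifts a resting neuron across threshold
#' within a single 1 ms step, times a safety factor. Used as the default
#' amplitude for scripted stimulus pulses.
#'
#' @param params A [lif_params()].
#' @param safety Multiplicative margin (default 1.2).
#' @return Amplitude in nA.
#' @export
super_threshold_amplitude <- function(params, safety = 1.2) {
  r_m <- params$tau_m / params$c_m
  gap <- params$v_thresh - params$v_rest
  safety * gap / (r_m * -expm1(-1 / params$tau_m)) - params$i_offset
}

#' Schedule a 1 ms super-threshold current pulse
#'
#' Builds stimulus rows (time, neuron, amplitude) that inject `amplitude`
#' into each listed neuron for `duration` consecutive 1 ms steps.
#'
#' @param neurons Integer vector of target neuron indices.
#' @param t Onset time in ms.
#' @param amplitude Pulse amplitude in nA.
#' @param duration Pulse length in ms (default 1).
#' @return A data frame with columns `time`, `neuron`, `amplitude`.
#' @export
inject_pulse <- function(neurons, t, amplitude, duration = 1) {
  steps <- rep(t + seq_len(duration) - 1L, each = length(neurons))
  data.frame(time = steps, neuron = rep(as.integer(neurons), duration),
             amplitude = amplitude)
}
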