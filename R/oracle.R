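# Dense clock-driven reference integrator. Every synapse, trace and dopamine
# concentration is advanced every 1 ms step; the within-step weight integral
# uses the same product-of-exponentials closed form as the event-driven
# engine, so the two implementations should agree to floating-point
# accuracy and any disagreement isolates an engine bug rather than a
# discretisation artefact.

#' One step of the dense clock-driven plasticity integrator
#'
#' Advances a dense state by one 1 ms step given the step's events. Order
#' within the step: (1) the weight accumulates the closed-form integral of
#' `C * D` over the step using start-of-step values; (2) all traces decay
#' analytically over the step; (3) dopamine increments are applied; (4) STDP
#' increments are applied to the eligibility traces, sampling partner traces
#' before any same-step increment (so simultaneous spikes never pair);
#' (5) spike traces are incremented; (6) weights of rows whose pre neuron
#' spiked are clamped (mirroring per-row clamping in the event engine).
#'
#' @param state A list as produced by [dense_state()].
#' @param spikes_pre Integer vector of pre neurons spiking this step.
#' @param spikes_post Integer vector of post neurons spiking this step.
#' @param dopamine_events Data frame with `target`, `d_c` for this step
#'   (zero rows for none).
#' @return The updated state (time advanced by 1 ms).
#' @export
dense_step <- function(state, spikes_pre = integer(0), spikes_post = integer(0),
                       dopamine_events = NULL) {
  pc <- state$pair_cfg
  nc <- state$nm_cfg
  inv <- 1 / nc$tau_c + 1 / nc$tau_d
  if (state$mode == "neuromod") {
    state$w <- state$w + state$C * state$D[state$post] * (1 - exp(-inv)) / inv
    state$C <- state$C * exp(-1 / nc$tau_c)
    state$D <- state$D * exp(-1 / nc$tau_d)
  }
  state$s_pre <- state$s_pre * exp(-1 / pc$tau_plus)
  state$s_post <- state$s_post * exp(-1 / pc$tau_minus)

  if (!is.null(dopamine_events) && nrow(dopamine_events) > 0) {
    for (k in seq_len(nrow(dopamine_events)))
      state$D[dopamine_events$target[k]] <-
        state$D[dopamine_events$target[k]] + dopamine_events$d_c[k]
  }

  target_field <- if (state$mode == "neuromod") "C" else "w"
  if (length(spikes_post)) {
    sel <- state$post %in% spikes_post
    state[[target_field]][sel] <- state[[target_field]][sel] +
      pc$a_plus * state$s_pre[state$pre[sel]]
  }
  if (length(spikes_pre)) {
    sel <- state$pre %in% spikes_pre
    state[[target_field]][sel] <- state[[target_field]][sel] -
      pc$a_minus * state$s_post[state$post[sel]]
  }
  if (length(spikes_pre)) state$s_pre[spikes_pre] <- state$s_pre[spikes_pre] + 1
  if (length(spikes_post)) state$s_post[spikes_post] <- state$s_post[spikes_post] + 1
  if (length(spikes_pre)) {
    sel <- state$pre %in% spikes_pre
    state$w[sel] <- clamp_weight(state$w[sel], nc)
  }
  state$time <- state$time + 1
  state
}

#' Create a dense plasticity state
#'
#' @param synapses Data frame with columns `pre`, `post`, `weight`.
#' @param n_neurons Number of neurons (traces are allocated per neuron).
#' @param pair_cfg A [pair_stdp_config()].
#' @param nm_cfg A [neuromod_config()].
#' @param mode `"neuromod"` or `"pair"`.
#' @return A list holding per-synapse weight/eligibility arrays, per-neuron
#'   trace and dopamine arrays, and the current time (0).
#' @export
dense_state <- function(synapses, n_neurons, pair_cfg = pair_stdp_config(),
                        nm_cfg = neuromod_config(),
                        mode = c("neuromod", "pair")) {
  mode <- match.arg(mode)
  list(pre = as.integer(synapses$pre), post = as.integer(synapses$post),
       w = as.numeric(synapses$weight), C = numeric(nrow(synapses)),
       s_pre = numeric(n_neurons), s_post = numeric(n_neurons),
       D = numeric(n_neurons), time = 0,
       pair_cfg = pair_cfg, nm_cfg = nm_cfg, mode = mode)
}

#' Dense clock-driven simulation of the plasticity dynamics
#'
#' Ground-truth integrator used to verify the event-driven engine: updates
#' every synapse every 1 ms. Guarded to small instances since it exists for
#' correctness, not performance.
#'
#' @param synapses Data frame with columns `pre`, `post`, `weight`.
#' @param pre_spikes,post_spikes Lists mapping neuron index to integer spike
#'   times (ms).
#' @param dopamine_events Data frame with `time`, `target`, `d_c`, or `NULL`.
#' @param duration Simulated duration in ms.
#' @param pair_cfg A [pair_stdp_config()].
#' @param nm_cfg A [neuromod_config()].
#' @param mode `"neuromod"` or `"pair"`.
#' @param record If `TRUE`, also return per-step weight and eligibility
#'   trajectories (rows = timesteps).
#' @return A list with `weights`, `eligibility`, `s_pre`, `s_post`, `D` at
#'   `duration`, and optionally `w_traj` / `c_traj` matrices.
#' @export
simulate_dense <- function(synapses, pre_spikes, post_spikes,
                           dopamine_events = NULL, duration,
                           pair_cfg = pair_stdp_config(),
                           nm_cfg = neuromod_config(),
                           mode = c("neuromod", "pair"), record = FALSE) {
  mode <- match.arg(mode)
  if (nrow(synapses) > 1e4)
    stop("simulate_dense is a correctness reference; refusing more than 10^4 synapses")
  n_neurons <- max(synapses$pre, synapses$post, length(pre_spikes),
                   length(post_spikes),
                   if (!is.null(dopamine_events)) dopamine_events$target else 0L)
  state <- dense_state(synapses, n_neurons, pair_cfg, nm_cfg, mode)

  # index events by timestep
  pre_at <- vector("list", duration)
  post_at <- vector("list", duration)
  da_at <- vector("list", duration)
  for (i in seq_along(pre_spikes))
    for (t in pre_spikes[[i]]) if (t >= 1 && t <= duration)
      pre_at[[t]] <- c(pre_at[[t]], i)
  for (j in seq_along(post_spikes))
    for (t in post_spikes[[j]]) if (t >= 1 && t <= duration)
      post_at[[t]] <- c(post_at[[t]], j)
  if (!is.null(dopamine_events) && nrow(dopamine_events) > 0)
    for (k in seq_len(nrow(dopamine_events))) {
      t <- dopamine_events$time[k]
      if (t >= 1 && t <= duration)
        da_at[[t]] <- rbind(da_at[[t]],
                            dopamine_events[k, c("target", "d_c"), drop = FALSE])
    }

  if (record) {
    w_traj <- matrix(NA_real_, nrow = duration, ncol = nrow(synapses))
    c_traj <- matrix(NA_real_, nrow = duration, ncol = nrow(synapses))
  }
  for (t in seq_len(duration)) {
    state <- dense_step(state,
                        spikes_pre = if (is.null(pre_at[[t]])) integer(0) else pre_at[[t]],
                        spikes_post = if (is.null(post_at[[t]])) integer(0) else post_at[[t]],
                        dopamine_events = da_at[[t]])
    if (record) {
      w_traj[t, ] <- state$w
      c_traj[t, ] <- state$C
    }
  }
  # final clamp mirrors the event engine's end-of-run flush
  if (mode == "neuromod") state$w <- clamp_weight(state$w, nm_cfg)
  out <- list(weights = state$w, eligibility = state$C,
              s_pre = state$s_pre, s_post = state$s_post, D = state$D)
  if (record) {
    out$w_traj <- w_traj
    out$c_traj <- c_traj
  }
  out
}
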