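# Experiment builders and runners.

test_that("single-synapse protocol follows the closed-form delay dependence", {
  # after the pre(1 ms)/post(3 ms) pair the eligibility is e^{-2/10}; a
  # dopaminergic spike at t_d then converts C(t_d) into weight drift with
  # gain d_c * tau_c tau_d / (tau_c + tau_d)
  expected <- function(td, d_c = 0.1)
    exp(-2 / 10) * exp(-(td - 3) / 1000) * d_c * (1000 * 200 / 1200)
  for (td in c(4, 100, 1000)) {
    expect_equal(run_single_synapse_protocol(td, 0.1), expected(td),
                 tolerance = 1e-6)
  }
  # punishment mirrors reward exactly
  expect_equal(run_single_synapse_protocol(500, -0.1),
               -run_single_synapse_protocol(500, 0.1), tolerance = 1e-12)
  # delay of 10 tau_c: weight change essentially gone
  expect_lt(abs(run_single_synapse_protocol(10000, 0.1)),
            1e-3 * abs(run_single_synapse_protocol(4, 0.1)))
})

test_that("delay sweep is monotone decreasing in magnitude", {
  sw <- sweep_dopamine_delay(seq(4, 3000, by = 250), 0.1)
  expect_true(all(diff(abs(sw$delta_w)) < 0))
  expect_true(all(sw$delta_w > 0))
})

test_that("conditioning network construction matches the stated counts", {
  net <- build_conditioning_network(1000, seed = 5)
  expect_equal(net$n_groups, 100)
  expect_equal(net$group_size, 50)
  expect_equal(length(net$groups), 100)
  expect_true(all(vapply(net$groups, length, integer(1)) == 50))
  expect_true(all(vapply(net$groups, anyDuplicated, integer(1)) == 0))
  n_syn <- nrow(net$synapses)
  expect_gt(n_syn, 0.9 * 1000 * 999 * 0.1)
  expect_lt(n_syn, 1.1 * 1000 * 999 * 0.1)
  # plastic synapses originate only from excitatory neurons
  expect_true(all(net$synapses$pre[net$synapses$kind == "neuromod"] <= 800))
  expect_true(all(net$synapses$kind[net$synapses$pre > 800] == "inhibitory"))
  # no self-connections
  expect_true(all(net$synapses$pre != net$synapses$post))
  # determinism
  net2 <- build_conditioning_network(1000, seed = 5)
  expect_identical(net$synapses, net2$synapses)
  expect_identical(net$groups, net2$groups)
  expect_error(build_conditioning_network(30), "multiple of 20")
})

test_that("stimulus schedule has uniform intervals and one reward per S1", {
  sch <- stimulus_schedule(100, duration = 300000, seed = 11)
  iv <- diff(sch$stimuli$time)
  expect_true(all(iv >= 100 & iv <= 300))
  expect_lt(abs(mean(iv) - 200), 6)
  n_s1 <- sum(sch$stimuli$group == 1)
  expect_equal(nrow(sch$rewards), n_s1)
  # reward delay in (0, 1000]
  s1_t <- sch$stimuli$time[sch$stimuli$group == 1]
  delays <- sch$rewards$time - s1_t
  expect_true(all(delays >= 1 & delays <= 1000))
  # roughly 1/n_groups of the events are S1
  expect_lt(abs(n_s1 / nrow(sch$stimuli) - 0.01), 0.015)
})

test_that("summarize_weights computes group and global means", {
  net <- build_conditioning_network(40, seed = 2)
  pre <- net$synapses$pre[net$synapses$kind == "neuromod"]
  w <- rep(1, length(pre))
  s <- summarize_weights(net, w, pre, group = 1)
  expect_equal(s$group_mean, s$global_mean)
  # doubling one group's outgoing weights doubles its mean exactly
  sel <- pre %in% net$groups[[1]]
  w2 <- w; w2[sel] <- 2
  s2 <- summarize_weights(net, w2, pre, group = 1)
  expect_equal(s2$group_mean, 2 * s$group_mean)
  expect_equal(sum(s2$snapshot), sum(w2[sel]))
})

test_that("reward/punishment weights are exactly inert without dopamine", {
  r <- run_reward_punishment(duration = 4000, seed = 3,
                             dopamine_enabled = FALSE)
  expect_identical(r$weights, rep(1.5, 10))
})

test_that("a short conditioning run produces summaries and rasters", {
  net <- build_conditioning_network(40, seed = 3)
  r <- run_conditioning(net, duration = 5000, seed = 3)
  expect_equal(r$summary$time_ms, seq(1000, 5000, by = 1000))
  expect_true(all(is.finite(r$summary$group_mean_nA)))
  expect_true(all(r$weights >= 0 & r$weights <= net$w_max))
  expect_true(all(r$spikes$neuron <= 40))
  # deterministic under identical seeds
  r2 <- run_conditioning(net, duration = 5000, seed = 3)
  expect_identical(r$summary, r2$summary)
  expect_identical(r$spikes, r2$spikes)
})
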