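# Event-driven synaptic machinery: ring buffer, lazy row processing, and
# equivalence of the R event engine with the dense clock-driven oracle.

test_that("ring buffer accumulates, delivers after the delay, and clears slots", {
  rb <- ring_buffer(3, max_delay = 4)
  add_weight_to_ring_buffer(rb, 1.0, 2, 1, t = 0)
  add_weight_to_ring_buffer(rb, 0.5, 2, 1, t = 0)
  out <- advance_timestep(rb) # t = 1
  expect_equal(out$exc, c(0, 1.5, 0))
  expect_equal(out$inh, c(0, 0, 0))
  # inhibitory channel is separate
  add_weight_to_ring_buffer(rb, -2, 1, 2, t = 1, inhibitory = TRUE)
  out2 <- advance_timestep(rb) # t = 2
  expect_equal(out2$inh, c(0, 0, 0))
  out3 <- advance_timestep(rb) # t = 3
  expect_equal(out3$inh, c(-2, 0, 0))
  expect_error(add_weight_to_ring_buffer(rb, 1, 1, 0, t = 3), "delay")
  expect_error(add_weight_to_ring_buffer(rb, 1, 1, 5, t = 3), "delay")
})

test_that("ring buffer slot reuse matches a dense delay matrix", {
  set.seed(4)
  n <- 4; max_delay <- 3; horizon <- 40
  rb <- ring_buffer(n, max_delay)
  dense <- matrix(0, nrow = horizon + max_delay + 1, ncol = n)
  deposits <- data.frame(t = sample(0:(horizon - 1), 60, replace = TRUE),
                         target = sample(n, 60, replace = TRUE),
                         delay = sample(max_delay, 60, replace = TRUE),
                         w = stats::runif(60))
  deposits <- deposits[order(deposits$t), ]
  got <- matrix(0, nrow = horizon, ncol = n)
  for (t in seq_len(horizon)) {
    hit <- deposits[deposits$t == t - 1, , drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      add_weight_to_ring_buffer(rb, hit$w[k], hit$target[k], hit$delay[k],
                                t = hit$t[k])
      dense[hit$t[k] + hit$delay[k] + 1, hit$target[k]] <-
        dense[hit$t[k] + hit$delay[k] + 1, hit$target[k]] + hit$w[k]
    }
    got[t, ] <- advance_timestep(rb)$exc
  }
  expect_equal(got, dense[1 + seq_len(horizon), ])
})

test_that("pair-STDP row processing reproduces a hand-replayed causal pair", {
  # pre at 1 ms (processed), post at 3 ms, row processed again at pre = 20 ms:
  # potentiation A+ e^{-2/10} sampled from the pre trace, then depression
  # A- e^{-17/12} sampled from the post trace.
  pc <- pair_stdp_config()
  nc <- neuromod_config(w_min = -Inf, w_max = Inf)
  h <- post_history(tau_post = pc$tau_minus, tau_d = nc$tau_d)
  row <- synaptic_row(1, targets = 2, weights = 1)
  process_row_pair_stdp(row, 1, list(NULL, h), pc, nc)
  record_post_spike(h, 3)
  process_row_pair_stdp(row, 20, list(NULL, h), pc, nc)
  expect_equal(row$weight, 1 + exp(-2 / 10) - exp(-17 / 12), tolerance = 1e-12)
  expect_equal(row$t_old, 20)
  expect_equal(row$s_i, exp(-19 / 10) + 1, tolerance = 1e-12)
})

test_that("a row with no post events in the window only depresses", {
  pc <- pair_stdp_config()
  nc <- neuromod_config(w_min = -Inf, w_max = Inf)
  h <- post_history(tau_post = pc$tau_minus, tau_d = nc$tau_d)
  record_post_spike(h, 2)
  row <- synaptic_row(1, targets = 2, weights = 1)
  row$t_old <- 5 # post spike is before the window
  process_row_pair_stdp(row, 10, list(NULL, h), pc, nc)
  expect_equal(row$weight, 1 - exp(-8 / 12), tolerance = 1e-12)
})

test_that("three-factor row processing gates weight change on dopamine", {
  pc <- pair_stdp_config()
  nc <- neuromod_config(tau_c = 1000, tau_d = 200, w_min = -Inf, w_max = Inf)
  # no dopamine anywhere: weight exactly unchanged, C evolves as pair STDP.
  # The pre trace is still zero at this row's first processing, so only the
  # depression term (post trace e^{-7/12} sampled at the pre spike) acts.
  h <- post_history(tau_post = pc$tau_minus, tau_d = nc$tau_d)
  record_post_spike(h, 3)
  row <- synaptic_row(1, targets = 2, weights = 1)
  process_row_neuromod(row, 10, list(NULL, h), pc, nc)
  expect_identical(row$weight, 1)
  expect_equal(row$eligibility, -exp(-7 / 12), tolerance = 1e-12)

  # reward after the pair: positive weight change, linear in d_c
  run_pair_reward <- function(d_c) {
    h <- post_history(tau_post = pc$tau_minus, tau_d = nc$tau_d)
    row <- synaptic_row(1, targets = 2, weights = 0)
    process_row_neuromod(row, 1, list(NULL, h), pc, nc)
    record_post_spike(h, 3)
    record_dopamine_spike(h, 4, d_c)
    process_row_neuromod(row, 3000, list(NULL, h), pc, nc)
    row$weight
  }
  w_plus <- run_pair_reward(0.1)
  w_minus <- run_pair_reward(-0.1)
  expect_gt(w_plus, 0)
  expect_equal(w_plus, -w_minus, tolerance = 1e-12)
})

test_that("simultaneous pre and post spikes do not pair", {
  pc <- pair_stdp_config()
  nc <- neuromod_config(w_min = -Inf, w_max = Inf)
  h <- post_history(tau_post = pc$tau_minus, tau_d = nc$tau_d)
  record_post_spike(h, 5)
  row <- synaptic_row(1, targets = 2, weights = 0)
  # pre also at 5: the post entry at 5 is in the window (potentiation samples
  # a pre trace that is still zero), and the pre-spike depression samples the
  # post trace *minus* the simultaneous +1 increment: both contributions 0.
  process_row_neuromod(row, 5, list(NULL, h), pc, nc)
  expect_identical(row$eligibility, 0)
})

test_that("event engine matches the dense oracle on random driven networks", {
  for (seed in 1:6) {
    case <- random_driven_case(seed)
    ev <- run_driven_r(case)
    dn <- run_driven_dense(case)
    expect_lt(max(rel_err(ev$weights, dn$weights)), 1e-9)
    expect_lt(max(rel_err(ev$eligibility, dn$eligibility)), 1e-9)
  }
  # with weight bounds active the two still agree
  case <- random_driven_case(99, w_min = 0, w_max = 1.6)
  ev <- run_driven_r(case)
  dn <- run_driven_dense(case)
  expect_lt(max(rel_err(ev$weights, dn$weights)), 1e-9)
  expect_true(all(ev$weights >= 0 & ev$weights <= 1.6))
})

test_that("compiled engine matches the dense oracle on random driven networks", {
  for (seed in 11:16) {
    case <- random_driven_case(seed)
    cp <- run_driven_compiled(case)
    dn <- run_driven_dense(case)
    expect_lt(max(rel_err(cp$weights, dn$weights)), 1e-9)
    expect_lt(max(rel_err(cp$eligibility, dn$eligibility)), 1e-9)
  }
})

test_that("pair-STDP mode of the engine matches a clock-driven replay", {
  case <- random_driven_case(21, n_dopamine = 0)
  # compare at the last pre-spike time of each row: lazy semantics mean later
  # post spikes are not yet applied by the event engine
  t_last <- max(unlist(case$pre_spikes))
  case$duration <- t_last
  case$post_spikes <- lapply(case$post_spikes, function(s) s[s <= t_last])
  ev <- run_driven_r(case, mode = "pair", flush_at_end = FALSE)
  dn <- run_driven_dense(case, mode = "pair")
  sel <- case$synapses$pre %in% which(vapply(case$pre_spikes, function(s)
    length(s) > 0 && max(s) == t_last, logical(1)))
  expect_lt(max(rel_err(ev$weights[sel], dn$weights[sel])), 1e-9)
})

test_that("dopamine-silent simulations leave every weight exactly unchanged", {
  case <- random_driven_case(31, n_dopamine = 0, duration = 5000)
  ev <- run_driven_r(case)
  expect_identical(ev$weights, case$synapses$weight)
  cp <- run_driven_compiled(within(case, dopamine <- dopamine[0, ]))
  expect_identical(cp$weights, case$synapses$weight)
})

test_that("history times are non-decreasing with dopamine-before-post ties", {
  case <- random_driven_case(41, n_dopamine = 40, duration = 1000)
  ev <- run_driven_r(case)
  for (h in ev$histories) {
    expect_true(!is.unsorted(h$time))
    same <- which(diff(h$time) == 0)
    for (i in same) {
      expect_false(h$type[i] == "post_spike" && h$type[i + 1] == "dopamine")
    }
  }
})

test_that("checkpoint flush and resume is exact", {
  case <- random_driven_case(51)
  whole <- run_driven_r(case)
  # same events, but flush all rows at an arbitrary mid-run checkpoint
  split_at <- 997
  syn <- case$synapses
  res <- simulate_event_driven(syn, case$pre_spikes, case$post_spikes,
                               case$dopamine, case$duration, case$pair_cfg,
                               case$nm_cfg, flush_at_end = TRUE)
  # manual split: run events <= split_at, flush, continue with the same
  # mutable state (histories/rows persist), then flush at the end
  rows <- res$rows # layout reference only
  h <- lapply(seq_along(res$histories), function(i)
    post_history(case$pair_cfg$tau_minus, case$nm_cfg$tau_d))
  pre_ids <- sort(unique(syn$pre))
  rows2 <- lapply(pre_ids, function(i) {
    sel <- syn$pre == i
    synaptic_row(i, syn$post[sel], syn$weight[sel], syn$delay[sel])
  })
  names(rows2) <- as.character(pre_ids)
  replay <- function(from, to) {
    for (t in from:to) {
      da <- case$dopamine[case$dopamine$time == t, , drop = FALSE]
      for (k in seq_len(nrow(da)))
        record_dopamine_spike(h[[da$target[k]]], t, da$d_c[k])
      for (j in seq_along(case$post_spikes))
        if (any(case$post_spikes[[j]] == t)) record_post_spike(h[[j]], t)
      for (i in pre_ids)
        if (any(case$pre_spikes[[i]] == t))
          process_row_neuromod(rows2[[as.character(i)]], t, h,
                               case$pair_cfg, case$nm_cfg)
    }
  }
  replay(1, split_at)
  for (r in rows2) flush_row(r, split_at, h, case$pair_cfg, case$nm_cfg)
  replay(split_at + 1, case$duration)
  for (r in rows2) flush_row(r, case$duration, h, case$pair_cfg, case$nm_cfg)
  for (i in pre_ids) {
    expect_equal(rows2[[as.character(i)]]$weight,
                 res$rows[[as.character(i)]]$weight, tolerance = 1e-12)
    expect_equal(rows2[[as.character(i)]]$eligibility,
                 res$rows[[as.character(i)]]$eligibility, tolerance = 1e-12)
  }
})
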