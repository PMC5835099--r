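# Pure plasticity mathematics: traces, STDP sampling, closed-form weight
# updates, clamping.

test_that("decay_trace evaluates the exponential decay and its edge cases", {
  expect_identical(decay_trace(2.5, 0, 10), 2.5)
  expect_identical(decay_trace(0, 123, 7), 0)
  # frozen value cross-checked against fine-step Euler integration of
  # ds/dt = -s/tau (2e6 steps gives 0.3678793, converging to the closed form)
  expect_equal(decay_trace(1.0, 1000, 1000), 0.3678794411714423, tolerance = 1e-12)
  expect_error(decay_trace(1, -1, 10), "elapsed")
  expect_error(decay_trace(1, 5, 0), "tau")
  expect_error(decay_trace(1, 5, -2), "tau")
})

test_that("decay_trace satisfies the semigroup property", {
  set.seed(1)
  for (k in 1:50) {
    x <- stats::runif(1, -5, 5)
    a <- stats::runif(1, 0, 2000)
    b <- stats::runif(1, 0, 2000)
    tau <- stats::runif(1, 1, 5000)
    expect_equal(decay_trace(decay_trace(x, a, tau), b, tau),
                 decay_trace(x, a + b, tau), tolerance = 1e-12)
  }
})

test_that("apply_post_spike samples the decayed pre trace", {
  cfg <- pair_stdp_config() # A+ = 1, tau+ = 10
  # pre spike at 1 ms (trace 1), post at 3 ms: dC = exp(-2/10)
  expect_equal(apply_post_spike(0, 3, trace_state(1, 1), cfg),
               0.8187307530779818, tolerance = 1e-12)
  # zero pre trace leaves C unchanged
  expect_identical(apply_post_spike(0.4, 50, trace_state(0, 1), cfg), 0.4)
  # accumulated trace: pre spikes at 0 and 10, post at 11:
  # trace at 10 is e^{-1} + 1, dC = (e^{-1} + 1) e^{-0.1} = e^{-1.1} + e^{-0.1}
  s_i <- decay_trace(1, 10, cfg$tau_plus) + 1
  expect_equal(apply_post_spike(0, 11, trace_state(s_i, 10), cfg),
               1.237708501734039, tolerance = 1e-12)
  expect_error(apply_post_spike(0, 1, trace_state(1, 5), cfg), "precedes")
})

test_that("apply_pre_spike mirrors apply_post_spike with sign flip", {
  cfg <- pair_stdp_config() # A- = 1, tau- = 12
  # post at 3 ms (trace 1), pre at 15 ms: dC = -e^{-1}
  expect_equal(apply_pre_spike(0, 15, trace_state(1, 3), cfg),
               -0.3678794411714423, tolerance = 1e-12)
  expect_identical(apply_pre_spike(0.2, 50, trace_state(0, 3), cfg), 0.2)
  # symmetry under (A+, tau+) <-> (A-, tau-)
  sym <- pair_stdp_config(a_plus = 0.7, a_minus = 0.7,
                          tau_plus = 9, tau_minus = 9)
  expect_equal(apply_pre_spike(0, 20, trace_state(1.3, 4), sym),
               -apply_post_spike(0, 20, trace_state(1.3, 4), sym),
               tolerance = 1e-15)
})

test_that("weight_delta matches adaptive quadrature of the drift integral", {
  cfg <- neuromod_config(tau_c = 1000, tau_d = 200, w_min = -Inf, w_max = Inf)
  expect_identical(weight_delta(1, 0.5, 10, 10, cfg), 0)
  expect_identical(weight_delta(3, 0, 0, 500, cfg), 0)
  # frozen: adaptive quadrature of C D e^{-u/tau_c} e^{-u/tau_d} over 100 ms
  expect_equal(weight_delta(1, 0.1, 0, 100, cfg), 7.519806065099559,
               tolerance = 1e-10)
  quad <- function(c0, d0, dt, cfg)
    c0 * d0 * stats::integrate(function(u) exp(-u / cfg$tau_c - u / cfg$tau_d),
                               0, dt, rel.tol = 1e-12)$value
  set.seed(2)
  for (k in 1:200) {
    cfgk <- neuromod_config(tau_c = stats::runif(1, 1, 5000),
                            tau_d = stats::runif(1, 1, 5000),
                            w_min = -Inf, w_max = Inf)
    c0 <- stats::runif(1, -10, 10)
    d0 <- stats::runif(1, -10, 10)
    dt <- stats::runif(1, 0, 5000)
    expect_equal(weight_delta(c0, d0, 0, dt, cfgk), quad(c0, d0, dt, cfgk),
                 tolerance = 1e-6)
  }
  expect_error(weight_delta(1, 1, 10, 5, cfg), "precede")
})

test_that("weight_delta is bilinear, monotone in the interval, and saturates", {
  cfg <- neuromod_config(tau_c = 700, tau_d = 120, w_min = -Inf, w_max = Inf)
  base <- weight_delta(1, 1, 0, 300, cfg)
  expect_equal(weight_delta(3.5, 1, 0, 300, cfg), 3.5 * base, tolerance = 1e-12)
  expect_equal(weight_delta(1, -2, 0, 300, cfg), -2 * base, tolerance = 1e-12)
  dts <- seq(0, 6000, by = 50)
  vals <- abs(weight_delta(2, 0.3, 0, dts, cfg))
  expect_true(all(diff(vals) >= 0))
  limit <- 2 * 0.3 * cfg$tau_c * cfg$tau_d / (cfg$tau_c + cfg$tau_d)
  expect_equal(weight_delta(2, 0.3, 0, 1e6, cfg), limit, tolerance = 1e-9)
  expect_equal(sign(weight_delta(-2, 0.3, 0, 100, cfg)), -1)
})

test_that("weight_delta_general reduces to the common-reference form and matches quadrature", {
  cfg <- neuromod_config(tau_c = 1000, tau_d = 200, w_min = -Inf, w_max = Inf)
  expect_equal(weight_delta_general(1.5, 50, 0.2, 50, 50, 400, cfg),
               weight_delta(1.5, 0.2, 50, 400, cfg), tolerance = 1e-14)
  expect_identical(weight_delta_general(0, 0, 0.7, 10, 20, 900, cfg), 0)
  quad <- function(c0, tc, d0, td, t0, t1, cfg)
    c0 * d0 * exp(-(t0 - tc) / cfg$tau_c - (t0 - td) / cfg$tau_d) *
      stats::integrate(function(v)
        exp(-v * (1 / cfg$tau_c + 1 / cfg$tau_d)),
        0, t1 - t0, rel.tol = 1e-12)$value
  set.seed(3)
  for (k in 1:200) {
    cfgk <- neuromod_config(tau_c = stats::runif(1, 1, 5000),
                            tau_d = stats::runif(1, 1, 5000),
                            w_min = -Inf, w_max = Inf)
    tc <- stats::runif(1, 0, 100); td <- stats::runif(1, 0, 100)
    t0 <- 100 + stats::runif(1, 0, 100); t1 <- t0 + stats::runif(1, 0, 3000)
    c0 <- stats::runif(1, -10, 10); d0 <- stats::runif(1, -10, 10)
    expect_equal(weight_delta_general(c0, tc, d0, td, t0, t1, cfgk),
                 quad(c0, tc, d0, td, t0, t1, cfgk), tolerance = 1e-6)
  }
  expect_error(weight_delta_general(1, 0, 1, 0, 100, 50, cfg), "precede")
  expect_error(weight_delta_general(1, 200, 1, 0, 100, 500, cfg), "reference")
})

test_that("clamp_weight clips to the configured bounds", {
  cfg <- neuromod_config(w_min = 0, w_max = 4)
  expect_identical(clamp_weight(2.2, cfg), 2.2)
  expect_identical(clamp_weight(-1, cfg), 0)
  expect_identical(clamp_weight(9, cfg), 4)
  expect_equal(clamp_weight(c(-3, 1, 7), cfg), c(0, 1, 4))
})

test_that("configuration constructors validate their arguments", {
  expect_error(pair_stdp_config(a_plus = 0), "a_plus")
  expect_error(pair_stdp_config(tau_minus = -3), "tau_minus")
  expect_error(neuromod_config(tau_c = 0), "tau_c")
  expect_error(neuromod_config(w_min = 2, w_max = 1), "w_min < w_max")
})
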