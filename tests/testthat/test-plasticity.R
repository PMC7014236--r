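# Traces, the three learning rules, and the event-driven replay, checked
# against closed-form exponentials and a hand-rolled per-synapse oracle.

test_that("trace decay follows the closed-form exponential and bumps at spikes", {
  expect_identical(decay_and_bump_trace(0, 100, 5, FALSE), 0)
  expect_equal(decay_and_bump_trace(1, 100, 100, FALSE), exp(-1))
  expect_equal(decay_and_bump_trace(0, 100, 1, TRUE), 1)
  # stepped decay over 100 ms at dt = 0.5 equals exp(-1) exactly
  # (multiplicative factors compose), within numerical noise
  v <- 1
  for (i in 1:200) v <- decay_and_bump_trace(v, 100, 0.5, FALSE)
  expect_equal(v, exp(-1), tolerance = 1e-3)
  expect_error(decay_and_bump_trace(1, -1, 1), "tau")
})

test_that("multiplicative bound factors pin the weight range", {
  expect_equal(bound_factors(1, 0.001, 1), list(F_plus = 0, F_minus = 0.001))
  expect_equal(bound_factors(0, 0.001, 1), list(F_plus = 0.001, F_minus = 0))
  expect_equal(bound_factors(0.5, 0.001, 1),
               list(F_plus = 5e-4, F_minus = 5e-4))
  expect_error(bound_factors(1.2), "\\[0, 1\\]")
})

test_that("pair and triplet deltas match the analytic trace products", {
  # pre spike 10 ms before post, tau1 = 10: trace = exp(-1)
  expect_equal(pair_ltp_delta(0, exp(-1), 0.001), 0.001 * exp(-1))
  expect_equal(pair_ltp_delta(0, exp(-1), 0.001), 3.679e-4,
               tolerance = 1e-4)
  expect_identical(pair_ltp_delta(0.3, 0), 0)
  expect_identical(pair_ltp_delta(1, 5), 0)
  expect_equal(pair_ltd_delta(0.5, exp(-1), 0.001, 1),
               -0.5 * 0.001 * exp(-1))
  expect_identical(pair_ltd_delta(0, 3), 0)
  # triplet: prior post 50 ms back on the slow trace tau2 = 100
  expect_equal(triplet_ltp_delta(0, exp(-1), exp(-0.5), 0.001),
               0.001 * exp(-1) * exp(-0.5))
  expect_equal(triplet_ltp_delta(0, exp(-1), exp(-0.5), 0.001),
               2.231e-4, tolerance = 1e-3)
  expect_identical(triplet_ltp_delta(0.4, 0.7, 0), 0)
  expect_identical(triplet_ltp_delta(1, 1, 1), 0)
})

test_that("forgetting integrates dw/dt = -w y / tau_f exactly per step", {
  expect_identical(forgetting_step(0.7, 0, 5, 10), 0.7)
  expect_equal(forgetting_step(1, 1, 10, 10), exp(-1))
  expect_identical(forgetting_step(0, 1, 10, 10), 0)
  expect_error(forgetting_step(0.5, 1, 1, -2), "tau_f")
  # stepped composition over 10 ms matches the closed form
  w <- 1
  for (i in 1:20) w <- forgetting_step(w, 1, 0.5, 10)
  expect_equal(w, exp(-1), tolerance = 1e-3)
})

test_that("event-driven replay reproduces the scripted pair example", {
  syn <- data.frame(pre = 1L, post = 2L, w = 0, rule = "pair",
                    lambda = 0.001, alpha = 1, tau_f = 10)
  ev <- data.frame(neuron = c(1L, 2L), time = c(0, 10))
  out <- stdp_replay(ev, syn)
  expect_equal(out$w, 0.001 * exp(-1), tolerance = 1e-9)

  # post before pre: depression read off the post trace
  syn$w <- 0.5
  ev2 <- data.frame(neuron = c(2L, 1L), time = c(0, 10))
  out2 <- stdp_replay(ev2, syn)
  expect_equal(out2$w, 0.5 - 0.5 * 0.001 * exp(-1), tolerance = 1e-9)
})

test_that("event-driven replay reproduces the scripted triplet example", {
  syn <- data.frame(pre = 1L, post = 2L, w = 0, rule = "triplet",
                    lambda = 0.001, alpha = 1, tau_f = 10)
  # prior post at -50 relative to the triggering post; pre 10 ms before
  ev <- data.frame(neuron = c(2L, 1L, 2L), time = c(0, 40, 50))
  out <- stdp_replay(ev, syn)
  # LTD at the pre spike reads y1_post = exp(-40/10)
  w_after_ltd <- 0 # w was 0, depression leaves 0
  expect_equal(out$w, 0.001 * exp(-1) * exp(-0.5), tolerance = 1e-9)
  # a first-ever post spike cannot potentiate (zero slow trace)
  ev0 <- data.frame(neuron = c(1L, 2L), time = c(0, 10))
  expect_equal(stdp_replay(ev0, syn)$w, 0)
})

test_that("replay matches the independent per-synapse oracle on random rasters", {
  set.seed(99)
  for (rule in c("pair", "triplet", "triplet_forgetting")) {
    for (rep in 1:5) {
      pre <- sort(runif(8, 0, 500))
      post <- sort(runif(8, 0, 500))
      # keep event times distinct so tie-break logic is not exercised here
      stopifnot(!any(pre %in% post))
      syn <- data.frame(pre = 1L, post = 2L, w = 0.5, rule = rule,
                        lambda = 0.01, alpha = 1.2, tau_f = 200)
      ev <- data.frame(neuron = c(rep(1L, 8), rep(2L, 8)),
                       time = c(pre, post))
      got <- stdp_replay(ev, syn, until = 500)$w
      want <- ref_stdp_one(pre, post, 0.5, rule, lambda = 0.01,
                           alpha = 1.2, tau_f = 200, until = 500)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("stepped engine converges to the event-driven weights as dt shrinks", {
  # scripted raster realized through strong pulses; single plastic synapse
  pre_times <- c(20, 120, 260, 300)
  post_times <- c(30, 110, 280)
  for (rule in c("pair", "triplet")) {
    net <- two_neuron_net(rule = rule, w0 = 0.5)
    pulses <- data.frame(
      stimulator = c(rep(1, length(pre_times)), rep(2, length(post_times))),
      onset = c(pre_times, post_times) - 1, duration = 1, amplitude = 120)
    stim <- stim_protocol(pulses, duration = 400)
    err <- sapply(c(0.5, 0.1), function(dtv) {
      sim <- simulate_snn(net, stim, dt = dtv, learning = TRUE)
      # engine spikes land on the grid: replay the *actual* raster
      ev <- sim$raster
      want <- stdp_replay(ev, net$synapses)$w
      abs(sim$final_weights$w - want)
    })
    expect_lt(err[1], 5e-5)          # O(dt) agreement at the default step
    expect_lt(err[2], err[1] + 1e-12) # shrinks with dt
  }
})

test_that("weights stay inside [0,1] under fuzzed simulation of every rule", {
  set.seed(123)
  for (rule in c("pair", "triplet", "triplet_forgetting")) {
    net <- build_single_neuron_testbed(
      5, rule = rule, init_w = c(0.05, 0.95),
      plasticity = list(lambda = 0.05, alpha = 2, tau_f = 50),
      pre_params = neuron_params("regular", D = 25),
      post_params = neuron_params("regular", D = 25))
    stim <- rate_pattern(c(2, 10, 25, 40, 50), duration = 60000)
    sim <- simulate_snn(net, stim, dt = 0.5, learning = TRUE,
                        snapshot_every = 500)
    expect_true(all(sim$snapshots >= 0 & sim$snapshots <= 1))
    expect_true(all(sim$final_weights$w >= 0 & sim$final_weights$w <= 1))
  }
})

test_that("non-plastic synapses never change and learning=FALSE freezes everything", {
  net <- build_single_neuron_testbed(4, rule = "triplet_forgetting",
                                     init_w = 0.6)
  net$synapses$rule[2] <- "none"
  stim <- rate_pattern(c(20, 20, 20, 20), duration = 20000)
  set.seed(5)
  sim <- simulate_snn(net, stim, dt = 0.5, learning = TRUE)
  expect_identical(sim$final_weights$w[2], 0.6)
  expect_false(isTRUE(all.equal(sim$final_weights$w[1], 0.6)))
  sim2 <- simulate_snn(net, stim, dt = 0.5, learning = FALSE, seed = 5)
  expect_identical(sim2$final_weights$w, net$synapses$w)
})
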