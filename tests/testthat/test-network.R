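# Network construction and simulation-engine contracts.

test_that("single-neuron testbed has the 10-to-1 feed-forward motif", {
  net <- build_single_neuron_testbed(10, rule = "pair")
  expect_identical(nrow(net$neurons), 11L)
  expect_identical(nrow(net$synapses), 10L)
  expect_identical(nrow(net$stimulators), 10L)
  expect_true(all(net$synapses$post == 11L))
  expect_true(all(net$synapses$rule == "pair"))
  net1 <- build_single_neuron_testbed(1, rule = "triplet")
  expect_identical(nrow(net1$neurons), 2L)
  expect_identical(nrow(net1$synapses), 1L)
  expect_error(build_single_neuron_testbed(0), "n_pre")
  set.seed(1)
  netw <- build_single_neuron_testbed(10, rule = "pair",
                                      init_w = c(0.25, 0.75))
  expect_true(all(netw$synapses$w >= 0.25 & netw$synapses$w <= 0.75))
})

test_that("classifier network wiring matches the documented topology", {
  set.seed(1)
  net <- build_emg_classifier(8, 3)
  tab <- table(net$neurons$layer)
  expect_identical(as.integer(tab[c("sensory", "sensory_inhibitory",
                                    "rest_detector", "classifier",
                                    "classifier_inhibitory")]),
                   c(8L, 8L, 1L, 3L, 3L))
  pl <- plastic_synapses(net)
  expect_identical(nrow(pl), 27L) # (8 sensory + 1 rest) x 3 classifiers
  expect_true(all(pl$rule == "triplet_forgetting"))
  expect_true(all(pl$w >= 0.25 & pl$w <= 0.75))
  # rest detector carries the strong-noise parameter
  expect_equal(net$neurons$D[net$neurons$layer == "rest_detector"], 700)
  # lateral inhibition: every classifier-inhibitory partner inhibits all
  # classifiers except its driver
  cls <- attr(net, "classifiers")
  for (j in seq_along(cls)) {
    partner <- net$synapses$post[net$synapses$pre == cls[j] &
                                   net$neurons$layer[
                                     match(net$synapses$post,
                                           net$neurons$id)] ==
                                   "classifier_inhibitory"]
    inhibits <- net$synapses$post[net$synapses$pre == partner]
    expect_setequal(inhibits, setdiff(cls, cls[j]))
  }
  set.seed(1)
  net2 <- build_emg_classifier(8, 2)
  expect_identical(nrow(plastic_synapses(net2)), 18L)
  expect_error(build_emg_classifier(1, 3), "n_channels")
  expect_error(build_emg_classifier(8, 1), "n_classes")
})

test_that("topology validation rejects malformed networks", {
  p <- neuron_params("regular")
  nn <- rbind(neuron_row_test(1L, "a", p), neuron_row_test(2L, "b", p))
  expect_error(snn_topology(nn, data.frame(pre = 1L, post = 1L, w = 0.5,
                                           rule = "none", lambda = 0,
                                           alpha = 1, tau_f = 10)),
               "self-synapses")
  expect_error(snn_topology(nn, data.frame(pre = 1L, post = 5L, w = 0.5,
                                           rule = "none", lambda = 0,
                                           alpha = 1, tau_f = 10)),
               "unknown neuron")
  # the [0,1] bound is a property of the plastic rule; fixed synapses
  # may exceed 1 but never go negative
  expect_error(snn_topology(nn, data.frame(pre = 1L, post = 2L, w = 1.5,
                                           rule = "pair", lambda = 0.001,
                                           alpha = 1, tau_f = 10)),
               "\\[0, 1\\]")
  expect_error(snn_topology(nn, data.frame(pre = 1L, post = 2L, w = -0.5,
                                           rule = "none", lambda = 0,
                                           alpha = 1, tau_f = 10)),
               ">= 0")
  expect_silent(snn_topology(nn, data.frame(pre = 1L, post = 2L, w = 3,
                                            rule = "none", lambda = 0,
                                            alpha = 1, tau_f = 10)))
  bad <- nn; bad$g[1] <- 1
  expect_error(snn_topology(bad, data.frame(pre = integer(),
                                            post = integer(),
                                            w = numeric(),
                                            rule = character(),
                                            lambda = numeric(),
                                            alpha = numeric(),
                                            tau_f = numeric())),
               "g = \\+2")
})

test_that("null simulations and seed determinism behave as contracts say", {
  net <- build_single_neuron_testbed(3, rule = "pair", init_w = 0.4)
  stim <- temporal_pattern(5, n = 3, duration = 1000)
  z <- simulate_snn(net, stim, duration = 0, dt = 0.5)
  expect_identical(nrow(z$raster), 0L)
  expect_identical(z$final_weights$w, net$synapses$w)
  noisy <- net
  noisy$neurons$D <- 20
  a <- simulate_snn(noisy, stim, dt = 0.5, seed = 42, learning = TRUE)
  b <- simulate_snn(noisy, stim, dt = 0.5, seed = 42, learning = TRUE)
  expect_identical(a$raster, b$raster)
  expect_identical(a$final_weights$w, b$final_weights$w)
  c2 <- simulate_snn(noisy, stim, dt = 0.5, seed = 43, learning = TRUE)
  expect_false(identical(a$raster, c2$raster))
})

test_that("a classifier that never fires keeps its input weights", {
  set.seed(7)
  net <- build_emg_classifier(8, 3)
  # silence the rest detector so nothing drives any classifier
  net$neurons$D[net$neurons$layer == "rest_detector"] <- 0
  stim <- stim_protocol(duration = 5000)
  sim <- simulate_snn(net, stim, dt = 0.5, learning = TRUE, seed = 1)
  expect_identical(sum(sim$raster$neuron %in% attr(net, "classifiers")), 0L)
  expect_identical(sim$final_weights$w, net$synapses$w)
})

test_that("rest detector fires when idle and is silenced by sensory activity", {
  set.seed(3)
  net <- build_emg_classifier(8, 3)
  rest <- attr(net, "rest")
  idle <- simulate_snn(net, stim_protocol(duration = 10000), dt = 0.5,
                       seed = 21)
  idle_rate <- sum(idle$raster$neuron == rest) / 10
  expect_gt(idle_rate, 2)
  # strong drive on every channel
  busy_stim <- stim_protocol(
    data.frame(stimulator = rep(1:8, each = 100),
               onset = rep(seq(0, 9900, 100), 8), duration = 1,
               amplitude = 120), duration = 10000)
  busy <- simulate_snn(net, busy_stim, dt = 0.5, seed = 21)
  busy_rate <- sum(busy$raster$neuron == rest) / 10
  expect_lt(busy_rate, idle_rate / 4)
})

test_that("rasters round-trip through CSV and weight snapshots are sane", {
  net <- build_single_neuron_testbed(2, rule = "pair")
  stim <- temporal_pattern(5, n = 2, duration = 3000)
  sim <- simulate_snn(net, stim, dt = 0.5, snapshot_every = 1000)
  f <- tempfile(fileext = ".csv")
  write_raster(sim, f)
  back <- read_raster(f)
  expect_equal(back$time, sim$raster$time)
  expect_equal(back$neuron, sim$raster$neuron)
  unlink(f)
  expect_true(all(diff(sim$snapshot_times) > 0))
  expect_true(all(sim$snapshot_times <= 3000))
})
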