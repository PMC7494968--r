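test_that("spike phase: midpoint, spike instants, endpoints, and error cases", {
  expect_equal(spike_phase(c(0, 100), 50), pi)
  expect_equal(spike_phase(c(0, 100, 200), 100), 2 * pi)
  expect_equal(spike_phase(c(0, 100), 0), 0)
  expect_equal(spike_phase(c(0, 100), 100), 2 * pi)
  # continuous, nondecreasing, gaining 2 pi per ISI
  s <- c(0, 30, 100, 250)
  tt <- seq(0, 250, by = 0.5)
  phi <- spike_phase(s, tt)
  expect_true(all(diff(phi) >= 0))
  expect_equal(spike_phase(s, s), 2 * pi * (0:3))
  expect_error(spike_phase(c(0, 100), 150), "interval")
  expect_error(spike_phase(100, 50), "2 spikes")
})

test_that("order parameter is exactly 1 for identical trains and vanishes for splay states", {
  train <- seq(0, 10000, by = 50)
  trains <- rep(list(train), 100)
  op <- order_parameter(trains, 5000, 10000)
  expect_identical(op$R_bar, 1)
  expect_identical(op$n_used, 100L)
  # identical but irregular trains still give exactly 1
  irr <- sort(c(seq(0, 10000, 80), seq(13, 10000, 197)))
  expect_identical(order_parameter(rep(list(irr), 7), 5000, 10000)$R_bar, 1)
  # evenly splayed periodic trains: sum of N-th roots of unity
  N <- 20; T_ <- 100
  splay <- lapply(seq_len(N) - 1, function(k) seq(k * T_ / N, 10500, by = T_))
  ops <- order_parameter(splay, 5000, 10000)
  expect_lt(max(ops$r_t), 1e-10)
  # single usable neuron
  one <- order_parameter(list(c(0, 50, 120, 10100), c(6000, 6100)),
                         5000, 10000)
  expect_identical(one$n_used, 1L)
  expect_equal(one$R_bar, 1)
})

test_that("order parameter stays in [0, 1] for random spike trains", {
  set.seed(42)
  for (rep in 1:20) {
    trains <- lapply(1:8, function(i)
      sort(c(0, stats::runif(sample(5:40, 1), 0, 1000), 1000)))
    op <- order_parameter(trains, 100, 900, stride_ms = 5)
    expect_gte(op$R_bar, 0)
    expect_lte(op$R_bar, 1)
  }
})

test_that("window clipping uses the largest commonly bracketed sub-window", {
  trains <- list(seq(10, 990, by = 40), seq(0, 950, by = 50))
  op <- order_parameter(trains, 0, 1000, window = "clip")
  expect_equal(op$window_used_ms, c(10, 950))
  expect_identical(op$n_used, 2L)
  expect_error(order_parameter(trains, 0, 1000), "bracketing")
})

test_that("ISI CV: zero for periodic trains, boundary case at 0.5, scale invariant", {
  periodic <- list(seq(0, 1000, by = 100))
  expect_identical(isi_cv(periodic, 0, 1000)$CV_bar, 0)
  # ISIs {1, 3}: population sd 1, mean 2 -> CV exactly 0.5 -> burst by the >= rule
  tr <- list(c(0, 1, 4))
  cv <- isi_cv(tr, 0, 10)
  expect_identical(cv$CV_bar, 0.5)
  expect_identical(classify_activity(0.5, cv$CV_bar)$pattern, "burst")
  # scale invariance
  set.seed(1)
  s <- sort(stats::runif(30, 0, 1000))
  expect_equal(isi_cv(list(s), 0, 1000)$CV_bar,
               isi_cv(list(10 * s), 0, 10000)$CV_bar)
  # sample-sd and pooled variants differ from the default where they should
  two <- list(c(0, 1, 4), c(0, 2, 4))
  expect_gt(isi_cv(two, 0, 10, sd_type = "sample")$CV_bar,
            isi_cv(two, 0, 10)$CV_bar)
  expect_error(isi_cv(list(c(1, 2)), 0, 10), "3 spikes")
})

test_that("mean firing frequency is the reciprocal network-mean ISI in Hz", {
  expect_equal(mean_firing_frequency(list(seq(0, 1000, 100)), 0, 1000), 10)
  expect_equal(mean_firing_frequency(list(seq(0, 1000, 40)), 0, 1000), 25)
  # doubling all spike times halves the frequency
  s <- list(sort(stats::runif(50, 0, 1000)))
  f1 <- mean_firing_frequency(s, 0, 1000)
  f2 <- mean_firing_frequency(lapply(s, `*`, 2), 0, 2000)
  expect_equal(f1, 2 * f2)
})

test_that("mean synaptic input: zero trace, constant trace, off-grid window ends", {
  tt <- 0:100
  expect_identical(mean_synaptic_input(tt, rep(0, 101), 10, 90), 0)
  expect_equal(mean_synaptic_input(tt, rep(2.5, 101), 10, 90), 2.5)
  expect_equal(mean_synaptic_input(tt, rep(2.5, 101), 10.5, 89.5), 2.5)
  # linear ramp: time average is the midpoint value
  expect_equal(mean_synaptic_input(tt, tt, 20, 80), 50)
  expect_error(mean_synaptic_input(tt, tt, -5, 80), "outside")
})

test_that("an uncoupled network yields exactly zero mean synaptic input", {
  net <- build_random_network(10, 0.5, seed = 2)
  net$adjacency[, ] <- 0L
  st <- sample_initial_state(10, seed = 3)
  sim <- aeif_simulate(net, aeif_params(), st, t_end_ms = 1500)
  expect_identical(mean_synaptic_input(sim$times, sim$isyn_mean, 500, 1500), 0)
})

test_that("classification thresholds: spike/burst at 0.5 CV, synchrony at the R cutoff", {
  expect_identical(classify_activity(1.0, 0.2),
                   list(pattern = "spike", sync_state = "synchronous"))
  expect_identical(classify_activity(0.3, 0.7),
                   list(pattern = "burst", sync_state = "desynchronous"))
  expect_identical(classify_activity(0.3, 0.5)$pattern, "burst")
  expect_identical(classify_activity(0.9, 0.1)$sync_state, "synchronous")
  expect_identical(classify_activity(0.89, 0.1)$sync_state, "desynchronous")
})

test_that("diagnostics agree with naive direct-formula reimplementations on toy trains", {
  set.seed(7)
  trains <- lapply(1:5, function(i) {
    n <- sample(6:10, 1)
    sort(stats::runif(n, 0, 100)) * 10
  })
  # ensure bracketing of a common window
  trains <- lapply(trains, function(s) c(0, s, 1000))
  R_mod <- order_parameter(trains, 200, 800, stride_ms = 0.1)$R_bar
  R_naive <- naive_order_parameter(trains, 200, 800, 0.1)
  expect_lt(abs(R_mod - R_naive), 1e-6)
  expect_lt(abs(isi_cv(trains, 0, 1000)$CV_bar -
                naive_cv_bar(trains, 0, 1000)), 1e-6)
  expect_lt(abs(mean_firing_frequency(trains, 0, 1000) -
                naive_f_bar(trains, 0, 1000)), 1e-6)
  tt <- seq(0, 1000, by = 1)
  tr <- sin(tt / 50) * 10
  expect_lt(abs(mean_synaptic_input(tt, tr, 100, 900) -
                naive_trapz_mean(tt, tr, 100, 900)), 1e-6)
})

test_that("order-parameter time average converges in the sampling stride", {
  set.seed(3)
  trains <- lapply(1:10, function(i) {
    isis <- stats::runif(60, 20, 60)
    c(0, cumsum(isis))
  })
  r1 <- order_parameter(trains, 200, 1200, stride_ms = 1)$R_bar
  r01 <- order_parameter(trains, 200, 1200, stride_ms = 0.1)$R_bar
  expect_lt(abs(r1 - r01), 5e-3)
})
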