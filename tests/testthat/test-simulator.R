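test_that("an unconnected neuron started at rest stays at rest", {
  net <- motif_network()
  net$adjacency[, ] <- 0L
  sim <- aeif_simulate(net, aeif_params(), zero_state(2), t_end_ms = 10000,
                       input = 0, record_state = TRUE)
  expect_lt(max(abs(sim$v_trace - (-70))), 0.1)
  expect_identical(sum(lengths(sim$spike_trains)), 0L)
})

test_that("an isolated neuron at twice rheobase fires tonically with adapting ISIs", {
  net <- motif_network()
  net$adjacency[, ] <- 0L
  I <- 2 * rheobase_current(2)
  sim <- aeif_simulate(net, aeif_params(g_exc_nS = 0), zero_state(2),
                       t_end_ms = 10000, input = I)
  s <- sim$spike_trains[[1]]
  expect_gt(length(s), 50)
  isi <- diff(s)
  # adaptation: early ISIs lengthen, late ISIs saturate
  expect_gt(isi[3], isi[1])
  late <- tail(isi, 10)
  expect_lt(stats::sd(late) / mean(late), 0.01)
  # spike-pattern regularity over the second half of the run
  cv <- isi_cv(sim$spike_trains[1], 5000, 10000)
  expect_lt(cv$CV_bar, 0.5)
  # spike times strictly increasing
  expect_true(all(isi > 0))
})

test_that("conductance decays exponentially between resets: log g affine with slope -1/tau_s", {
  net <- motif_network()
  net$adjacency[, ] <- 0L
  dt <- 0.001
  sim <- aeif_simulate(net, aeif_params(g_exc_nS = 0), zero_state(2, g0 = 1),
                       t_end_ms = 20, dt_ms = dt, input = 0,
                       sample_stride_ms = dt, record_state = TRUE)
  g <- sim$g_trace[, 1]
  k <- round(2.728 / dt) # one synaptic time constant in steps
  expect_equal(g[1 + k] / g[1], exp(-1), tolerance = 1e-12)
  expect_equal(g[1 + 2 * k] / g[1 + k], exp(-1), tolerance = 1e-12)
  # log-affine: equal ratios across every stretch of equal length
  r <- g[seq(1001, 5001, by = 500)] / g[seq(501, 4501, by = 500)]
  expect_lt(max(abs(r - r[1])), 1e-12)
})

test_that("synaptic currents follow the delayed-conductance coupling law", {
  p <- aeif_params()
  # no delayed conductance -> no current
  net <- build_random_network(10, 0.5, seed = 3)
  expect_equal(synaptic_current(rep(-60, 10), rep(0, 10), net, p), rep(0, 10))
  # single excitatory edge: (0 - (-70)) * 1 nS = 70 pA
  me <- motif_network()
  expect_equal(synaptic_current(c(-70, -70), c(1, 0), me, p), c(0, 70))
  # single inhibitory edge: (-80 - (-70)) * 1 nS = -10 pA
  mi <- motif_network(type = c("inh", "inh"))
  expect_equal(synaptic_current(c(-70, -70), c(1, 0), mi, p), c(0, -10))
  expect_error(synaptic_current(rep(-60, 9), rep(0, 10), net, p), "size")
})

test_that("current signs are correct over a whole coupled run", {
  # excitatory-only network below 0 mV: mean current never negative
  net <- build_random_network(20, 0.5, excitatory_fraction = 1, seed = 4)
  p <- aeif_params(g_exc_nS = 0.1, g_rel = 0, d_exc_ms = 3, d_inh_ms = 3)
  st <- sample_initial_state(20, seed = 5)
  sim <- aeif_simulate(net, p, st, t_end_ms = 1000)
  expect_true(all(sim$isyn_mean >= 0))
  # inhibitory-only network above -80 mV: never positive
  neti <- build_random_network(20, 0.5, excitatory_fraction = 0, seed = 4)
  pi_ <- aeif_params(g_exc_nS = 0.1, g_rel = 6, d_exc_ms = 3, d_inh_ms = 3)
  simi <- aeif_simulate(neti, pi_, st, t_end_ms = 1000)
  expect_true(all(simi$isyn_mean <= 0))
  expect_true(all(simi$g_final >= 0))
})

test_that("delayed conductance view: zero pre-history, identity at zero delay, grid lookup", {
  tt <- seq(0, 10, by = 0.5)
  g <- exp(-tt / 2.728)
  expect_identical(delayed_conductance(g, tt, t = 3, delay_ms = 5), 0)
  expect_equal(delayed_conductance(g, tt, t = 3, delay_ms = 0), g[tt == 3])
  expect_equal(delayed_conductance(g, tt, t = 7.5, delay_ms = 2.5),
               g[tt == 5])
  gm <- cbind(g, 2 * g)
  expect_equal(delayed_conductance(gm, tt, t = 3, delay_ms = 5), c(0, 0))
  expect_error(delayed_conductance(g, tt, t = 20, delay_ms = 0), "beyond")
  expect_error(delayed_conductance(g, tt, t = 3, delay_ms = -1))
})

test_that("postsynaptic current turns on exactly one delay after the presynaptic spike", {
  for (d in c(0, 5, 50, 110)) {
    net <- motif_network()
    p <- aeif_params(g_exc_nS = 0.5, g_rel = 6, d_exc_ms = d, d_inh_ms = d)
    sim <- aeif_simulate(net, p, zero_state(2),
                         t_end_ms = d + 60,
                         input = c(2 * rheobase_current(2), 0),
                         sample_stride_ms = 0.01)
    t_spike <- sim$spike_trains[[1]][1]
    t_on <- sim$times[which(abs(sim$isyn_mean) > 0)[1]]
    expect_lte(abs((t_on - t_spike) - d), 0.01 + 1e-9)
  }
})

test_that("perturbing the presynaptic neuron affects the target only after the delay", {
  d <- 20
  p <- aeif_params(g_exc_nS = 0.5, g_rel = 6, d_exc_ms = d, d_inh_ms = d)
  net <- motif_network()
  I1 <- 2 * rheobase_current(2)
  base <- aeif_simulate(net, p, zero_state(2), t_end_ms = 120,
                        input = c(I1, 0), sample_stride_ms = 0.01,
                        record_state = TRUE)
  # perturb neuron 1's initial voltage; neuron 2 starts identically
  pert <- aeif_simulate(net, p, list(v0 = c(-65, -70), w0 = c(0, 0),
                                     g0 = c(0, 0)),
                        t_end_ms = 120, input = c(I1, 0),
                        sample_stride_ms = 0.01, record_state = TRUE)
  dv2 <- abs(base$v_trace[, 2] - pert$v_trace[, 2])
  t_first <- min(base$spike_trains[[1]][1], pert$spike_trains[[1]][1])
  before <- base$times < t_first + d - 0.01
  expect_identical(max(dv2[before]), 0)
  expect_gt(max(dv2[!before]), 0)
})

test_that("halving the step changes each spike time by less than one original step per spike", {
  net <- motif_network(a = c(1.95, 2.05), back_edge = TRUE)
  p <- aeif_params(g_exc_nS = 0.3, g_rel = 6, d_exc_ms = 10, d_inh_ms = 10)
  init <- list(v0 = c(-65, -60), w0 = c(10, 30), g0 = c(0, 0))
  I <- 2 * rheobase_current(net$a)
  s1 <- aeif_simulate(net, p, init, t_end_ms = 1000, dt_ms = 0.01, input = I)
  s2 <- aeif_simulate(net, p, init, t_end_ms = 1000, dt_ms = 0.005, input = I)
  for (i in 1:2) {
    a1 <- s1$spike_trains[[i]]
    a2 <- s2$spike_trains[[i]]
    n <- min(length(a1), length(a2))
    expect_gt(n, 5)
    # discretization drift accumulates through the resets: bound per spike
    # (non-strict: detection times are quantized to the coarser grid)
    expect_true(all(abs(a1[1:n] - a2[1:n]) <= 0.01 * seq_len(n) + 1e-9))
  }
})

test_that("spike times are insensitive to the detection threshold relative to the ISI", {
  net <- motif_network()
  net$adjacency[, ] <- 0L
  I <- 2 * rheobase_current(2)
  init <- list(v0 = c(-65, -60), w0 = c(10, 30), g0 = c(0, 0))
  s40 <- aeif_simulate(net, aeif_params(g_exc_nS = 0), init,
                       t_end_ms = 1000, input = I)
  s30 <- aeif_simulate(net, aeif_params(g_exc_nS = 0, V_thres_mV = -30),
                       init, t_end_ms = 1000, input = I)
  a1 <- s40$spike_trains[[1]]
  a2 <- s30$spike_trains[[1]]
  n <- min(length(a1), length(a2))
  expect_identical(length(a1), length(a2))
  # raising the threshold a full 10 mV delays each detection by the extra
  # upstroke traversal time, ~0.1 ms: a small fraction of any ISI
  shift_per_spike <- abs(a2[1:n] - a1[1:n]) / seq_len(n)
  expect_lt(max(shift_per_spike), 0.15)
  expect_lt(max(shift_per_spike) / mean(diff(a1)), 0.01)
})

test_that("simulation is deterministic and spike trains round-trip through text", {
  net <- build_random_network(10, 0.5, seed = 6)
  p <- aeif_params(g_exc_nS = 0.3, g_rel = 6, d_exc_ms = 5, d_inh_ms = 2)
  st <- sample_initial_state(10, seed = 8)
  s1 <- aeif_simulate(net, p, st, t_end_ms = 500)
  s2 <- aeif_simulate(net, p, st, t_end_ms = 500)
  expect_identical(s1$spike_trains, s2$spike_trains)
  expect_identical(s1$isyn_mean, s2$isyn_mean)
  f <- withr::local_tempfile(fileext = ".txt")
  write_spike_trains(s1, f)
  back <- read_spike_trains(f, 10)
  expect_equal(back, s1$spike_trains)
})

test_that("the fixed-step integrator matches an adaptive reference on an uncoupled neuron", {
  p <- aeif_params(g_exc_nS = 0)
  a <- 2
  I <- 2 * rheobase_current(a)
  net <- motif_network(a = c(a, a))
  net$adjacency[, ] <- 0L
  sim <- aeif_simulate(net, p, zero_state(2), t_end_ms = 2000, input = I)
  ref <- aeif_reference_single(p, a, I, -70, 0, 2000)
  s <- sim$spike_trains[[1]]
  expect_identical(length(s), length(ref))
  # within two steps per spike (discretization drift carried through resets)
  expect_true(all(abs(s - ref) <= 0.02 * seq_along(ref)))
})
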