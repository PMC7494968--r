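#' Simulate the delayed-conductance AEIF network
#'
#' Fixed-step integration of the network dynamics: explicit Euler for the
#' membrane potential and adaptation current, exact exponential decay for
#' the synaptic conductances.  At each step, delayed conductances (each
#' presynaptic neuron's conductance lagged by `d_exc_ms` or `d_inh_ms`
#' according to its type, rounded to the nearest step) drive the synaptic
#' currents; any neuron whose potential exceeds `V_thres_mV` is reset
#' (`V -> V_r`, `w -> w + b`, own conductance `g -> g + g_s` with `g_s`
#' typed by its own excitatory/inhibitory label) and its spike time
#' recorded.  The conductance history on `[-max(d), 0]` is identically
#' zero: no neuron has spiked before the simulation starts.
#'
#' Simultaneous spikes interact only after their delays: all resets of a
#' step are applied first, and the post-reset conductance is what enters the
#' delayed view, so with `d = 0` a spike is seen by its targets at the very
#' step it occurs.
#'
#' @param network an [build_random_network()] object.
#' @param params an [aeif_params()] object.
#' @param init an [sample_initial_state()] object (or a list with `v0`,
#'   `w0`, `g0`).
#' @param t_end_ms simulation end time, ms.
#' @param dt_ms integration step, ms (default 0.01).
#' @param input per-neuron constant input currents, pA; defaults to twice
#'   each neuron's rheobase via [input_currents()].
#' @param sample_stride_ms stride for the recorded traces, ms (default 1);
#'   independent of the integration step.
#' @param record_state also record per-neuron V, w, g traces (default
#'   FALSE; the network-mean synaptic current is always recorded).
#' @return an object of class `aeif_sim`: list with `spike_trains` (list of
#'   per-neuron strictly increasing spike times, ms), `times` (sampled
#'   times, ms), `isyn_mean` (network-mean synaptic current at the sampled
#'   times, pA), optional `v_trace`/`w_trace`/`g_trace` matrices (samples x
#'   neurons), `dt_ms`, `t_end_ms`, `params`, `n_neurons`, and the final
#'   state.
#' @examples
#' net <- build_random_network(20, 0.5, seed = 1)
#' st <- sample_initial_state(20, seed = 2)
#' sim <- aeif_simulate(net, aeif_params(d_inh_ms = 5), st, t_end_ms = 500)
#' length(sim$spike_trains[[1]])
#' @export
aeif_simulate <- function(network, params, init,
                          t_end_ms = 10000, dt_ms = 0.01,
                          input = NULL, sample_stride_ms = 1,
                          record_state = FALSE) {
  stopifnot(inherits(params, "aeif_params"))
  n <- network$n_neurons
  if (length(init$v0) != n || length(init$w0) != n || length(init$g0) != n)
    stop("initial state length does not match the network size")
  if (t_end_ms <= 0 || dt_ms <= 0) stop("t_end_ms and dt_ms must be positive")
  if (is.null(input)) input <- input_currents(network, params)
  if (length(input) == 1) input <- rep(input, n)
  if (length(input) != n) stop("input length does not match the network size")

  core <- aeif_integrate_core(
    adjacency = network$adjacency,
    is_exc = network$neuron_type == "exc",
    a = network$a, input = input,
    par = unclass(params),
    v0 = as.numeric(init$v0), w0 = as.numeric(init$w0),
    g0 = as.numeric(init$g0),
    t_end = t_end_ms, dt = dt_ms, sample_stride = sample_stride_ms,
    record_state = record_state)

  structure(c(core, list(
    dt_ms = dt_ms, t_end_ms = t_end_ms, sample_stride_ms = sample_stride_ms,
    n_neurons = n, params = params, input = input,
    network_seed = network$seed, init_seed = init$seed
  )), class = "aeif_sim")
}

#' @export
print.aeif_sim <- function(x, ...) {
  nsp <- vapply(x$spike_trains, length, integer(1))
  cat("AEIF network simulation\n")
  cat(sprintf("  %d neurons, %g ms at dt = %g ms\n", x$n_neurons, x$t_end_ms,
              x$dt_ms))
  cat(sprintf("  spikes: %d total (per neuron: min %d, median %g, max %d)\n",
              sum(nsp), min(nsp), stats::median(nsp), max(nsp)))
  cat(sprintf("  mean synaptic current over run: %.2f pA\n",
              mean(x$isyn_mean)))
  invisible(x)
}

#' Synaptic currents from delayed conductances
#'
#' The per-neuron synaptic current given the current membrane potentials and
#' the delayed presynaptic conductances:
#' `I_i = sum_j (V_rev_j - V_i) A_ij g_j(t - d_j)`,
#' where the reversal potential and delay of each term are those of the
#' presynaptic neuron `j`.  This is the instantaneous coupling law the
#' integrator applies at every step; exposed for testing and for building
#' diagnostics on recorded conductance histories.
#'
#' @param v_now per-neuron membrane potentials at time t, mV.
#' @param delayed_g per-presynaptic-neuron conductances already evaluated at
#'   `t - d_j`, nS.
#' @param network an `aeif_network`.
#' @param params an `aeif_params` (for the reversal potentials).
#' @return per-neuron synaptic currents, pA.
#' @examples
#' net <- build_random_network(10, 0.5, seed = 1)
#' synaptic_current(rep(-70, 10), rep(0, 10), net, aeif_params()) # all zero
#' @export
synaptic_current <- function(v_now, delayed_g, network, params) {
  n <- network$n_neurons
  if (length(v_now) != n || length(delayed_g) != n)
    stop("state vectors do not match the network size")
  v_rev <- ifelse(network$neuron_type == "exc",
                  params$V_rev_exc_mV, params$V_rev_inh_mV)
  # I_i = sum_j A_ij g_j V_rev_j - V_i sum_j A_ij g_j
  drive <- as.numeric(network$adjacency %*% (delayed_g * v_rev))
  shunt <- as.numeric(network$adjacency %*% delayed_g)
  drive - v_now * shunt
}

#' Delayed view of a conductance history
#'
#' Reads a recorded conductance trace at `t - delay`, with the convention
#' that the history is identically zero for times at or before zero (no
#' spiking before the simulation starts).  The lagged time is rounded to
#' the nearest stored grid point.
#'
#' @param g_values conductance samples, nS: a numeric vector (one neuron) or
#'   a matrix (samples x neurons).
#' @param times sample times of `g_values`, ms (uniform grid from 0).
#' @param t current time, ms.
#' @param delay_ms delay, ms (>= 0); `0` returns the value at `t` itself.
#' @return the conductance(s) at `t - delay_ms`; zero when `t - delay_ms <= 0`.
#' @examples
#' tt <- seq(0, 10, 0.5)
#' g <- exp(-tt / 2.728)
#' delayed_conductance(g, tt, t = 3, delay_ms = 5) # 0: still in pre-history
#' delayed_conductance(g, tt, t = 3, delay_ms = 0) # g at 3 ms
#' @export
delayed_conductance <- function(g_values, times, t, delay_ms) {
  if (delay_ms < 0) stop("delay_ms must be nonnegative")
  t_lag <- t - delay_ms
  one <- is.null(dim(g_values))
  if (t_lag <= 0) {
    return(if (one) 0 else rep(0, ncol(g_values)))
  }
  if (t_lag > max(times) + 1e-9) stop("t - delay_ms lies beyond the stored history")
  idx <- which.min(abs(times - t_lag))
  if (one) g_values[idx] else g_values[idx, ]
}

#' Write / read spike trains as plain text
#'
#' Two-column whitespace-delimited text, one spike per line:
#' `neuron_index spike_time_ms`, 0-based neuron indices, sorted by time —
#' the raster-plot source format.
#'
#' @param spike_trains list of per-neuron spike-time vectors (ms), or an
#'   `aeif_sim`.
#' @param file path.
#' @param n_neurons for `read_spike_trains`: total neuron count (neurons
#'   that never fired have no lines in the file).
#' @return `write_spike_trains` returns the input invisibly;
#'   `read_spike_trains` returns a list of per-neuron spike-time vectors.
#' @export
write_spike_trains <- function(spike_trains, file) {
  if (inherits(spike_trains, "aeif_sim")) spike_trains <- spike_trains$spike_trains
  df <- data.frame(
    neuron = rep(seq_along(spike_trains) - 1L,
                 vapply(spike_trains, length, integer(1))),
    time_ms = unlist(spike_trains, use.names = FALSE))
  df <- df[order(df$time_ms, df$neuron), ]
  utils::write.table(df, file, row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(spike_trains)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(file, n_neurons) {
  df <- utils::read.table(file, header = FALSE,
                          col.names = c("neuron", "time_ms"))
  out <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    out[[i]] <- sort(df$time_ms[df$neuron == i - 1L])
  }
  out
}

#' High-accuracy reference integration of a single uncoupled AEIF neuron
#'
#' Adaptive-step integration (lsoda, via deSolve) of the two-variable
#' subthreshold system with event-based threshold detection: integration
#' stops at the root `V = V_thres`, the reset map is applied, and
#' integration resumes.  Serves as an independent oracle for the fixed-step
#' network integrator in the uncoupled case.
#'
#' @param params an `aeif_params`.
#' @param a subthreshold adaptation conductance, nS.
#' @param input constant input current, pA.
#' @param v0,w0 initial conditions (mV, pA).
#' @param t_end_ms end time, ms.
#' @param rtol,atol solver tolerances.
#' @return numeric vector of spike times, ms.
#' @export
aeif_reference_single <- function(params, a, input, v0, w0, t_end_ms,
                                  rtol = 1e-10, atol = 1e-8) {
  deriv <- function(t, y, parms) {
    v <- y[1]; w <- y[2]
    arg <- min((v - params$V_T_mV) / params$delta_T_mV, params$exp_cap)
    dv <- (-params$g_L_nS * (v - params$E_L_mV) +
             params$g_L_nS * params$delta_T_mV * exp(arg) -
             w + input) / params$C_pF
    dw <- (a * (v - params$E_L_mV) - w) / params$tau_w_ms
    list(c(dv, dw))
  }
  rootfun <- function(t, y, parms) y[1] - params$V_thres_mV
  eventfun <- function(t, y, parms) c(params$V_r_mV, y[2] + params$b_pA)

  spikes <- numeric(0)
  t_now <- 0
  y <- c(v0, w0)
  # restart after each reset so the root (an upward crossing) is re-armed
  while (t_now < t_end_ms) {
    sol <- deSolve::lsoda(y, times = c(t_now, t_end_ms), func = deriv,
                          parms = NULL, rootfunc = rootfun,
                          events = list(func = eventfun, root = TRUE,
                                        terminalroot = 1),
                          rtol = rtol, atol = atol, maxsteps = 500000)
    troot <- attr(sol, "troot")
    if (is.null(troot) || length(troot) == 0) break
    t_now <- troot[length(troot)]
    spikes <- c(spikes, t_now)
    y <- c(params$V_r_mV, sol[nrow(sol), 3] + params$b_pA)
  }
  spikes
}
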