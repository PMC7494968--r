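#' Spike phase by linear interpolation between spikes
#'
#' The phase of a neuron at time `t`, defined between consecutive spikes:
#' `Phi(t) = 2 pi m + 2 pi (t - t_m) / (t_{m+1} - t_m)` for
#' `t in [t_m, t_{m+1})`, with `m = 0, 1, 2, ...` counting spikes from the
#' first.  The phase is continuous, nondecreasing, and gains exactly
#' `2 pi` per inter-spike interval.
#'
#' @param spike_times strictly increasing spike times of one neuron, ms
#'   (at least 2).
#' @param t evaluation time(s), ms; must lie within
#'   `[min(spike_times), max(spike_times)]`.
#' @return phase(s) in radians.
#' @examples
#' spike_phase(c(0, 100), 50)        # pi
#' spike_phase(c(0, 100, 200), 100)  # 2 pi
#' @export
spike_phase <- function(spike_times, t) {
  m <- length(spike_times)
  if (m < 2) stop("at least 2 spikes are needed to define a phase")
  if (any(diff(spike_times) <= 0)) stop("spike times must be strictly increasing")
  if (any(t < spike_times[1] | t > spike_times[m]))
    stop("t must lie within the spike-bracketed interval")
  idx <- findInterval(t, spike_times)
  idx[idx == m] <- m - 1 # right endpoint belongs to the last interval
  2 * pi * (idx - 1) +
    2 * pi * (t - spike_times[idx]) /
      (spike_times[idx + 1] - spike_times[idx])
}

#' Time-averaged Kuramoto order parameter on spike phases
#'
#' The modulus of the population-mean phase factor,
#' `r(t) = | (1/N') sum_j exp(i Phi_j(t)) |`, averaged over sample times in
#' the analysis window.  It ranges from 0 to 1 and approaches 1 for
#' synchronous behavior.  Only neurons whose spikes bracket the whole
#' window (first spike at or before `t_ini`, last at or after `t_fin`)
#' have a defined phase throughout and enter the average; their count and
#' the number excluded are reported.
#'
#' When a simulation ends at `t_fin` itself, hardly any neuron has a spike
#' at or beyond the window's right edge even though all fire continually.
#' `window = "clip"` handles this by shrinking the window to the largest
#' sub-interval bracketed by every firing neuron,
#' `[max_j first_j, min_j last_j]` intersected with the request, so that
#' all of them keep a defined phase; the effective window is reported.
#'
#' @param spike_trains list of per-neuron spike-time vectors, ms.
#' @param t_ini_ms,t_fin_ms analysis window, ms (defaults 5000 and 10000).
#' @param stride_ms sampling stride for the time average, ms (default 1).
#' @param window `"strict"` (default): only neurons bracketing the whole
#'   requested window are used; `"clip"`: the window is shrunk as above.
#' @return list with `R_bar` (the time average), `r_t` (instantaneous
#'   values), `times`, `n_used`, `n_excluded`, `window_used_ms`.
#' @examples
#' trains <- rep(list(seq(0, 10000, 50)), 100)
#' order_parameter(trains)$R_bar # exactly 1
#' @export
order_parameter <- function(spike_trains, t_ini_ms = 5000, t_fin_ms = 10000,
                            stride_ms = 1,
                            window = c("strict", "clip")) {
  window <- match.arg(window)
  if (t_fin_ms <= t_ini_ms) stop("t_fin_ms must exceed t_ini_ms")
  if (window == "clip") {
    firing <- spike_trains[vapply(spike_trains, length, integer(1)) >= 2]
    if (length(firing) == 0) stop("no neuron has at least 2 spikes")
    t_ini_ms <- max(t_ini_ms, max(vapply(firing, `[`, numeric(1), 1)))
    t_fin_ms <- min(t_fin_ms,
                    min(vapply(firing, function(s) s[length(s)], numeric(1))))
    if (t_fin_ms <= t_ini_ms)
      stop("clipped window is empty: some neuron fires only outside the window")
  }
  usable <- vapply(spike_trains, function(s) {
    length(s) >= 2 && s[1] <= t_ini_ms && s[length(s)] >= t_fin_ms
  }, logical(1))
  if (!any(usable)) stop("no neuron has spikes bracketing the whole window")
  ts <- seq(t_ini_ms, t_fin_ms, by = stride_ms)
  used <- spike_trains[usable]
  # piecewise-linear phase: knots at spikes, values 2 pi (0, 1, 2, ...)
  z <- rep(0 + 0i, length(ts))
  for (s in used) {
    phi <- stats::approx(s, 2 * pi * (seq_along(s) - 1), xout = ts)$y
    z <- z + exp(1i * phi)
  }
  r_t <- Mod(z) / length(used)
  list(R_bar = mean(r_t), r_t = r_t, times = ts,
       n_used = sum(usable), n_excluded = sum(!usable),
       window_used_ms = c(t_ini_ms, t_fin_ms))
}

#' Inter-spike-interval coefficient of variation
#'
#' Per-neuron CV of the inter-spike intervals (ISI) formed by the spikes
#' falling inside the analysis window, `CV = sd(ISI) / mean(ISI)`, and the
#' network summary `CV_bar`.  Neurons with fewer than 3 spikes in the
#' window (fewer than 2 ISIs) are excluded.  By default `CV_bar` is the
#' mean of per-neuron CVs, which measures irregularity without conflating
#' it with rate heterogeneity across neurons; `average = "pooled"` instead
#' pools all ISIs network-wide before taking sd/mean.  The standard
#' deviation is the population form by default (`sd_type = "sample"`
#' switches to the n-1 denominator).
#'
#' @param spike_trains list of per-neuron spike-time vectors, ms.
#' @param t_ini_ms,t_fin_ms analysis window, ms.
#' @param average `"per_neuron"` (default) or `"pooled"`.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return list with `CV_bar`, per-neuron `cv`, per-neuron `isi_mean` (ms),
#'   `n_used`, `n_excluded`.
#' @examples
#' isi_cv(list(c(0, 1, 4) * 100), 0, 500)$CV_bar # sd/mean of ISIs {100, 300}
#' @export
isi_cv <- function(spike_trains, t_ini_ms = 5000, t_fin_ms = 10000,
                   average = c("per_neuron", "pooled"),
                   sd_type = c("population", "sample")) {
  average <- match.arg(average)
  sd_type <- match.arg(sd_type)
  sdev <- function(x) {
    if (sd_type == "population") sqrt(mean((x - mean(x))^2)) else stats::sd(x)
  }
  isis <- lapply(spike_trains, function(s) {
    s <- s[s >= t_ini_ms & s <= t_fin_ms]
    if (length(s) < 3) NULL else diff(s)
  })
  ok <- !vapply(isis, is.null, logical(1))
  if (!any(ok)) stop("no neuron has at least 3 spikes in the window")
  cv <- rep(NA_real_, length(spike_trains))
  cv[ok] <- vapply(isis[ok], function(x) sdev(x) / mean(x), numeric(1))
  isi_mean <- rep(NA_real_, length(spike_trains))
  isi_mean[ok] <- vapply(isis[ok], mean, numeric(1))
  cv_bar <- if (average == "per_neuron") {
    mean(cv[ok])
  } else {
    pooled <- unlist(isis[ok], use.names = FALSE)
    sdev(pooled) / mean(pooled)
  }
  list(CV_bar = cv_bar, cv = cv, isi_mean = isi_mean,
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Mean firing frequency
#'
#' `F_bar = 1 / ISI_bar`, in Hz, where `ISI_bar` is the network-mean ISI:
#' the average over neurons of each neuron's mean inter-spike interval in
#' the analysis window (ms, converted to Hz).
#'
#' @inheritParams isi_cv
#' @return mean firing frequency, Hz.
#' @examples
#' mean_firing_frequency(list(seq(0, 1000, 100)), 0, 1000) # 10 Hz
#' @export
mean_firing_frequency <- function(spike_trains, t_ini_ms = 5000,
                                  t_fin_ms = 10000) {
  res <- isi_cv(spike_trains, t_ini_ms, t_fin_ms)
  isi_bar_ms <- mean(res$isi_mean[!is.na(res$isi_mean)])
  1000 / isi_bar_ms
}

#' Mean synaptic input over the analysis window
#'
#' Time average (trapezoidal over the stored samples) of the network-mean
#' synaptic current on `[t_ini, t_fin]`.
#'
#' @param times sample times, ms (must cover the window).
#' @param trace network-mean synaptic current at `times`, pA.
#' @param t_ini_ms,t_fin_ms analysis window, ms.
#' @return mean synaptic input, pA.
#' @examples
#' mean_synaptic_input(0:100, rep(2.5, 101), 10, 90) # 2.5
#' @export
mean_synaptic_input <- function(times, trace, t_ini_ms = 5000,
                                t_fin_ms = 10000) {
  if (t_ini_ms < min(times) || t_fin_ms > max(times))
    stop("window lies outside the stored trace")
  keep <- times >= t_ini_ms & times <= t_fin_ms
  tt <- times[keep]
  yy <- trace[keep]
  # close the window exactly if its endpoints fall between samples
  if (tt[1] > t_ini_ms) {
    tt <- c(t_ini_ms, tt)
    yy <- c(stats::approx(times, trace, t_ini_ms)$y, yy)
  }
  nl <- length(tt)
  if (tt[nl] < t_fin_ms) {
    tt <- c(tt, t_fin_ms)
    yy <- c(yy, stats::approx(times, trace, t_fin_ms)$y)
  }
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2) / (t_fin_ms - t_ini_ms)
}

#' Classify the collective activity
#'
#' Pattern by the CV rule — burst when `CV_bar >= 0.5`, spike when
#' `CV_bar < 0.5` — and synchronization state by an order-parameter
#' threshold: synchronous when `R_bar >= sync_threshold`.  The 0.5 CV bound
#' is the field's spike/burst rule; the synchronization cutoff (default
#' 0.9) is a map-classification convention.
#'
#' @param R_bar time-averaged order parameter.
#' @param CV_bar mean ISI coefficient of variation.
#' @param sync_threshold order-parameter cutoff (default 0.9).
#' @param cv_threshold spike/burst cutoff (default 0.5).
#' @return list with `pattern` (`"spike"`/`"burst"`) and `sync_state`
#'   (`"synchronous"`/`"desynchronous"`).
#' @examples
#' classify_activity(1.0, 0.2)  # synchronous spikes
#' classify_activity(0.3, 0.7)  # desynchronous bursts
#' @export
classify_activity <- function(R_bar, CV_bar, sync_threshold = 0.9,
                              cv_threshold = 0.5) {
  list(pattern = if (CV_bar >= cv_threshold) "burst" else "spike",
       sync_state = if (R_bar >= sync_threshold) "synchronous"
                    else "desynchronous")
}

#' Full diagnostics of a simulation
#'
#' Computes the four summary measures on the analysis window — the
#' time-averaged Kuramoto order parameter `R_bar`, the mean ISI coefficient
#' of variation `CV_bar`, the mean firing frequency `F_bar` (Hz), and the
#' mean synaptic input `Is_bar` (pA) — and classifies the activity
#' (spike/burst by the 0.5 CV rule, synchronous/desynchronous by the
#' order-parameter threshold).
#'
#' @param sim an [aeif_simulate()] result.
#' @param t_ini_ms,t_fin_ms analysis window, ms (defaults 5000 and 10000).
#' @param stride_ms sampling stride for the order-parameter average, ms.
#' @param sync_threshold order-parameter cutoff for the synchrony label.
#' @param cv_average,cv_sd passed to [isi_cv()].
#' @return an object of class `aeif_diagnostics`: list with `R_bar`,
#'   `CV_bar`, `F_bar_Hz`, `Is_bar_pA`, `pattern`, `sync_state`,
#'   `window_ms`, `n_used_R`, `n_excluded_R`, `n_used_cv`.
#' @export
diagnose <- function(sim, t_ini_ms = 5000, t_fin_ms = 10000, stride_ms = 1,
                     sync_threshold = 0.9,
                     cv_average = "per_neuron", cv_sd = "population") {
  if (t_fin_ms > sim$t_end_ms) stop("analysis window exceeds the simulated span")
  op <- order_parameter(sim$spike_trains, t_ini_ms, t_fin_ms, stride_ms,
                        window = "clip")
  cv <- isi_cv(sim$spike_trains, t_ini_ms, t_fin_ms,
               average = cv_average, sd_type = cv_sd)
  fbar <- mean_firing_frequency(sim$spike_trains, t_ini_ms, t_fin_ms)
  isb <- mean_synaptic_input(sim$times, sim$isyn_mean, t_ini_ms, t_fin_ms)
  cls <- classify_activity(op$R_bar, cv$CV_bar, sync_threshold)
  structure(list(
    R_bar = op$R_bar, CV_bar = cv$CV_bar, F_bar_Hz = fbar, Is_bar_pA = isb,
    pattern = cls$pattern, sync_state = cls$sync_state,
    window_ms = c(t_ini_ms, t_fin_ms),
    n_used_R = op$n_used, n_excluded_R = op$n_excluded,
    n_used_cv = cv$n_used
  ), class = "aeif_diagnostics")
}

#' @export
print.aeif_diagnostics <- function(x, ...) {
  cat("Synchronization diagnostics on [",
      x$window_ms[1] / 1000, ", ", x$window_ms[2] / 1000, "] s\n", sep = "")
  cat(sprintf("  R_bar  = %.4f   (%s, %d neurons used)\n", x$R_bar,
              x$sync_state, x$n_used_R))
  cat(sprintf("  CV_bar = %.4f   (%s pattern)\n", x$CV_bar, x$pattern))
  cat(sprintf("  F_bar  = %.3f Hz\n", x$F_bar_Hz))
  cat(sprintf("  Is_bar = %.3f pA\n", x$Is_bar_pA))
  invisible(x)
}

#' One-row summary of a diagnostics object
#'
#' @param x an `aeif_diagnostics`.
#' @param row.names,optional,... passed on conventionally (unused).
#' @return a one-row data.frame with `R`, `CV`, `F_Hz`, `Is_pA`, `pattern`,
#'   `sync_state`, `n_used`.
#' @export
as.data.frame.aeif_diagnostics <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(R = x$R_bar, CV = x$CV_bar, F_Hz = x$F_bar_Hz,
             Is_pA = x$Is_bar_pA, pattern = x$pattern,
             sync_state = x$sync_state, n_used = x$n_used_R)
}
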