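#' Raster plot of spike times
#'
#' Spike times (x) by neuron index (y); synchronous activity shows as
#' aligned vertical stripes.
#'
#' @param sim an `aeif_sim`, or a list of per-neuron spike-time vectors.
#' @param window_ms optional `c(from, to)` restriction, ms.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data.frame.
#' @export
plot_raster <- function(sim, window_ms = NULL, ...) {
  trains <- if (inherits(sim, "aeif_sim")) sim$spike_trains else sim
  df <- data.frame(
    time_ms = unlist(trains, use.names = FALSE),
    neuron = rep(seq_along(trains), vapply(trains, length, integer(1))))
  if (!is.null(window_ms))
    df <- df[df$time_ms >= window_ms[1] & df$time_ms <= window_ms[2], ]
  graphics::plot(df$time_ms, df$neuron, pch = ".", cex = 2,
                 xlab = "time (ms)", ylab = "neuron index", ...)
  invisible(df)
}

#' Network-mean synaptic current trace
#'
#' @param sim an `aeif_sim`.
#' @param window_ms optional `c(from, to)` restriction, ms.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data.frame.
#' @export
plot_mean_current <- function(sim, window_ms = NULL, ...) {
  keep <- if (is.null(window_ms)) rep(TRUE, length(sim$times))
          else sim$times >= window_ms[1] & sim$times <= window_ms[2]
  graphics::plot(sim$times[keep], sim$isyn_mean[keep], type = "l",
                 xlab = "time (ms)", ylab = "mean synaptic current (pA)", ...)
  invisible(data.frame(time_ms = sim$times[keep],
                       isyn_pA = sim$isyn_mean[keep]))
}

#' Color map of a diagnostic over the delay plane
#'
#' @param grid an [sweep_delays()] result.
#' @param measure one of `"R"`, `"CV"`, `"F_Hz"`, `"Is_pA"`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot_delay_map <- function(grid, measure = c("R", "CV", "F_Hz", "Is_pA"),
                           ...) {
  measure <- match.arg(measure)
  m <- grid_matrix(grid, measure)
  graphics::image(grid$d_exc_values, grid$d_inh_values, m,
                  xlab = "excitatory delay (ms)",
                  ylab = "inhibitory delay (ms)",
                  main = measure,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(m)
}
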