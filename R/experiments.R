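#' Scenario configuration
#'
#' Bundles every knob of a simulation scenario: network generation, model
#' parameters, run length, analysis window, number of realizations and the
#' master seed.  Each realization redraws the initial conditions and the
#' per-neuron adaptation levels from realization-specific sub-seeds; the
#' wiring is drawn once per scenario unless `redraw_wiring = TRUE`.
#'
#' @param g_exc_nS,g_rel,d_exc_ms,d_inh_ms coupling parameters, passed to
#'   [aeif_params()] together with `...`.
#' @param n_neurons,connection_probability,excitatory_fraction,a_range
#'   network generation parameters, see [build_random_network()].
#' @param v_range,w_range initial-condition intervals (mV, pA).
#' @param t_end_ms simulation length, ms.
#' @param window_ms analysis window `c(t_ini, t_fin)`, ms.
#' @param dt_ms integration step, ms.
#' @param sample_stride_ms trace sampling stride, ms.
#' @param n_realizations realizations (independent initial conditions) per
#'   scenario (default 10).
#' @param master_seed integer master seed.
#' @param redraw_wiring redraw the adjacency for every realization
#'   (default FALSE: fixed wiring, new initial conditions and adaptation).
#' @param input_per_neuron per-neuron rheobase-based inputs (default TRUE).
#' @param sync_threshold order-parameter cutoff for the synchrony label.
#' @param ... further arguments to [aeif_params()].
#' @return an object of class `aeif_scenario` (a named list).
#' @examples
#' cfg <- scenario_config(g_exc_nS = 0.2, g_rel = 6, d_exc_ms = 75,
#'                        d_inh_ms = 5, n_realizations = 3, t_end_ms = 2000,
#'                        window_ms = c(1000, 2000))
#' @export
scenario_config <- function(g_exc_nS = 0.2, g_rel = 6,
                            d_exc_ms = 0, d_inh_ms = 0,
                            n_neurons = 100, connection_probability = 0.5,
                            excitatory_fraction = 0.8, a_range = c(1.9, 2.1),
                            v_range = c(-70, -50), w_range = c(0, 80),
                            t_end_ms = 10000, window_ms = c(5000, 10000),
                            dt_ms = 0.01, sample_stride_ms = 1,
                            n_realizations = 10, master_seed = 1,
                            redraw_wiring = FALSE, input_per_neuron = TRUE,
                            sync_threshold = 0.9, ...) {
  if (t_end_ms < window_ms[2])
    stop("t_end_ms must reach the end of the analysis window")
  if (n_realizations < 1) stop("n_realizations must be at least 1")
  structure(list(
    g_exc_nS = g_exc_nS, g_rel = g_rel,
    d_exc_ms = d_exc_ms, d_inh_ms = d_inh_ms,
    n_neurons = n_neurons, connection_probability = connection_probability,
    excitatory_fraction = excitatory_fraction, a_range = a_range,
    v_range = v_range, w_range = w_range,
    t_end_ms = t_end_ms, window_ms = window_ms,
    dt_ms = dt_ms, sample_stride_ms = sample_stride_ms,
    n_realizations = n_realizations, master_seed = master_seed,
    redraw_wiring = redraw_wiring, input_per_neuron = input_per_neuron,
    sync_threshold = sync_threshold,
    params_extra = list(...)
  ), class = "aeif_scenario")
}

scenario_params <- function(config, d_exc_ms = NULL, d_inh_ms = NULL) {
  do.call(aeif_params, c(list(
    g_exc_nS = config$g_exc_nS, g_rel = config$g_rel,
    d_exc_ms = if (is.null(d_exc_ms)) config$d_exc_ms else d_exc_ms,
    d_inh_ms = if (is.null(d_inh_ms)) config$d_inh_ms else d_inh_ms
  ), config$params_extra))
}

#' Run a scenario over independent realizations
#'
#' Simulates and diagnoses `n_realizations` runs of one scenario.  Each
#' realization draws fresh initial conditions and adaptation levels (and,
#' with `redraw_wiring`, fresh wiring) from seeds derived deterministically
#' from the master seed, so the full set is reproducible and individual
#' realizations can be recomputed in isolation.
#'
#' @param config an [scenario_config()] object.
#' @param d_exc_ms,d_inh_ms optional delay overrides (used by
#'   [sweep_delays()]).
#' @param keep_sims keep the full simulation objects (default FALSE: only
#'   diagnostics are retained).
#' @return an object of class `aeif_scenario_result`: list with
#'   `realizations` (data.frame, one row per realization: `realization`,
#'   `seed`, `R`, `CV`, `F_Hz`, `Is_pA`, `pattern`, `sync_state`,
#'   `n_used`), `mean` (named numeric: mean `R`, `CV`, `F_Hz`, `Is_pA`),
#'   `diagnostics` (list), optional `sims`, and the config.
#' @export
run_scenario <- function(config, d_exc_ms = NULL, d_inh_ms = NULL,
                         keep_sims = FALSE) {
  stopifnot(inherits(config, "aeif_scenario"))
  params <- scenario_params(config, d_exc_ms, d_inh_ms)
  cell <- c(round(params$d_exc_ms * 1000), round(params$d_inh_ms * 1000))
  net0 <- build_random_network(config$n_neurons,
                               config$connection_probability,
                               config$excitatory_fraction, config$a_range,
                               seed = derive_seed(config$master_seed, "wiring"))
  diags <- vector("list", config$n_realizations)
  sims <- if (keep_sims) vector("list", config$n_realizations) else NULL
  rows <- vector("list", config$n_realizations)
  for (k in seq_len(config$n_realizations)) {
    seed_k <- derive_seed(config$master_seed, "cell", cell[1], cell[2], k)
    net <- if (config$redraw_wiring) {
      build_random_network(config$n_neurons, config$connection_probability,
                           config$excitatory_fraction, config$a_range,
                           seed = seed_k)
    } else {
      n <- net0
      n$a <- sample_heterogeneity(config$n_neurons, config$a_range,
                                  seed = derive_seed(seed_k, "adaptation"))
      n
    }
    init <- sample_initial_state(config$n_neurons, config$v_range,
                                 config$w_range,
                                 seed = derive_seed(seed_k, "init"))
    input <- input_currents(net, params, per_neuron = config$input_per_neuron)
    sim <- aeif_simulate(net, params, init, t_end_ms = config$t_end_ms,
                         dt_ms = config$dt_ms, input = input,
                         sample_stride_ms = config$sample_stride_ms)
    dg <- diagnose(sim, config$window_ms[1], config$window_ms[2],
                   sync_threshold = config$sync_threshold)
    diags[[k]] <- dg
    if (keep_sims) sims[[k]] <- sim
    rows[[k]] <- cbind(data.frame(realization = k, seed = seed_k),
                       as.data.frame(dg))
  }
  realizations <- do.call(rbind, rows)
  structure(list(
    realizations = realizations,
    mean = c(R = mean(realizations$R), CV = mean(realizations$CV),
             F_Hz = mean(realizations$F_Hz),
             Is_pA = mean(realizations$Is_pA)),
    diagnostics = diags, sims = sims,
    d_exc_ms = params$d_exc_ms, d_inh_ms = params$d_inh_ms,
    config = config
  ), class = "aeif_scenario_result")
}

#' @export
print.aeif_scenario_result <- function(x, ...) {
  cat(sprintf("Scenario: g_exc = %g nS, g = %g, d_exc = %g ms, d_inh = %g ms\n",
              x$config$g_exc_nS, x$config$g_rel, x$d_exc_ms, x$d_inh_ms))
  cat(sprintf("  %d realization(s); means: R = %.4f, CV = %.4f, F = %.2f Hz, Is = %.2f pA\n",
              nrow(x$realizations), x$mean["R"], x$mean["CV"],
              x$mean["F_Hz"], x$mean["Is_pA"]))
  invisible(x)
}

#' Sweep the excitatory/inhibitory delay plane
#'
#' Runs [run_scenario()] on every cell of the `d_exc x d_inh` grid and
#' aggregates per-cell means of the four diagnostics over realizations.
#' Realization seeds are derived from (master seed, cell delays,
#' realization index), so extending the grid never changes existing cells.
#' With `progress_file` set, per-realization rows are appended to a CSV as
#' they complete and a re-run resumes from the finished cells.
#'
#' @param config an [scenario_config()] object (its `d_exc_ms`/`d_inh_ms`
#'   are ignored in favor of the grid axes).
#' @param d_exc_values,d_inh_values strictly increasing axis values, ms.
#' @param progress_file optional CSV path for append-and-resume.
#' @param verbose print one line per cell.
#' @return an object of class `aeif_delay_grid`: list with `long`
#'   (data.frame: `d_exc_ms`, `d_inh_ms`, `realization`, `R`, `CV`,
#'   `F_Hz`, `Is_pA`), `cells` (data.frame of per-cell means with
#'   realization counts and labels), the axes, and the config.
#' @export
sweep_delays <- function(config, d_exc_values, d_inh_values,
                         progress_file = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "aeif_scenario"))
  if (length(d_exc_values) == 0 || length(d_inh_values) == 0)
    stop("delay axes must be nonempty")
  if (is.unsorted(d_exc_values, strictly = TRUE) ||
      is.unsorted(d_inh_values, strictly = TRUE))
    stop("delay axes must be strictly increasing")

  done <- NULL
  if (!is.null(progress_file) && file.exists(progress_file))
    done <- utils::read.csv(progress_file)

  long <- list()
  for (dx in d_exc_values) {
    for (dy in d_inh_values) {
      if (!is.null(done)) {
        prev <- done[abs(done$d_exc_ms - dx) < 1e-9 &
                     abs(done$d_inh_ms - dy) < 1e-9, ]
        if (nrow(prev) >= config$n_realizations) {
          long[[length(long) + 1]] <- prev[seq_len(config$n_realizations), ]
          next
        }
      }
      res <- run_scenario(config, d_exc_ms = dx, d_inh_ms = dy)
      rows <- data.frame(d_exc_ms = dx, d_inh_ms = dy,
                         realization = res$realizations$realization,
                         R = res$realizations$R, CV = res$realizations$CV,
                         F_Hz = res$realizations$F_Hz,
                         Is_pA = res$realizations$Is_pA)
      long[[length(long) + 1]] <- rows
      if (!is.null(progress_file))
        utils::write.table(rows, progress_file, append = file.exists(progress_file),
                           col.names = !file.exists(progress_file),
                           row.names = FALSE, sep = ",")
      if (verbose)
        message(sprintf("cell d_exc = %g, d_inh = %g: R = %.3f, CV = %.3f",
                        dx, dy, mean(rows$R), mean(rows$CV)))
    }
  }
  long <- do.call(rbind, long)
  cells <- stats::aggregate(cbind(R, CV, F_Hz, Is_pA) ~ d_exc_ms + d_inh_ms,
                            long, mean)
  counts <- stats::aggregate(realization ~ d_exc_ms + d_inh_ms, long, length)
  names(counts)[3] <- "n_realizations"
  cells <- merge(cells, counts)
  labs <- mapply(function(R, CV) classify_activity(R, CV,
                                                   config$sync_threshold),
                 cells$R, cells$CV, SIMPLIFY = FALSE)
  cells$pattern <- vapply(labs, `[[`, character(1), "pattern")
  cells$sync_state <- vapply(labs, `[[`, character(1), "sync_state")
  cells <- cells[order(cells$d_exc_ms, cells$d_inh_ms), ]
  rownames(cells) <- NULL
  structure(list(long = long, cells = cells,
                 d_exc_values = d_exc_values, d_inh_values = d_inh_values,
                 config = config), class = "aeif_delay_grid")
}

#' @export
print.aeif_delay_grid <- function(x, ...) {
  cat(sprintf("Delay-plane sweep: %d x %d cells, %d realization(s) each\n",
              length(x$d_exc_values), length(x$d_inh_values),
              x$config$n_realizations))
  print(x$cells)
  invisible(x)
}

#' Per-measure wide table of a delay sweep
#'
#' @param grid an [sweep_delays()] result.
#' @param measure one of `"R"`, `"CV"`, `"F_Hz"`, `"Is_pA"`.
#' @return a matrix with `d_exc` on rows and `d_inh` on columns.
#' @export
grid_matrix <- function(grid, measure = c("R", "CV", "F_Hz", "Is_pA")) {
  measure <- match.arg(measure)
  m <- matrix(NA_real_, length(grid$d_exc_values), length(grid$d_inh_values),
              dimnames = list(d_exc_ms = grid$d_exc_values,
                              d_inh_ms = grid$d_inh_values))
  for (r in seq_len(nrow(grid$cells))) {
    i <- match(grid$cells$d_exc_ms[r], grid$d_exc_values)
    j <- match(grid$cells$d_inh_ms[r], grid$d_inh_values)
    m[i, j] <- grid$cells[[measure]][r]
  }
  m
}

#' Read / write a scenario configuration as a key-value file
#'
#' Plain-text YAML with units embedded in the key names (`*_ms`, `*_nS`,
#' `*_mV`, `*_pA`); the single source of truth for command-line runs.
#'
#' @param config an `aeif_scenario`.
#' @param path file path.
#' @return `read_scenario_config` returns an `aeif_scenario`.
#' @export
write_scenario_config <- function(config, path) {
  x <- unclass(config)
  x$params_extra <- if (length(x$params_extra)) x$params_extra else NULL
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  extra <- x$params_extra
  x$params_extra <- NULL
  do.call(scenario_config, c(x, extra))
}

#' Preset scenarios of the delay study
#'
#' Named reference parameter points of the delay analysis: the weak-coupling
#' regime
#' (`g_exc = 0.2 nS`, `g = 6`) with a short inhibitory delay and excitatory
#' delays around the synchronization window (65/75/85 ms), the same regime
#' probed along the inhibitory-delay axis, and the strong-coupling regime
#' (`g_exc = 0.8 nS`, `g = 6`) at four delay points spanning desynchronized
#' spikes, synchronized bursts, and synchronized spikes.
#'
#' @param name preset name; with no argument, all presets are returned.
#' @param ... overrides passed to [scenario_config()] (e.g.
#'   `n_realizations`, `master_seed`).
#' @return a list of `aeif_scenario` objects (or a single one when `name`
#'   is given and the preset is a single point).
#' @export
scenario_presets <- function(name = c("weak_dexc_probe", "weak_dinh_probe",
                                      "weak_mid_dinh", "strong_points"),
                             ...) {
  name <- match.arg(name)
  mk <- function(gx, g, dx, dy)
    scenario_config(g_exc_nS = gx, g_rel = g, d_exc_ms = dx, d_inh_ms = dy,
                    ...)
  switch(name,
    weak_dexc_probe = lapply(c(65, 75, 85),
                             function(dx) mk(0.2, 6, dx, 5)),
    weak_dinh_probe = lapply(c(70, 60, 10),
                             function(dy) mk(0.2, 6, 75, dy)),
    weak_mid_dinh = lapply(c(65, 75, 85),
                           function(dx) mk(0.2, 6, dx, 30)),
    strong_points = list(
      both_zero = mk(0.8, 6, 0, 0),
      inh_only = mk(0.8, 6, 0, 50),
      mixed = mk(0.8, 6, 70, 50),
      long_exc = mk(0.8, 6, 110, 50)))
}
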