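#' Build a random directed excitatory/inhibitory network
#'
#' Samples a directed Erdos-Renyi adjacency matrix without self-connections:
#' each ordered pair `(i, j)`, `i != j`, is connected independently with the
#' given probability.  Neurons are split into a fixed excitatory majority and
#' inhibitory minority (Dale's principle: a neuron's outgoing synapses all
#' carry its own type).  Each neuron is guaranteed at least one incident
#' connection (incoming or outgoing): any fully isolated neuron receives one
#' randomly drawn outgoing edge after the Bernoulli draw.  Per-neuron
#' subthreshold adaptation conductances are drawn uniformly from `a_range`.
#'
#' The adjacency convention is `adjacency[i, j] == 1` when presynaptic neuron
#' `j` projects to postsynaptic neuron `i`.  Neuron indices are fixed: neurons
#' `1..n_exc` are excitatory and the remainder inhibitory, where
#' `n_exc = round(excitatory_fraction * n_neurons)`; only the wiring and the
#' parameter draws are random.  Independent sub-streams derived from `seed`
#' drive the wiring and the adaptation draw, so each can be varied in
#' isolation (see [derive_seed()]).
#'
#' @param n_neurons number of neurons (>= 2).
#' @param connection_probability probability of each directed edge, in (0, 1].
#' @param excitatory_fraction fraction of excitatory neurons (default 0.8).
#' @param a_range interval (nS) for the uniform subthreshold adaptation draw.
#' @param seed integer master seed.
#' @return an object of class `aeif_network`: a list with `n_neurons`,
#'   `adjacency` (integer matrix), `neuron_type` (character,
#'   `"exc"`/`"inh"`), `a` (numeric, nS), `connection_probability`,
#'   `n_edges`, `n_edges_pre_repair`, `n_repaired`, `seed`.
#' @examples
#' net <- build_random_network(100, 0.5, seed = 1)
#' net
#' connection_probability_of(net$n_edges, net$n_neurons)
#' @export
build_random_network <- function(n_neurons = 100, connection_probability = 0.5,
                                 excitatory_fraction = 0.8,
                                 a_range = c(1.9, 2.1), seed = 1) {
  if (n_neurons < 2) stop("n_neurons must be at least 2")
  if (connection_probability <= 0 || connection_probability > 1)
    stop("connection_probability must lie in (0, 1]")
  if (excitatory_fraction < 0 || excitatory_fraction > 1)
    stop("excitatory_fraction must lie in [0, 1]")

  n <- as.integer(n_neurons)
  set.seed(derive_seed(seed, "wiring"))
  adjacency <- matrix(stats::rbinom(n * n, 1L, connection_probability), n, n)
  diag(adjacency) <- 0L
  n_edges_pre <- sum(adjacency)

  # minimum-degree repair: isolated neurons get one random outgoing edge
  isolated <- which(rowSums(adjacency) + colSums(adjacency) == 0)
  for (j in isolated) {
    target <- sample(setdiff(seq_len(n), j), 1L)
    adjacency[target, j] <- 1L
  }

  n_exc <- as.integer(round(excitatory_fraction * n))
  neuron_type <- c(rep("exc", n_exc), rep("inh", n - n_exc))

  a <- sample_heterogeneity(n, a_range, seed = derive_seed(seed, "adaptation"))

  structure(list(
    n_neurons = n,
    adjacency = adjacency,
    neuron_type = neuron_type,
    a = a,
    connection_probability = connection_probability,
    n_edges = sum(adjacency),
    n_edges_pre_repair = n_edges_pre,
    n_repaired = length(isolated),
    seed = seed
  ), class = "aeif_network")
}

#' @export
print.aeif_network <- function(x, ...) {
  cat("Random directed E/I network\n")
  cat(sprintf("  neurons: %d (%d excitatory, %d inhibitory)\n", x$n_neurons,
              sum(x$neuron_type == "exc"), sum(x$neuron_type == "inh")))
  cat(sprintf("  edges: %d (density %.4f, target probability %.3f)\n",
              x$n_edges, connection_probability_of(x$n_edges, x$n_neurons),
              x$connection_probability))
  cat(sprintf("  adaptation a: [%.3f, %.3f] nS\n", min(x$a), max(x$a)))
  invisible(x)
}

#' Empirical connection probability of a directed network
#'
#' The connection probability implied by an edge count: the number of edges
#' divided by the number of possible directed connections `N (N - 1)`
#' (self-connections excluded).
#'
#' @param n_edges total number of directed edges.
#' @param n_neurons number of neurons (>= 2).
#' @return the edge density, a fraction in `[0, 1]`.
#' @examples
#' connection_probability_of(4950, 100) # 0.5
#' @export
connection_probability_of <- function(n_edges, n_neurons) {
  if (n_neurons < 2) stop("n_neurons must be at least 2")
  n_max <- n_neurons * (n_neurons - 1)
  if (n_edges < 0 || n_edges > n_max)
    stop("n_edges must lie in [0, n_neurons * (n_neurons - 1)]")
  n_edges / n_max
}

#' Sample per-neuron subthreshold adaptation conductances
#'
#' Draws i.i.d. uniform values on `a_range` (nS), the per-neuron level of
#' subthreshold adaptation entering the adaptation-current dynamics.
#'
#' @param n_neurons number of values to draw.
#' @param a_range numeric length-2 interval (nS), lower <= upper.
#' @param seed integer seed.
#' @return numeric vector of length `n_neurons`.
#' @export
sample_heterogeneity <- function(n_neurons, a_range = c(1.9, 2.1), seed = 1) {
  stopifnot(length(a_range) == 2)
  if (a_range[1] > a_range[2]) stop("a_range bounds are reversed")
  set.seed(seed)
  stats::runif(n_neurons, a_range[1], a_range[2])
}

#' Sample random initial conditions
#'
#' Membrane potentials uniform on `v_range` (mV), adaptation currents uniform
#' on `w_range` (pA), and all synaptic conductances zero.  Together with the
#' integrator's zero conductance pre-history on `[-max(d), 0]` this realizes
#' an initial profile in which no neuron has recently spiked.
#'
#' @param n_neurons number of neurons.
#' @param v_range initial membrane potential interval, mV.
#' @param w_range initial adaptation current interval, pA.
#' @param seed integer seed.
#' @return an object of class `aeif_state`: list with numeric vectors `v0`
#'   (mV), `w0` (pA), `g0` (nS, all zero), and `seed`.
#' @examples
#' st <- sample_initial_state(100, seed = 42)
#' range(st$v0)
#' @export
sample_initial_state <- function(n_neurons, v_range = c(-70, -50),
                                 w_range = c(0, 80), seed = 1) {
  stopifnot(length(v_range) == 2, length(w_range) == 2)
  if (v_range[1] > v_range[2] || w_range[1] > w_range[2])
    stop("interval bounds are reversed")
  set.seed(seed)
  structure(list(
    v0 = stats::runif(n_neurons, v_range[1], v_range[2]),
    w0 = stats::runif(n_neurons, w_range[1], w_range[2]),
    g0 = rep(0, n_neurons),
    seed = seed
  ), class = "aeif_state")
}

#' Write / read a network as plain text
#'
#' The adjacency is exported as a directed edge list with one edge per line,
#' `presynaptic_index postsynaptic_index` (0-based), and the neuron table
#' (index, type, a_nS) as a tab-separated file.
#'
#' @param network an `aeif_network`.
#' @param edge_file path for the edge list.
#' @param neuron_file path for the neuron table.
#' @return `write_network` returns the network invisibly; `read_network`
#'   returns an `aeif_network` (with `connection_probability` set to the
#'   empirical density and no repair metadata).
#' @export
write_network <- function(network, edge_file, neuron_file) {
  idx <- which(network$adjacency == 1L, arr.ind = TRUE)
  # column = presynaptic, row = postsynaptic; 0-based on disk
  edges <- data.frame(pre = idx[, 2] - 1L, post = idx[, 1] - 1L)
  edges <- edges[order(edges$pre, edges$post), ]
  utils::write.table(edges, edge_file, row.names = FALSE, col.names = FALSE,
                     sep = " ")
  neurons <- data.frame(index = seq_len(network$n_neurons) - 1L,
                        type = network$neuron_type, a_nS = network$a)
  utils::write.table(neurons, neuron_file, row.names = FALSE, sep = "\t",
                     quote = FALSE)
  invisible(network)
}

#' @rdname write_network
#' @export
read_network <- function(edge_file, neuron_file) {
  neurons <- utils::read.table(neuron_file, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  n <- nrow(neurons)
  adjacency <- matrix(0L, n, n)
  edges <- utils::read.table(edge_file, header = FALSE,
                             col.names = c("pre", "post"))
  adjacency[cbind(edges$post + 1L, edges$pre + 1L)] <- 1L
  structure(list(
    n_neurons = n,
    adjacency = adjacency,
    neuron_type = neurons$type,
    a = neurons$a_nS,
    connection_probability = connection_probability_of(sum(adjacency), n),
    n_edges = sum(adjacency),
    n_edges_pre_repair = NA_integer_,
    n_repaired = NA_integer_,
    seed = NA_integer_
  ), class = "aeif_network")
}
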