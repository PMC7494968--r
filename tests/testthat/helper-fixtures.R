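# Small fixtures and independent brute-force oracles used across the suite.

# two-neuron motif: neuron 1 projects to neuron 2 (and optionally back)
motif_network <- function(a = c(2, 2), back_edge = FALSE,
                          type = c("exc", "inh")) {
  net <- build_random_network(2, 0.5, seed = 1)
  net$adjacency[, ] <- 0L
  net$adjacency[2, 1] <- 1L
  if (back_edge) net$adjacency[1, 2] <- 1L
  net$neuron_type <- type
  net$a <- a
  net
}

zero_state <- function(n, v0 = -70, w0 = 0, g0 = 0) {
  list(v0 = rep(v0, length.out = n), w0 = rep(w0, length.out = n),
       g0 = rep(g0, length.out = n), seed = NA_integer_)
}

# direct evaluation of the time-averaged order parameter from the phase
# formula, one neuron and one sample time at a time
naive_order_parameter <- function(spike_trains, t_ini, t_fin, stride) {
  ts <- seq(t_ini, t_fin, by = stride)
  usable <- Filter(function(s) length(s) >= 2 && s[1] <= t_ini &&
                     s[length(s)] >= t_fin, spike_trains)
  r <- numeric(length(ts))
  for (k in seq_along(ts)) {
    z <- 0 + 0i
    for (s in usable) {
      m <- max(which(s <= ts[k]))
      if (m == length(s)) m <- m - 1
      phi <- 2 * pi * (m - 1) + 2 * pi * (ts[k] - s[m]) / (s[m + 1] - s[m])
      z <- z + exp(1i * phi)
    }
    r[k] <- Mod(z) / length(usable)
  }
  mean(r)
}

naive_cv_bar <- function(spike_trains, t_ini, t_fin) {
  cvs <- c()
  for (s in spike_trains) {
    s <- s[s >= t_ini & s <= t_fin]
    if (length(s) < 3) next
    isi <- diff(s)
    cvs <- c(cvs, sqrt(mean((isi - mean(isi))^2)) / mean(isi))
  }
  mean(cvs)
}

naive_f_bar <- function(spike_trains, t_ini, t_fin) {
  means <- c()
  for (s in spike_trains) {
    s <- s[s >= t_ini & s <= t_fin]
    if (length(s) < 3) next
    means <- c(means, mean(diff(s)))
  }
  1000 / mean(means)
}

naive_trapz_mean <- function(times, trace, t_ini, t_fin) {
  keep <- times >= t_ini & times <= t_fin
  tt <- times[keep]; yy <- trace[keep]
  tot <- 0
  for (k in seq_len(length(tt) - 1))
    tot <- tot + (tt[k + 1] - tt[k]) * (yy[k] + yy[k + 1]) / 2
  tot / (t_fin - t_ini)
}

# brute-force rheobase: largest input for which the subthreshold system
# (with w on its nullcline) still has a fixed point, by scanning the
# stationary input curve I(V) over a fine grid
bruteforce_rheobase <- function(a, g_L = 12, E_L = -70, V_T = -50,
                                delta_T = 2) {
  v <- seq(E_L - 10, V_T + 20, by = 1e-4)
  iv <- (g_L + a) * (v - E_L) - g_L * delta_T * exp((v - V_T) / delta_T)
  max(iv)
}
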