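#' AEIF model and coupling parameters
#'
#' Constructs the parameter set of the adaptive exponential
#' integrate-and-fire (AEIF) network with conductance-based delayed
#' synapses.  Defaults are the package's standard set: C = 200 pF, g_L = 12 nS,
#' E_L = -70 mV, Delta_T = 2 mV, V_T = -50 mV, tau_w = 300 ms, b = 70 pA,
#' V_r = -58 mV, tau_s = 2.728 ms, excitatory reversal 0 mV, inhibitory
#' reversal -80 mV.  The inhibitory conductance is tied to the excitatory
#' one through the relative inhibitory conductance `g_rel = g_inh / g_exc`.
#'
#' The unit system is closed (mV, ms, pA, nS, pF): nS x mV = pA and
#' pF x mV / ms = pA, so no hidden conversion factors appear anywhere.
#'
#' The numerical spike-detection threshold `V_thres` is not part of the
#' biophysics: once the membrane potential passes it, the exponential term
#' diverges so fast that spike times are insensitive to its exact value.
#' The default is `V_T + 5 * Delta_T = -40 mV`.
#'
#' @param g_exc_nS excitatory synaptic conductance increment per spike, nS.
#' @param g_rel relative inhibitory conductance `g_inh / g_exc`
#'   (dimensionless); `g_inh_nS = g_rel * g_exc_nS` always.
#' @param d_exc_ms,d_inh_ms conduction delay of excitatory / inhibitory
#'   presynaptic conductances, ms (>= 0).
#' @param C_pF membrane capacitance, pF.
#' @param g_L_nS leak conductance, nS.
#' @param E_L_mV resting (leak reversal) potential, mV.
#' @param delta_T_mV slope factor of the exponential spike-initiation term, mV.
#' @param V_T_mV exponential-term threshold potential, mV.
#' @param tau_w_ms adaptation time constant, ms.
#' @param b_pA spike-triggered adaptation increment, pA.
#' @param V_r_mV reset potential, mV.
#' @param tau_s_ms synaptic conductance decay time constant, ms.
#' @param V_rev_exc_mV,V_rev_inh_mV synaptic reversal potentials, mV.
#' @param V_thres_mV numerical spike detection threshold, mV.
#' @param exp_cap cap on the argument of the exponential spike-initiation
#'   term (overflow guard; unreachable below `V_thres_mV`).
#' @return an object of class `aeif_params` (a named list).
#' @examples
#' p <- aeif_params(g_exc_nS = 0.2, g_rel = 6, d_exc_ms = 75, d_inh_ms = 5)
#' p
#' @export
aeif_params <- function(g_exc_nS = 0.2, g_rel = 6,
                        d_exc_ms = 0, d_inh_ms = 0,
                        C_pF = 200, g_L_nS = 12, E_L_mV = -70,
                        delta_T_mV = 2, V_T_mV = -50,
                        tau_w_ms = 300, b_pA = 70, V_r_mV = -58,
                        tau_s_ms = 2.728,
                        V_rev_exc_mV = 0, V_rev_inh_mV = -80,
                        V_thres_mV = -40, exp_cap = 50) {
  p <- list(C_pF = C_pF, g_L_nS = g_L_nS, E_L_mV = E_L_mV,
            delta_T_mV = delta_T_mV, V_T_mV = V_T_mV,
            tau_w_ms = tau_w_ms, b_pA = b_pA, V_r_mV = V_r_mV,
            tau_s_ms = tau_s_ms,
            g_exc_nS = g_exc_nS, g_rel = g_rel,
            g_inh_nS = g_rel * g_exc_nS,
            V_rev_exc_mV = V_rev_exc_mV, V_rev_inh_mV = V_rev_inh_mV,
            d_exc_ms = d_exc_ms, d_inh_ms = d_inh_ms,
            V_thres_mV = V_thres_mV, exp_cap = exp_cap)
  validate_aeif_params(p)
  structure(p, class = "aeif_params")
}

validate_aeif_params <- function(p) {
  pos <- c("C_pF", "g_L_nS", "delta_T_mV", "tau_w_ms", "tau_s_ms")
  for (nm in pos)
    if (p[[nm]] <= 0) stop(nm, " must be strictly positive")
  if (p$g_exc_nS < 0 || p$g_rel < 0) stop("conductances must be nonnegative")
  if (p$d_exc_ms < 0 || p$d_inh_ms < 0) stop("delays must be nonnegative")
  if (abs(p$g_inh_nS - p$g_rel * p$g_exc_nS) > 0)
    stop("g_inh_nS must equal g_rel * g_exc_nS")
  invisible(p)
}

#' @export
print.aeif_params <- function(x, ...) {
  cat("AEIF network parameters\n")
  cat(sprintf("  membrane: C = %g pF, g_L = %g nS, E_L = %g mV, Delta_T = %g mV, V_T = %g mV\n",
              x$C_pF, x$g_L_nS, x$E_L_mV, x$delta_T_mV, x$V_T_mV))
  cat(sprintf("  adaptation: tau_w = %g ms, b = %g pA; reset V_r = %g mV\n",
              x$tau_w_ms, x$b_pA, x$V_r_mV))
  cat(sprintf("  synapse: tau_s = %g ms, g_exc = %g nS, g_inh = %g nS (g = %g)\n",
              x$tau_s_ms, x$g_exc_nS, x$g_inh_nS, x$g_rel))
  cat(sprintf("  reversal: %g / %g mV (exc/inh); delays d_exc = %g ms, d_inh = %g ms\n",
              x$V_rev_exc_mV, x$V_rev_inh_mV, x$d_exc_ms, x$d_inh_ms))
  cat(sprintf("  detection threshold: %g mV\n", x$V_thres_mV))
  invisible(x)
}

#' Rheobase current of the AEIF neuron
#'
#' The saddle-node input current of the subthreshold system: the largest
#' constant input for which the resting fixed point still exists.  With the
#' adaptation current at its nullcline, w = a (V - E_L), fixed points of the
#' membrane equation satisfy
#' `I = (g_L + a)(V - E_L) - g_L Delta_T exp((V - V_T)/Delta_T)`, whose
#' maximum over V gives the closed form
#' `I_rheo = (g_L + a) * (V_T - E_L - Delta_T + Delta_T * log(1 + a/g_L))`.
#' Above `I_rheo` the neuron fires repetitively.
#'
#' @param a subthreshold adaptation conductance, nS (vectorized).
#' @param g_L_nS leak conductance, nS.
#' @param E_L_mV resting potential, mV.
#' @param V_T_mV threshold potential, mV.
#' @param delta_T_mV slope factor, mV.
#' @return rheobase current(s), pA.
#' @examples
#' rheobase_current(0)   # 216 pA with the default membrane parameters
#' rheobase_current(2)   # about 256.3 pA
#' @export
rheobase_current <- function(a, g_L_nS = 12, E_L_mV = -70, V_T_mV = -50,
                             delta_T_mV = 2) {
  if (g_L_nS <= 0 || delta_T_mV <= 0)
    stop("g_L_nS and delta_T_mV must be strictly positive")
  if (any(a < 0)) stop("a must be nonnegative")
  (g_L_nS + a) *
    (V_T_mV - E_L_mV - delta_T_mV + delta_T_mV * log(1 + a / g_L_nS))
}

#' Per-neuron constant input currents
#'
#' The constant input drive of each neuron, a multiple of its own rheobase
#' current (default twice).  With `per_neuron = TRUE` the rheobase uses each
#' neuron's own adaptation level `a_i`, so inputs differ slightly across the
#' network; with `per_neuron = FALSE` a common input computed from
#' `a_nominal` is used for all neurons.
#'
#' @param network an `aeif_network`.
#' @param params an `aeif_params`.
#' @param rheobase_multiple input as a multiple of rheobase (default 2).
#' @param per_neuron use each neuron's own `a_i` (default) or a common value.
#' @param a_nominal nominal adaptation (nS) for the common-input mode.
#' @return numeric vector of input currents, pA.
#' @export
input_currents <- function(network, params, rheobase_multiple = 2,
                           per_neuron = TRUE, a_nominal = 2) {
  a_used <- if (per_neuron) network$a else rep(a_nominal, network$n_neurons)
  rheobase_multiple * rheobase_current(a_used, params$g_L_nS, params$E_L_mV,
                                       params$V_T_mV, params$delta_T_mV)
}
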