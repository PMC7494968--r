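# aeifnet

Simulation and analysis of **delayed-conductance networks of adaptive
exponential integrate-and-fire (AEIF) neurons**, for studying how
transmission delays in excitatory and inhibitory synapses shape neuronal
synchronization.

Conduction delays in the brain reach tens of milliseconds, and the balance
of excitation and inhibition is thought to protect against pathological
synchrony. This package builds random directed networks of 100 AEIF
neurons (80% excitatory / 20% inhibitory, connection probability 0.5),
integrates their dynamics with conductance-based synapses that act after a
per-type delay, and measures when and how the population synchronizes —
letting you map the `(d_exc, d_inh)` delay plane into synchronized /
desynchronized and spike / burst regimes.

## Model

Each neuron obeys

```
C dV/dt   = -g_L (V - E_L) + g_L Δ_T exp((V - V_T)/Δ_T) - w + I + I_syn
τ_w dw/dt = a (V - E_L) - w
τ_s dg/dt = -g
```

with the delayed synaptic current
`I_syn_i(t) = Σ_j [V_REV_j - V_i(t)] A_ij g_j(t - d_j)` — the reversal
potential (0 mV excitatory, −80 mV inhibitory) and delay (`d_exc` or
`d_inh`) are those of the *presynaptic* neuron `j`. On crossing threshold:
`V → V_r`, `w → w + b`, `g → g + g_s` (own type's conductance increment;
`g_inh = g · g_exc` with relative inhibition `g`). Each neuron is driven
at twice its own rheobase current, the saddle-node point
`I_rheo = (g_L + a)(V_T − E_L − Δ_T + Δ_T ln(1 + a/g_L))`.

Synchronization diagnostics on the `[5 s, 10 s]` analysis window:

* `R̄` — time-averaged Kuramoto order parameter on linearly interpolated
  spike phases (1 = perfect synchrony),
* `CV̄` — mean per-neuron coefficient of variation of inter-spike
  intervals (`≥ 0.5` labels bursting, `< 0.5` regular spiking),
* `F̄` — mean firing frequency (Hz),
* `Ī_s` — mean synaptic input (pA).

## Worked example

A weak-coupling network (`g_exc = 0.2` nS, `g = 6`) with a short
inhibitory delay and a 75 ms excitatory delay — a point where delayed
excitation synchronizes the population:

```r
library(aeifnet)
net    <- build_random_network(n_neurons = 100, connection_probability = 0.5, seed = 1)
params <- aeif_params(g_exc_nS = 0.2, g_rel = 6, d_exc_ms = 75, d_inh_ms = 5)
init   <- sample_initial_state(100, seed = 2)
sim    <- aeif_simulate(net, params, init, t_end_ms = 10000)
diagnose(sim)
#> Synchronization diagnostics on [5, 10] s
#>   R_bar  = 0.9989   (synchronous, 100 neurons used)
#>   CV_bar = 0.0001   (spike pattern)
#>   F_bar  = 12.642 Hz
#>   Is_bar = 4.316 pA
```

`R̄ ≈ 1` with `CV̄ ≈ 0`: the whole network fires in near-perfect lockstep
at ~12.6 Hz in a regular (non-bursting) pattern. Moving the excitatory
delay to 65 or 85 ms (same seed, same network) drops `R̄` to ~0.15 and
~0.62 — synchronization is non-monotonic in the delay. At strong coupling
(`g_exc = 0.8` nS), a purely inhibitory delay (`d_exc = 0, d_inh = 50` ms)
instead produces synchronized *bursts* (`CV̄ ≈ 3.4`), while
`d_exc = d_inh = 0` stays at desynchronized spikes.

Scenario averaging over independent initial conditions and delay-plane
sweeps:

```r
cfg  <- scenario_config(g_exc_nS = 0.2, g_rel = 6, n_realizations = 10, master_seed = 1)
grid <- sweep_delays(cfg, d_exc_values = seq(40, 110, 10), d_inh_values = seq(0, 70, 10))
plot_delay_map(grid, "R")       # synchronization domains in the delay plane
plot_raster(run_scenario(cfg, d_exc_ms = 75, d_inh_ms = 5, keep_sims = TRUE)$sims[[1]])
```

A thin command-line interface (`inst/exec/aeifnet`, verbs
`generate-network`, `simulate`, `diagnose`, `sweep`, `render`) wraps the
same functions, driven by a YAML key-value config
(`write_scenario_config`).

See `vignettes/delayed-conductance-methods.Rmd` for the numerical scheme
(fixed-step Euler with exact conductance decay and ring-buffer delayed
coupling), the diagnostics' definitions and edge-case policies, and the
design decisions.

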