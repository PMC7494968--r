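---
title: "Methods: delayed-conductance AEIF networks and their synchronization diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed-conductance AEIF networks and their synchronization diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`aeifnet` simulates networks of adaptive exponential integrate-and-fire
(AEIF) neurons coupled by conductance-based synapses whose effect arrives
with a transmission delay, and quantifies when such networks synchronize.
The scientific question it serves is how the *timing* of excitation and
inhibition — not just their strength — shapes collective spiking: delays of
tens of milliseconds are physiological (corticothalamic conduction can
exceed 50 ms), and the balance of excitation and inhibition is widely held
to protect the brain against pathological synchrony.

Each neuron `i` obeys

$$C \frac{dV_i}{dt} = -g_L (V_i - E_L)
    + g_L \Delta_T e^{(V_i - V_T)/\Delta_T} - w_i + I_i + I^{syn}_i,$$
$$\tau_w \frac{dw_i}{dt} = a_i (V_i - E_L) - w_i, \qquad
  \tau_s \frac{dg_i}{dt} = -g_i,$$

with the synaptic current

$$I^{syn}_i(t) = \sum_j \left[V^{REV}_j - V_i(t)\right] A_{ij}\, g_j(t - d_j),$$

where `A[i, j] = 1` when presynaptic neuron `j` projects to postsynaptic
neuron `i`, `V_REV` is 0 mV for excitatory and −80 mV for inhibitory
presynaptic neurons, and the delay `d_j` is `d_exc` or `d_inh` by
presynaptic type.  When `V_i` crosses the detection threshold the neuron is
reset: `V -> V_r`, `w -> w + b`, and its own conductance jumps by `g_exc`
or `g_inh = g * g_exc` according to its type.  Units are closed throughout
(mV, ms, pA, nS, pF): `nS * mV = pA` and `pF * mV / ms = pA`.

The network is a directed Erdős–Rényi digraph on 100 neurons (connection
probability 0.5, no self-connections, every neuron guaranteed at least one
incident edge), 80% excitatory / 20% inhibitory at the *neuron* level
(Dale's principle: the reversal potential, conductance increment and delay
of an edge are properties of its presynaptic neuron).  Heterogeneity enters
through the subthreshold adaptation `a_i ~ U[1.9, 2.1]` nS, and each neuron
is driven at twice its own rheobase,

$$I_{rheo}(a) = (g_L + a)\left(V_T - E_L - \Delta_T
   + \Delta_T \ln(1 + a/g_L)\right),$$

the saddle-node current of the subthreshold system (with the defaults,
256.3 pA at `a = 2` nS, so inputs sit near 513 pA).  A switch
(`input_per_neuron = FALSE`) drives all neurons at the common value computed
from the nominal `a = 2` nS instead.

## Numerical scheme

The integrator (`aeif_simulate`, compiled core) uses a fixed step,
default 0.01 ms:

* **V and w** advance by explicit Euler.  Event-driven resets destroy the
  high-order accuracy of fancier schemes anyway; 0.01 ms resolves the 2 mV
  slope-factor dynamics (the fastest pre-threshold scale) comfortably.
* **g** advances by the *exact* factor `exp(-dt / tau_s)` per step, so
  between resets `log g` is affine in `t` with slope `-1/tau_s` by
  construction; the suite asserts `g(t + tau_s) / g(t) = e^{-1}` to
  ~1e-12 relative (the residual is the accumulated rounding of repeated
  multiplication, a few parts in 1e13).
* **Delays** are rounded to the nearest integer number of steps (error
  < 5 µs at the default step).  Delayed coupling is implemented by
  per-target running sums of delayed presynaptic conductances: because
  every conductance shares `tau_s`, the sums decay by the same exact
  factor, and a reset of neuron `j` at `t*` is queued to jump its targets'
  sums at `t* + d_j`.  This is algebraically identical to reading a
  per-neuron ring buffer of conductance history but costs O(N) per step
  instead of O(N²).  The queue starts empty, which realizes the required
  initial profile: no neuron has spiked on `[-max(d), 0]`, so the delayed
  view of any time ≤ 0 is zero (a nonzero `g0` is queued to arrive at
  `t = d_j`).
* **Resets** are detected *after* the step (`V > V_thres`), applied all at
  once, and the post-reset conductance is what enters the delayed view —
  so with `d = 0` a spike reaches its targets at the step it occurs, and
  simultaneous spikes interact only after their delays.
* **Overflow**: the exponential argument is capped (default cap 50, i.e.
  V = 50 mV at `V_T = -50`, `Delta_T = 2`), far above any state reachable
  before the −40 mV detection threshold; once `V > V_thres` the reset fires
  before the exponential is ever evaluated at a larger V.

**Detection threshold.** `V_thres` is a numerical device, not a printed
model constant; the default is `V_T + 5 Delta_T = -40` mV.  Because the
exponential term accelerates the upstroke so strongly, the threshold choice
shifts each detection by a fixed small amount: moving it by a full
10 mV (to −30 mV) delays each spike by ~0.1 ms (the extra upstroke
traversal), under 1% of an inter-spike interval.  Note the shift *accumulates over spikes* — a later
detection resets later, offsetting the whole subsequent train — so
"insensitivity" is a per-spike statement, which is what the tests assert.
The same accumulation logic applies to step-size convergence (halving the
step moves spike times by ~0.006 ms per elapsed spike) and to the
single-neuron validation against an independent adaptive-step reference
(deSolve's lsoda with root-triggered reset events): over a 10 s tonic run
all 125 spikes match within 2 steps per spike index.

## Diagnostics

All measures are computed on the analysis window, default `[5 s, 10 s]`
(the first 5 s discard transients):

* **Order parameter** `R̄`: each neuron's phase grows linearly from `2πm`
  at its m-th spike to `2π(m+1)` at the next; `r(t)` is the modulus of the
  population-mean phase factor and `R̄` its time average, evaluated as a
  discrete mean at a 1 ms stride (convergence against a 0.1 ms stride is
  asserted in the suite).  `R̄ = 1` exactly for identical trains; evenly
  splayed periodic trains give `r(t)` at the roots-of-unity cancellation
  floor (< 1e-10).
* **CV̄**: per-neuron coefficient of variation of inter-spike intervals
  (population SD / mean over the ISIs inside the window; neurons with
  fewer than 3 windowed spikes are excluded), averaged across neurons.
  Averaging per-neuron CVs rather than pooling ISIs network-wide keeps
  rate heterogeneity (every neuron has its own `a_i`, hence its own rate)
  from masquerading as irregularity; `average = "pooled"` and
  `sd_type = "sample"` switches are provided.  `CV̄ ≥ 0.5` labels burst,
  `< 0.5` spike.
* **F̄** `= 1 / ISĪ` in Hz, with `ISĪ` the mean over neurons of per-neuron
  mean windowed ISIs.
* **Ī_s**: trapezoidal time average of the network-mean synaptic current
  over the window.
* **Classification**: the 0.5 CV bound is the field's conventional
  spike/burst rule; the synchrony label (`R̄ ≥ 0.9` by default) is a
  map-reading convention of this package — delay-plane synchrony maps are
  continuous in `R̄` and fix no canonical cutoff — and is kept clearly
  separate from the CV rule.

**Window policy.** The phase is undefined outside a neuron's first and last
spikes.  With the analysis window ending at the simulation end (10 s),
essentially no neuron has a spike *at or beyond* `t_fin`, even though all
fire continually — so the strict "use only neurons bracketing the whole
window" rule would discard everyone.  `order_parameter` therefore supports
two policies: `"strict"` (the default; used by the identical-trains and
splay checks, where trains do span the window) and `"clip"` (used by
`diagnose`), which shrinks the window to the largest sub-interval bracketed
by every firing neuron — in practice it ends one ISI (~80 ms) early, a <2%
change of a 5 s window.  The effective window is reported alongside the
result.

## Experiments

`run_scenario` simulates `n_realizations` independent realizations (default
10, the package's standard averaging protocol) of one parameter point;
`sweep_delays` tiles the `(d_exc, d_inh)` plane.  Seeds derive
deterministically from `(master_seed, cell delays, realization index)`, so
re-runs are bit-identical, cells are independent, and extending a grid
never changes existing cells.  Realizations redraw the initial conditions
and the adaptation draw but keep the wiring fixed (the averaging is over
initial conditions, not topologies); `redraw_wiring = TRUE` redraws
everything.
Sweeps can append per-realization rows to a progress CSV and resume from
finished cells.  The sweep grid resolution is configurable; no canonical
resolution is fixed because runtime scales linearly with cells (a
100-neuron, 10 s cell takes ~10 s of CPU).

Preset scenario families (`scenario_presets`) encode the probed points: the
weak-coupling regime (`g_exc = 0.2` nS, `g = 6`) with `d_inh = 5` ms and
`d_exc ∈ {65, 75, 85}` ms, where synchronization is non-monotonic in the
excitatory delay (measured mean `R̄` ≈ 0.15 / 0.999 / 0.62); the same
regime probed along `d_inh`; and the strong-coupling regime
(`g_exc = 0.8` nS) at four delay points spanning desynchronized spikes
(`d_exc = d_inh = 0`, CV̄ ≈ 0.07), synchronized bursts
(`d_exc = 0, d_inh = 50` ms, CV̄ ≈ 3.4), and synchronized spikes
(`d_exc = 70, d_inh = 50` ms).

## What the generator does and does not emulate

The synthetic network *is* the system under analysis — there is no external
data —
so passing tests establish internal correctness of the construction,
integration and diagnostics, and reproduction of the delay-plane
phenomenology under the stated conditions.  The generator emulates none of
the structure of real cortical tissue beyond the E/I split: connectivity is
homogeneous-random (no distance dependence, clustering, or degree
heterogeneity beyond binomial), synapses are static single-exponential
conductances, inputs are noiseless constants, and delays take exactly two
values.  Conclusions about real neuronal populations therefore rest on the
model's adequacy, not on anything this package can test.

## Numerical and degenerate-input choices

* Delays representable on the step grid; `d = 0` is valid (same-step
  interaction, post-reset convention above).
* `connection_probability = 0` is rejected (the minimum-degree guarantee
  would be unsatisfiable); `p = 1` yields the complete digraph.
* Degenerate sampling intervals (`[2, 2]` nS, `[-60, -60]` mV) are allowed
  and produce constants; reversed bounds are errors.
* Neurons with fewer than 3 windowed spikes are excluded from CV/F̄ (their
  count is reported); diagnostics error out only if *no* neuron qualifies.
* Non-finite states abort the integration with the offending time and
  neuron; the exponential-argument cap makes this unreachable under sane
  parameters.

## Problem sizes used by the test suite

Unit tests run 2–20 neuron motifs over spans of 0.3–2 s.  The end-to-end
checks run the full study conditions — 100 neurons, 10 s at 0.01 ms — for
the uncoupled regime (1 run), the oracle comparison (1 run), the
weak-coupling delay probe (3 delays × 3 realizations) and the
strong-coupling transition (2 points × 3 realizations); 3 realizations are
used because the measured effect margins (order-parameter gaps > 0.3, CV
gaps > 3) dwarf realization-to-realization scatter, and runtime grows
linearly with realizations.
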