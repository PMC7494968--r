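#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step integrator for a delayed-conductance AEIF network.
//
// Units: mV, ms, pA, nS, pF (closed system: nS*mV = pA, pF*mV/ms = pA).
//
// Scheme: explicit Euler for V and w; exact exponential decay for the
// synaptic conductances g (and for the delayed-conductance sums, which share
// the same time constant).  Threshold crossings are detected on the grid;
// resets follow V -> V_r, w -> w + b, g -> g + g_s.
//
// Delays: each presynaptic neuron's conductance acts on its targets with a
// lag d_exc or d_inh (rounded to the nearest step).  Because every
// conductance decays with the same tau_s, the per-postsynaptic sums
//   SE_i(t) = sum_j_exc A_ij g_j(t - d_exc),  SI_i(t) = sum_j_inh A_ij g_j(t - d_inh)
// obey the same exponential decay between jump events; a conductance jump of
// neuron j at time t* reaches its targets at t* + d_j.  Those arrivals are
// queued on a ring buffer indexed by step, realizing the zero ("not
// spiking") pre-history on [-d, 0] for free: nothing is queued before the
// first spike, so the delayed view of any time <= 0 is the initial g only,
// itself queued as an arrival at step d_j when g0 > 0.

// [[Rcpp::export]]
List aeif_integrate_core(IntegerMatrix adjacency, LogicalVector is_exc,
                         NumericVector a, NumericVector input,
                         List par,
                         NumericVector v0, NumericVector w0, NumericVector g0,
                         double t_end, double dt, double sample_stride,
                         bool record_state) {
  const int n = adjacency.nrow();
  const double C      = as<double>(par["C_pF"]);
  const double gL     = as<double>(par["g_L_nS"]);
  const double EL     = as<double>(par["E_L_mV"]);
  const double DT     = as<double>(par["delta_T_mV"]);
  const double VT     = as<double>(par["V_T_mV"]);
  const double tauw   = as<double>(par["tau_w_ms"]);
  const double bjump  = as<double>(par["b_pA"]);
  const double Vr     = as<double>(par["V_r_mV"]);
  const double taus   = as<double>(par["tau_s_ms"]);
  const double gexc   = as<double>(par["g_exc_nS"]);
  const double ginh   = as<double>(par["g_inh_nS"]);
  const double VrevE  = as<double>(par["V_rev_exc_mV"]);
  const double VrevI  = as<double>(par["V_rev_inh_mV"]);
  const double dexc   = as<double>(par["d_exc_ms"]);
  const double dinh   = as<double>(par["d_inh_ms"]);
  const double Vthres = as<double>(par["V_thres_mV"]);
  const double expcap = as<double>(par["exp_cap"]);

  if (dt <= 0) stop("step size must be positive");
  const long nsteps = (long) std::llround(t_end / dt);
  const double decay = std::exp(-dt / taus);
  const long ds_exc = (long) std::lround(dexc / dt);
  const long ds_inh = (long) std::lround(dinh / dt);
  const long ringlen = std::max(ds_exc, ds_inh) + 2;

  // adjacency stored as postsynaptic target lists per presynaptic neuron
  std::vector< std::vector<int> > targets(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (adjacency(i, j) != 0) targets[j].push_back(i);

  // delayed-conductance jump queue: (presynaptic neuron, jump size)
  std::vector< std::vector< std::pair<int, double> > > queue(ringlen);

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> g(g0.begin(), g0.end());
  std::vector<double> SE(n, 0.0), SI(n, 0.0), Isyn(n, 0.0);

  // initial conductances enter the delayed view at t = d_j
  for (int j = 0; j < n; ++j) {
    if (g[j] > 0.0) {
      long ds = is_exc[j] ? ds_exc : ds_inh;
      if (ds <= nsteps) queue[ds % ringlen].push_back(std::make_pair(j, g[j]));
    }
  }

  const long stride_steps = std::max(1L, (long) std::lround(sample_stride / dt));
  const long nsamp = nsteps / stride_steps + 1;
  NumericVector times(nsamp), isyn_mean(nsamp);
  NumericMatrix Vrec, Wrec, Grec;
  if (record_state) {
    Vrec = NumericMatrix(nsamp, n);
    Wrec = NumericMatrix(nsamp, n);
    Grec = NumericMatrix(nsamp, n);
  }
  std::vector< std::vector<double> > spikes(n);
  long isamp = 0;

  for (long step = 0; step <= nsteps; ++step) {
    const double t = step * dt;

    // jumps in the delayed conductances reaching their targets at this step
    std::vector< std::pair<int, double> > &due = queue[step % ringlen];
    for (size_t k = 0; k < due.size(); ++k) {
      const int j = due[k].first;
      const double amt = due[k].second;
      const std::vector<int> &tg = targets[j];
      if (is_exc[j]) for (size_t m = 0; m < tg.size(); ++m) SE[tg[m]] += amt;
      else           for (size_t m = 0; m < tg.size(); ++m) SI[tg[m]] += amt;
    }
    due.clear();

    // synaptic currents at time t
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      Isyn[i] = SE[i] * (VrevE - V[i]) + SI[i] * (VrevI - V[i]);
      acc += Isyn[i];
    }

    if (step % stride_steps == 0) {
      times[isamp] = t;
      isyn_mean[isamp] = acc / n;
      if (record_state)
        for (int i = 0; i < n; ++i) {
          Vrec(isamp, i) = V[i];
          Wrec(isamp, i) = w[i];
          Grec(isamp, i) = g[i];
        }
      ++isamp;
    }
    if (step == nsteps) break;

    // Euler update of V and w; exact decay of g and the delayed sums
    for (int i = 0; i < n; ++i) {
      double arg = (V[i] - VT) / DT;
      if (arg > expcap) arg = expcap;
      const double dV = (-gL * (V[i] - EL) + gL * DT * std::exp(arg)
                         - w[i] + input[i] + Isyn[i]) * dt / C;
      const double dw = (a[i] * (V[i] - EL) - w[i]) * dt / tauw;
      V[i] += dV;
      w[i] += dw;
      g[i] *= decay;
      SE[i] *= decay;
      SI[i] *= decay;
    }

    // threshold detection and reset at t + dt
    const double tnext = t + dt;
    for (int i = 0; i < n; ++i) {
      if (V[i] > Vthres) {
        V[i] = Vr;
        w[i] += bjump;
        const double gs = is_exc[i] ? gexc : ginh;
        g[i] += gs;
        spikes[i].push_back(tnext);
        const long ds = is_exc[i] ? ds_exc : ds_inh;
        const long due_step = step + 1 + ds;
        if (due_step <= nsteps && gs > 0.0)
          queue[due_step % ringlen].push_back(std::make_pair(i, gs));
      }
    }

    if (step % 10000 == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i]) || !std::isfinite(w[i]))
          stop("non-finite state at t = %f ms (neuron %d)", t, i + 1);
      Rcpp::checkUserInterrupt();
    }
  }

  List sp(n);
  for (int i = 0; i < n; ++i) sp[i] = NumericVector(spikes[i].begin(), spikes[i].end());

  List out = List::create(
    _["spike_trains"] = sp,
    _["times"] = times,
    _["isyn_mean"] = isyn_mean,
    _["v_final"] = NumericVector(V.begin(), V.end()),
    _["w_final"] = NumericVector(w.begin(), w.end()),
    _["g_final"] = NumericVector(g.begin(), g.end()),
    _["n_steps"] = (double) nsteps);
  if (record_state) {
    out["v_trace"] = Vrec;
    out["w_trace"] = Wrec;
    out["g_trace"] = Grec;
  }
  return out;
}
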