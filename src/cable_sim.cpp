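// Tree-structured Crank-Nicolson integrator for branched passive cables,
// with double-exponential (or alpha) synaptic conductances, point current
// injection, and an ideal somatic voltage clamp.
//
// Units: mV, ms, nA, uS, nF. Compartments are ordered parents-first
// (parent[i] < i, root parent = -1), so a single sweep performs the Hines
// elimination.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Solve A v = rhs where A is symmetric tree-tridiagonal with diagonal d and
// off-diagonal u[i] coupling i with parent[i]. Overwrites d and rhs; result
// in v. `clamped` marks rows whose value is fixed to rhs (identity rows with
// couplings already folded into neighbours by the caller).
static void hines_solve(int n, const IntegerVector& parent,
                        std::vector<double>& d, const std::vector<double>& u,
                        std::vector<double>& rhs, std::vector<double>& v,
                        const std::vector<char>& clamped) {
  for (int i = n - 1; i > 0; --i) {
    int p = parent[i];
    if (clamped[i] || clamped[p]) continue;
    double f = u[i] / d[i];
    d[p] -= f * u[i];
    rhs[p] -= f * rhs[i];
  }
  v[0] = rhs[0] / d[0];
  for (int i = 1; i < n; ++i) {
    int p = parent[i];
    if (clamped[i]) { v[i] = rhs[i] / d[i]; continue; }
    if (clamped[p]) { v[i] = rhs[i] / d[i]; continue; } // coupling pre-folded
    v[i] = (rhs[i] - u[i] * v[p]) / d[i];
  }
}

// Steady-state solve of the passive system with optional clamp and point
// currents: K v = b, K the conductance matrix.
// [[Rcpp::export(name = ".cable_steady")]]
NumericVector cable_steady(IntegerVector parent, NumericVector g_ax,
                           NumericVector g_leak, NumericVector e_leak,
                           int clamp_node, double clamp_v,
                           IntegerVector inj_node, NumericVector inj_nA) {
  int n = parent.size();
  std::vector<double> d(n), u(n, 0.0), rhs(n), v(n);
  std::vector<char> clamped(n, 0);
  for (int i = 0; i < n; ++i) {
    d[i] = g_leak[i];
    rhs[i] = g_leak[i] * e_leak[i];
  }
  for (int i = 1; i < n; ++i) {
    d[i] += g_ax[i];
    d[parent[i]] += g_ax[i];
    u[i] = -g_ax[i];
  }
  for (int k = 0; k < inj_node.size(); ++k) rhs[inj_node[k]] += inj_nA[k];
  if (clamp_node >= 0) {
    clamped[clamp_node] = 1;
    // fold clamp value into neighbours
    for (int i = 1; i < n; ++i) {
      if (i == clamp_node) rhs[parent[i]] -= u[i] * clamp_v;
      if (parent[i] == clamp_node) rhs[i] -= u[i] * clamp_v;
    }
    d[clamp_node] = 1.0; rhs[clamp_node] = clamp_v;
  }
  hines_solve(n, parent, d, u, rhs, v, clamped);
  return NumericVector(v.begin(), v.end());
}

// Full time-domain simulation.
//
// stim:    per-step injected current (nA) at stim_node, length nstep
//          (evaluated at step midpoints), or length 0 for none.
// clamp_v: per-step clamp command (mV) at clamp_node, length nstep + 1
//          (values at sample times), or length 0 for no clamp.
// Synapses: double-exponential unless tau_rise == tau_decay (alpha).
// Events: (ev_syn, ev_step) sorted by step; weight 1 each.
// Records voltages at rec_nodes every `sample_every` steps, plus the clamp
// electrode current (nA) if clamped.
// [[Rcpp::export(name = ".cable_sim")]]
List cable_sim(IntegerVector parent, NumericVector g_ax, NumericVector g_leak,
               NumericVector cap, NumericVector e_leak, double dt, int nstep,
               int stim_node, NumericVector stim,
               int clamp_node, NumericVector clamp_v,
               IntegerVector syn_node, NumericVector syn_gmax,
               NumericVector syn_tr, NumericVector syn_td,
               NumericVector syn_erev,
               IntegerVector ev_syn, IntegerVector ev_step,
               IntegerVector rec_nodes, int sample_every,
               NumericVector v_init) {
  int n = parent.size();
  int ns = syn_node.size();
  bool has_clamp = clamp_node >= 0 && clamp_v.size() > 0;
  bool has_stim = stim.size() > 0;

  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> gax_sum(n, 0.0);
  for (int i = 1; i < n; ++i) {
    gax_sum[i] += g_ax[i];
    gax_sum[parent[i]] += g_ax[i];
  }

  // synapse states and per-step decay factors
  std::vector<double> sa(ns, 0.0), sb(ns, 0.0), dec_r(ns), dec_d(ns),
      norm(ns);
  std::vector<char> alpha(ns, 0);
  for (int s = 0; s < ns; ++s) {
    double tr = syn_tr[s], td = syn_td[s];
    if (std::abs(tr - td) <= 0.01 * td) {
      alpha[s] = 1;
      dec_d[s] = std::exp(-dt / td);
      dec_r[s] = 0.0;
      norm[s] = std::exp(1.0) / td; // g = gmax * (t/td) e^{1-t/td}
    } else {
      dec_r[s] = std::exp(-dt / tr);
      dec_d[s] = std::exp(-dt / td);
      double tp = tr * td / (td - tr) * std::log(td / tr);
      norm[s] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    }
  }

  int nsamp = nstep / sample_every + 1;
  NumericMatrix vout(rec_nodes.size(), nsamp);
  NumericVector iclamp(has_clamp ? nsamp : 0);
  std::vector<double> gsyn(n, 0.0), ssyn(n, 0.0);
  std::vector<double> d(n), u(n), rhs(n), vnew(n);
  std::vector<char> clamped(n, 0);
  if (has_clamp) clamped[clamp_node] = 1;
  for (int i = 1; i < n; ++i) u[i] = -0.5 * g_ax[i];

  // neighbours of the clamp node (for folding and electrode current)
  std::vector<int> cl_nb, cl_nb_edge;
  if (has_clamp) {
    for (int i = 1; i < n; ++i) {
      if (i == clamp_node) { cl_nb.push_back(parent[i]); cl_nb_edge.push_back(i); }
      else if (parent[i] == clamp_node) { cl_nb.push_back(i); cl_nb_edge.push_back(i); }
    }
    v[clamp_node] = clamp_v[0];
  }

  auto electrode_current = [&](int step_idx, double t_dvdt) {
    double vc = v[clamp_node];
    double I = g_leak[clamp_node] * (vc - e_leak[clamp_node]);
    for (size_t k = 0; k < cl_nb.size(); ++k)
      I += g_ax[cl_nb_edge[k]] * (vc - v[cl_nb[k]]);
    I += gsyn[clamp_node] * vc - ssyn[clamp_node];
    I += cap[clamp_node] * t_dvdt;
    if (has_stim && stim_node == clamp_node && step_idx < nstep)
      I -= stim[step_idx];
    return I;
  };

  // record initial sample
  for (int r = 0; r < rec_nodes.size(); ++r) vout(r, 0) = v[rec_nodes[r]];
  if (has_clamp) iclamp[0] = electrode_current(0, 0.0);

  int ev = 0, nev = ev_syn.size();
  for (int step = 0; step < nstep; ++step) {
    // advance synapse states to this step's midpoint
    while (ev < nev && ev_step[ev] <= step) {
      int s = ev_syn[ev];
      if (alpha[s]) sa[s] += 1.0; else { sa[s] += 1.0; sb[s] += 1.0; }
      ++ev;
    }
    std::fill(gsyn.begin(), gsyn.end(), 0.0);
    std::fill(ssyn.begin(), ssyn.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      double g;
      if (alpha[s]) {
        // sb accumulates t*exp(-t/tau) via exact recurrence
        sb[s] = dec_d[s] * (sb[s] + dt * sa[s]);
        sa[s] *= dec_d[s];
        g = syn_gmax[s] * norm[s] * sb[s];
      } else {
        sa[s] *= dec_r[s];
        sb[s] *= dec_d[s];
        g = syn_gmax[s] * norm[s] * (sb[s] - sa[s]);
      }
      if (g != 0.0) {
        gsyn[syn_node[s]] += g;
        ssyn[syn_node[s]] += g * syn_erev[s];
      }
    }

    // assemble A = C/dt + K/2, rhs = (C/dt - K/2) v + s
    for (int i = 0; i < n; ++i) {
      double gtot = g_leak[i] + gax_sum[i] + gsyn[i];
      double cdt = cap[i] / dt;
      d[i] = cdt + 0.5 * gtot;
      double Kv = gtot * v[i];
      rhs[i] = cdt * v[i] + g_leak[i] * e_leak[i] + ssyn[i];
      // subtract axial neighbour terms of K v
      rhs[i] -= 0.5 * Kv;
    }
    for (int i = 1; i < n; ++i) {
      rhs[i] += 0.5 * g_ax[i] * v[parent[i]];
      rhs[parent[i]] += 0.5 * g_ax[i] * v[i];
    }
    if (has_stim) rhs[stim_node] += stim[step];
    if (has_clamp) {
      double vc_next = clamp_v[step + 1];
      for (size_t k = 0; k < cl_nb.size(); ++k)
        rhs[cl_nb[k]] -= u[cl_nb_edge[k]] * vc_next;
      d[clamp_node] = 1.0;
      rhs[clamp_node] = vc_next;
    }

    hines_solve(n, parent, d, u, rhs, vnew, clamped);
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(vnew[i])) { bad = true; break; }
      v[i] = vnew[i];
    }
    if (bad) stop("cable_sim: non-finite state at step %d (t = %.3f ms)",
                  step + 1, (step + 1) * dt);

    if ((step + 1) % sample_every == 0) {
      int k = (step + 1) / sample_every;
      for (int r = 0; r < rec_nodes.size(); ++r) vout(r, k) = v[rec_nodes[r]];
      if (has_clamp) {
        double dvdt = (clamp_v[step + 1] - clamp_v[step]) / dt;
        iclamp[k] = electrode_current(step, dvdt);
      }
    }
  }
  return List::create(_["v"] = vout, _["i_clamp"] = iclamp);
}
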