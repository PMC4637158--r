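// Fast kernels: two-variable surrogate kinetics, activity trackers,
// union-find side-to-side connectivity, content hash.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-variable excitable surrogate (Mitchell-Schaeffer form) expressed on the
// physiological voltage scale: u = (V - V_rest) / V_amp in [0, 1], recovery
// gate h in eta[0, ]. du/dt = h u^2 (1-u)/tau_in - u/tau_out + stim/V_amp;
// dh/dt = (1-h)/tau_open for u < u_gate, -h/tau_close otherwise.
// pars = (tau_in, tau_out, tau_open, tau_close, u_gate, V_rest, V_amp)
// [[Rcpp::export(name = ".surrogate_step")]]
void surrogate_step(NumericVector V, NumericMatrix eta, NumericVector stim,
                    int n_sub, double dt, NumericVector pars) {
  int n = V.size();
  if (eta.nrow() != 1 || eta.ncol() != n)
    stop("eta must be 1 x length(V)");
  double tau_in = pars[0], tau_out = pars[1], tau_open = pars[2],
         tau_close = pars[3], u_gate = pars[4], v_rest = pars[5],
         v_amp = pars[6];
  double *v = REAL(V), *h = REAL(eta), *st = REAL(stim);
  for (int c = 0; c < n; ++c) {
    double u = (v[c] - v_rest) / v_amp;
    double hc = h[c], s = st[c] / v_amp;
    for (int k = 0; k < n_sub; ++k) {
      double du = hc * u * u * (1.0 - u) / tau_in - u / tau_out + s;
      double dh = (u < u_gate) ? (1.0 - hc) / tau_open : -hc / tau_close;
      u += dt * du;
      hc += dt * dh;
      if (u < -0.05) u = -0.05;           // guard against stim overshoot
      if (u > 1.05) u = 1.05;
      if (hc < 0.0) hc = 0.0;
      if (hc > 1.0) hc = 1.0;
    }
    v[c] = v_rest + v_amp * u;
    h[c] = hc;
    if (!std::isfinite(v[c]))
      stop("non-finite state after reaction step: V in cell %d", c + 1);
    if (!std::isfinite(h[c]))
      stop("non-finite state after reaction step: h in cell %d", c + 1);
  }
}

// Incremental activity tracking at the coarse (diffusion) time step.
// armed: 1 when the AP detector is re-armed (V has been below v_rearm since
// the last counted upstroke). act_time: first upward crossing of v_act (NA
// until seen). last_active: latest t with V >= v_act. ap_count: upward
// crossings of v_up with re-arming hysteresis at v_rearm.
// [[Rcpp::export(name = ".update_trackers")]]
void update_trackers(NumericVector V, IntegerVector armed,
                     IntegerVector ap_count, NumericVector act_time,
                     NumericVector last_active, double t,
                     double v_act, double v_up, double v_rearm) {
  int n = V.size();
  double *v = REAL(V);
  int *ar = INTEGER(armed), *ap = INTEGER(ap_count);
  double *at = REAL(act_time), *la = REAL(last_active);
  for (int i = 0; i < n; ++i) {
    if (v[i] >= v_act) {
      if (ISNA(at[i])) at[i] = t;
      la[i] = t;
    }
    if (ar[i] && v[i] >= v_up) {
      ap[i] += 1;
      ar[i] = 0;
    } else if (!ar[i] && v[i] <= v_rearm) {
      ar[i] = 1;
    }
  }
}

// Side-to-side connectivity by union-find on the retained links of the cell
// network. links: m x 2 matrix of 1-based cell ids; removed: per-cell flag;
// left/right: 1-based ids of the cells touching the two opposing sides.
// [[Rcpp::export(name = ".percolates")]]
bool percolates(int n, IntegerMatrix links, LogicalVector removed,
                IntegerVector left, IntegerVector right) {
  std::vector<int> parent(n + 1);
  for (int i = 0; i <= n; ++i) parent[i] = i;
  // iterative path-halving find
  struct UF {
    std::vector<int> &p;
    int find(int x) {
      while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
      return x;
    }
  } uf{parent};
  int m = links.nrow();
  const int *a = INTEGER(links), *b = a + m;
  const int *rm = LOGICAL(removed);
  for (int k = 0; k < m; ++k) {
    int i = a[k], j = b[k];
    if (rm[i - 1] || rm[j - 1]) continue;
    int ri = uf.find(i), rj = uf.find(j);
    if (ri != rj) parent[ri] = rj;
  }
  // virtual source node 0 tied to the alive left side
  int src = -1;
  for (int k = 0; k < left.size(); ++k) {
    int i = left[k];
    if (rm[i - 1]) continue;
    if (src < 0) src = uf.find(i);
    else {
      int r = uf.find(i);
      if (r != src) { parent[r] = src; }
    }
  }
  if (src < 0) return false;
  src = uf.find(src);
  for (int k = 0; k < right.size(); ++k) {
    int i = right[k];
    if (rm[i - 1]) continue;
    if (uf.find(i) == src) return true;
  }
  return false;
}

// FNV-1a content hash of an integer vector, as 16 hex digits.
// [[Rcpp::export(name = ".fnv_hash")]]
String fnv_hash(IntegerVector x) {
  uint64_t h = 1469598103934665603ULL;
  const int *p = INTEGER(x);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    uint32_t v = (uint32_t)p[i];
    for (int b = 0; b < 4; ++b) {
      h ^= (v >> (8 * b)) & 0xffu;
      h *= 1099511628211ULL;
    }
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return String(buf);
}
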