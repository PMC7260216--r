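// Multi-state speciation-extinction (MuSSE) pruning core.
//
// The coupled ODEs per branch, for k character states, are
//   dE_i/dt = mu_i - (lam_i + mu_i + sum_{j!=i} q_ij) E_i
//             + lam_i E_i^2 + sum_{j!=i} q_ij E_j
//   dD_i/dt = -(lam_i + mu_i + sum_{j!=i} q_ij) D_i
//             + 2 lam_i E_i D_i + sum_{j!=i} q_ij D_j
// integrated tipward -> rootward with a Dormand-Prince 5(4) adaptive
// stepper. D vectors are renormalised at branch tops and node merges,
// with the log scaler accumulated, so large trees do not underflow.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct MusseSystem {
  int k;
  std::vector<double> lam, mu;
  std::vector<double> Q;      // row-major k*k, diagonal = -rowsum(offdiag)
  std::vector<double> decay;  // lam_i + mu_i + sum_{j!=i} q_ij

  MusseSystem(const NumericVector& lam_, const NumericVector& mu_,
              const NumericMatrix& Q_) {
    k = lam_.size();
    lam.assign(lam_.begin(), lam_.end());
    mu.assign(mu_.begin(), mu_.end());
    Q.resize(k * k);
    decay.resize(k);
    for (int i = 0; i < k; ++i) {
      double qs = 0.0;
      for (int j = 0; j < k; ++j) {
        Q[i * k + j] = Q_(i, j);
        if (j != i) qs += Q_(i, j);
      }
      decay[i] = lam[i] + mu[i] + qs;
    }
  }

  // y = (E_1..E_k, D_1..D_k)
  void rhs(const double* y, double* dy) const {
    const double* E = y;
    const double* D = y + k;
    if (k == 2) {  // unrolled: the dominant case in practice
      const double q12 = Q[1], q21 = Q[2];
      dy[0] = mu[0] - decay[0] * E[0] + lam[0] * E[0] * E[0] + q12 * E[1];
      dy[1] = mu[1] - decay[1] * E[1] + lam[1] * E[1] * E[1] + q21 * E[0];
      dy[2] = (2.0 * lam[0] * E[0] - decay[0]) * D[0] + q12 * D[1];
      dy[3] = (2.0 * lam[1] * E[1] - decay[1]) * D[1] + q21 * D[0];
      return;
    }
    for (int i = 0; i < k; ++i) {
      double qe = 0.0, qd = 0.0;
      const double* qrow = &Q[i * k];
      for (int j = 0; j < k; ++j) {
        if (j == i) continue;
        qe += qrow[j] * E[j];
        qd += qrow[j] * D[j];
      }
      dy[i]     = mu[i] - decay[i] * E[i] + lam[i] * E[i] * E[i] + qe;
      dy[k + i] = -decay[i] * D[i] + 2.0 * lam[i] * E[i] * D[i] + qd;
    }
  }
};

// Dormand-Prince 5(4) coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
             e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Scratch buffers reused across every branch of a pruning pass; per-call
// allocation would otherwise dominate the runtime on large trees.
struct Workspace {
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, ytmp, y5;
  explicit Workspace(int n)
      : k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n), ytmp(n), y5(n) {}
};

// Integrate y over [0, len]; y modified in place.
void propagate(const MusseSystem& sys, Workspace& ws, std::vector<double>& y,
               double len, double rtol, double atol) {
  if (len <= 0.0) return;
  const int n = 2 * sys.k;
  std::vector<double>&k1 = ws.k1, &k2 = ws.k2, &k3 = ws.k3, &k4 = ws.k4,
      &k5 = ws.k5, &k6 = ws.k6, &k7 = ws.k7, &ytmp = ws.ytmp, &y5 = ws.y5;
  double t = 0.0;
  double h = len;
  int nsteps = 0;
  sys.rhs(y.data(), k1.data());  // FSAL
  while (t < len) {
    if (++nsteps > 1000000)
      stop("ODE integration exceeded the step budget on a branch");
    if (t + h > len) h = len - t;
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    sys.rhs(ytmp.data(), k2.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sys.rhs(ytmp.data(), k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sys.rhs(ytmp.data(), k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    sys.rhs(ytmp.data(), k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    sys.rhs(ytmp.data(), k6.data());
    for (int i = 0; i < n; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    sys.rhs(y5.data(), k7.data());
    // error estimate: 5th order solution minus embedded 4th order
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = std::fabs(y5[i] - y4) / sc;
      if (e > errnorm) errnorm = e;
    }
    if (errnorm <= 1.0) {
      t += h;
      y.swap(y5);
      k1.swap(k7);  // FSAL reuse
      // keep the solution in its physical domain
      for (int i = 0; i < sys.k; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
        if (y[sys.k + i] < 0.0) y[sys.k + i] = 0.0;
      }
    }
    double fac = 0.9 * std::pow(errnorm > 1e-30 ? errnorm : 1e-30, -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-14 * len)
      stop("ODE step size underflow during branch integration");
    if (errnorm > 1.0) sys.rhs(y.data(), k1.data());
  }
}

struct PruneCache {
  int k, ntip, nnode, nedge, root;
  std::vector<double> nodeD;     // post-merge, normalised, per node (k each)
  std::vector<double> nodeE;     // per node
  std::vector<double> nodeLogc;  // accumulated log scaler per node
  std::vector<double> edgeTopD;  // per edge: normalised D at parent end
  std::vector<double> edgeTopE;
  std::vector<double> edgeLogc;  // log scaler of this edge's top D alone
  std::vector<int> parent, childEdge;  // per node: parent id (0 = none),
                                       // index of edge leading down to it
  std::vector<std::vector<int>> childEdges;  // per node: outgoing edge idx
};

// Full postorder pruning pass. edge is the ape edge matrix (1-based ids,
// tips 1..ntip) already in postorder.
void prune(const IntegerMatrix& edge, const NumericVector& edge_length,
           int ntip, const NumericMatrix& tipD, const MusseSystem& sys,
           double rtol, double atol, PruneCache& pc) {
  const int k = sys.k;
  const int nedge = edge.nrow();
  const int nnodes = nedge + 1;  // total node count for a rooted tree
  pc.k = k;
  pc.ntip = ntip;
  pc.nedge = nedge;
  pc.nnode = nnodes;
  pc.nodeD.assign((size_t)nnodes * k, -1.0);
  pc.nodeE.assign((size_t)nnodes * k, 0.0);
  pc.nodeLogc.assign(nnodes, 0.0);
  pc.edgeTopD.assign((size_t)nedge * k, 0.0);
  pc.edgeTopE.assign((size_t)nedge * k, 0.0);
  pc.edgeLogc.assign(nedge, 0.0);
  pc.parent.assign(nnodes, 0);
  pc.childEdge.assign(nnodes, -1);
  pc.childEdges.assign(nnodes, std::vector<int>());

  std::vector<int> nchild(nnodes, 0);
  // tip initial conditions
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < k; ++s) pc.nodeD[(size_t)i * k + s] = tipD(i, s);

  std::vector<double> y(2 * k);
  Workspace ws(2 * k);
  for (int e = 0; e < nedge; ++e) {
    int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    pc.parent[ch] = par + 1;
    pc.childEdge[ch] = e;
    pc.childEdges[par].push_back(e);
    if (pc.nodeD[(size_t)ch * k] < 0.0)
      stop("postorder violation: child node visited before its subtree");
    for (int s = 0; s < k; ++s) {
      y[s] = pc.nodeE[(size_t)ch * k + s];
      y[k + s] = pc.nodeD[(size_t)ch * k + s];
    }
    propagate(sys, ws, y, edge_length[e], rtol, atol);
    double sumD = 0.0;
    for (int s = 0; s < k; ++s) sumD += y[k + s];
    if (!(sumD > 0.0) || !std::isfinite(sumD))
      stop("likelihood vanished or became non-finite on edge %d", e + 1);
    for (int s = 0; s < k; ++s) {
      pc.edgeTopE[(size_t)e * k + s] = y[s];
      pc.edgeTopD[(size_t)e * k + s] = y[k + s] / sumD;
    }
    pc.edgeLogc[e] = std::log(sumD);
    // merge into parent
    double* pd = &pc.nodeD[(size_t)par * k];
    double* pe = &pc.nodeE[(size_t)par * k];
    if (nchild[par] == 0) {
      for (int s = 0; s < k; ++s) {
        pd[s] = pc.edgeTopD[(size_t)e * k + s];
        pe[s] = y[s];
      }
      pc.nodeLogc[par] = pc.nodeLogc[ch] + pc.edgeLogc[e];
    } else {
      double sm = 0.0;
      for (int s = 0; s < k; ++s) {
        pd[s] *= sys.lam[s] * pc.edgeTopD[(size_t)e * k + s];
        pe[s] = 0.5 * (pe[s] + y[s]);
        sm += pd[s];
      }
      if (!(sm > 0.0) || !std::isfinite(sm))
        stop("likelihood vanished at the merge above edge %d", e + 1);
      for (int s = 0; s < k; ++s) pd[s] /= sm;
      pc.nodeLogc[par] += pc.nodeLogc[ch] + pc.edgeLogc[e] + std::log(sm);
    }
    nchild[par]++;
  }
  pc.root = edge(nedge - 1, 0) - 1;  // postorder: last edge points at root
}

// Root-level log-likelihood from a (normalised) root D with log scaler.
// root_mode: 1 = FitzJohn state weighting, 2 = flat, 3 = given pi.
double root_loglik(const MusseSystem& sys, const std::vector<double>& D,
                   const std::vector<double>& E, double logc, int root_mode,
                   const NumericVector& pi_given, bool condition) {
  const int k = sys.k;
  std::vector<double> pi(k);
  double sd = 0.0;
  for (int s = 0; s < k; ++s) sd += D[s];
  if (root_mode == 1) {
    if (!(sd > 0.0)) return R_NegInf;
    for (int s = 0; s < k; ++s) pi[s] = D[s] / sd;
  } else if (root_mode == 2) {
    for (int s = 0; s < k; ++s) pi[s] = 1.0 / k;
  } else {
    for (int s = 0; s < k; ++s) pi[s] = pi_given[s];
  }
  double lik = 0.0;
  for (int s = 0; s < k; ++s) lik += pi[s] * D[s];
  if (condition) {
    double cfac = 0.0;
    for (int s = 0; s < k; ++s)
      cfac += pi[s] * sys.lam[s] * (1.0 - E[s]) * (1.0 - E[s]);
    if (!(cfac > 0.0)) return R_NegInf;
    lik /= cfac;
  }
  if (!(lik > 0.0)) return R_NegInf;
  return std::log(lik) + logc;
}

}  // namespace

// [[Rcpp::export]]
double musse_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                        int ntip, NumericMatrix tipD, NumericVector lam,
                        NumericVector mu, NumericMatrix Q, int root_mode,
                        NumericVector pi_given, bool condition, double rtol,
                        double atol) {
  MusseSystem sys(lam, mu, Q);
  PruneCache pc;
  prune(edge, edge_length, ntip, tipD, sys, rtol, atol, pc);
  const int k = sys.k;
  std::vector<double> D(pc.nodeD.begin() + (size_t)pc.root * k,
                        pc.nodeD.begin() + (size_t)(pc.root + 1) * k);
  std::vector<double> E(pc.nodeE.begin() + (size_t)pc.root * k,
                        pc.nodeE.begin() + (size_t)(pc.root + 1) * k);
  return root_loglik(sys, D, E, pc.nodeLogc[pc.root], root_mode, pi_given,
                     condition);
}

// Marginal ancestral states: for every node, clamp its state and rebuild
// the likelihood along the node-to-root path, reusing cached subtree
// partials everywhere off the path; normalise over states.
// [[Rcpp::export]]
NumericMatrix musse_marginals_cpp(IntegerMatrix edge,
                                  NumericVector edge_length, int ntip,
                                  NumericMatrix tipD, NumericVector lam,
                                  NumericVector mu, NumericMatrix Q,
                                  int root_mode, NumericVector pi_given,
                                  bool condition, double rtol, double atol) {
  MusseSystem sys(lam, mu, Q);
  PruneCache pc;
  prune(edge, edge_length, ntip, tipD, sys, rtol, atol, pc);
  const int k = sys.k;
  const int nnodes = pc.nnode;
  NumericMatrix out(nnodes, k);
  std::vector<double> y(2 * k), D(k), E(k);
  Workspace ws(2 * k);

  for (int v = 0; v < nnodes; ++v) {
    std::vector<double> ll(k, R_NegInf);
    for (int s0 = 0; s0 < k; ++s0) {
      if (pc.nodeD[(size_t)v * k + s0] <= 0.0) continue;  // inadmissible
      // clamp node v to state s0
      for (int s = 0; s < k; ++s) D[s] = (s == s0) ? pc.nodeD[(size_t)v * k + s] : 0.0;
      double logc = pc.nodeLogc[v];
      int cur = v;
      while (pc.parent[cur] != 0) {
        int par = pc.parent[cur] - 1;
        int e = pc.childEdge[cur];
        for (int s = 0; s < k; ++s) {
          y[s] = pc.nodeE[(size_t)cur * k + s];
          y[k + s] = D[s];
        }
        propagate(sys, ws, y, edge_length[e], rtol, atol);
        // merge with the cached branch tops of cur's siblings
        double sm = 0.0;
        bool internal_par = pc.childEdges[par].size() > 1;
        for (int s = 0; s < k; ++s) D[s] = y[k + s];
        if (internal_par) {
          for (int s = 0; s < k; ++s) D[s] *= sys.lam[s];
          for (int oe : pc.childEdges[par]) {
            if (oe == e) continue;
            for (int s = 0; s < k; ++s)
              D[s] *= pc.edgeTopD[(size_t)oe * k + s];
            logc += pc.edgeLogc[oe];
            int och = edge(oe, 1) - 1;
            logc += pc.nodeLogc[och];
          }
        }
        for (int s = 0; s < k; ++s) sm += D[s];
        if (!(sm > 0.0)) { logc = R_NegInf; break; }
        for (int s = 0; s < k; ++s) D[s] /= sm;
        logc += std::log(sm);
        cur = par;
      }
      if (!std::isfinite(logc)) continue;
      for (int s = 0; s < k; ++s) E[s] = pc.nodeE[(size_t)cur * k + s];
      ll[s0] = root_loglik(sys, D, E, logc, root_mode, pi_given, condition);
    }
    double mx = R_NegInf;
    for (int s = 0; s < k; ++s) mx = std::max(mx, ll[s]);
    double tot = 0.0;
    if (std::isfinite(mx)) {
      for (int s = 0; s < k; ++s)
        if (std::isfinite(ll[s])) tot += std::exp(ll[s] - mx);
    }
    for (int s = 0; s < k; ++s)
      out(v, s) = (std::isfinite(mx) && std::isfinite(ll[s]))
                      ? std::exp(ll[s] - mx) / tot
                      : 0.0;
  }
  return out;
}

// Single-branch propagation, exposed for diagnostics and tests.
// [[Rcpp::export]]
NumericVector musse_branch_cpp(NumericVector E0, NumericVector D0,
                               double len, NumericVector lam,
                               NumericVector mu, NumericMatrix Q,
                               double rtol, double atol) {
  MusseSystem sys(lam, mu, Q);
  int k = lam.size();
  std::vector<double> y(2 * k);
  for (int s = 0; s < k; ++s) {
    y[s] = E0[s];
    y[k + s] = D0[s];
  }
  Workspace ws(2 * k);
  propagate(sys, ws, y, len, rtol, atol);
  return NumericVector(y.begin(), y.end());
}
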