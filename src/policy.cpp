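// Dynamic-programming solution of the earning-rate-optimal stopping policy.
//
// States are <x, t> on a uniform grid; actions are left / right / fix.
// Terminal values use the analytic coherence posterior (Gaussian likelihoods
// times the prior, renormalised), which holds regardless of bound shape or
// provisional deadlines. The continuation value marginalises the one-step
// Gaussian transition over the coherence posterior. The earning rate rho is
// located by bisection on V(s0) = 0; value and policy are symmetric under
// x -> -x with left/right relabelled, so only x >= 0 is computed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct PolicyGrid {
  int N, half, T, K, wband;
  double dx, dt;
  std::vector<double> coh, prior, fk, ak; // fk = exp(kappa*coh*dx)
  std::vector< std::vector<double> > g;   // per-coherence step kernel
};

// posterior p(coh_k | x_j, t) for j >= half, into wpost[k][j-half]
static void posterior_half(const PolicyGrid& G, double kappa, int it,
                           std::vector< std::vector<double> >& wpost) {
  const double t = it * G.dt;
  const int H = G.N - G.half;
  std::vector<double> norm(H, 0.0);
  for (int k = 0; k < G.K; ++k) {
    double Ak = (it == 0) ? 1.0 : std::exp(-0.5 * kappa * kappa * G.coh[k] * G.coh[k] * t);
    double e = G.prior[k] * Ak;
    const double f = (it == 0) ? 1.0 : G.fk[k];
    for (int j = 0; j < H; ++j) {
      wpost[k][j] = e;
      norm[j] += e;
      e *= f;
    }
  }
  for (int k = 0; k < G.K; ++k)
    for (int j = 0; j < H; ++j) wpost[k][j] /= norm[j];
}

// One backward induction for a candidate rho. Fills bounds (length T) when
// record = true. Returns V at the origin, t = 0.
static double backward_value(const PolicyGrid& G, double kappa, double rho,
                             double term_cost, double cancel_cost,
                             double Rc, double Re, double Rcancel,
                             const std::vector<double>& pcancel,
                             bool record, std::vector<double>& bounds) {
  const int H = G.N - G.half; // nodes with x >= 0
  std::vector<double> V(G.N), Vh(H), EVk(H);
  std::vector< std::vector<double> > wpost(G.K, std::vector<double>(H));
  std::vector< std::vector<double> > conv(G.K, std::vector<double>(H));

  // terminal slice t = T: forced choice of the better side
  posterior_half(G, kappa, G.T, wpost);
  for (int j = 0; j < H; ++j) {
    double pc = 0.0;
    for (int k = 0; k < G.K; ++k) {
      if (G.coh[k] > 0) pc += wpost[k][j];
      else if (G.coh[k] == 0) pc += 0.5 * wpost[k][j];
    }
    Vh[j] = pc * Rc + (1.0 - pc) * Re - rho * term_cost;
  }
  for (int j = 0; j < H; ++j) { V[G.half + j] = Vh[j]; V[G.half - j] = Vh[j]; }

  for (int it = G.T - 1; it >= 0; --it) {
    // continuation: per-coherence convolution of V(., t+dt) with the step kernel
    for (int k = 0; k < G.K; ++k) {
      const std::vector<double>& gk = G.g[k];
      for (int j = 0; j < H; ++j) {
        double s = 0.0;
        int jj = G.half + j;
        for (int b = -G.wband; b <= G.wband; ++b) {
          int idx = jj + b;
          if (idx < 0) idx = 0;
          if (idx >= G.N) idx = G.N - 1;
          s += gk[b + G.wband] * V[idx];
        }
        conv[k][j] = s;
      }
    }
    posterior_half(G, kappa, it, wpost);
    double pc_t = pcancel.empty() ? 0.0 : pcancel[it];
    int frontier = -1;
    for (int j = H - 1; j >= 0; --j) {
      double pc = 0.0, ev = 0.0;
      for (int k = 0; k < G.K; ++k) {
        if (G.coh[k] > 0) pc += wpost[k][j];
        else if (G.coh[k] == 0) pc += 0.5 * wpost[k][j];
        ev += wpost[k][j] * conv[k][j];
      }
      double Qterm = pc * Rc + (1.0 - pc) * Re - rho * term_cost;
      double Qfix = (1.0 - pc_t) * (ev - rho * G.dt)
        + pc_t * (Rcancel - rho * cancel_cost);
      if (Qterm >= Qfix) { Vh[j] = Qterm; frontier = j; }
      else Vh[j] = Qfix;
    }
    // frontier = smallest j >= 0 (x >= 0) where terminating is optimal
    if (record) {
      if (frontier < 0) bounds[it] = (H - 1) * G.dx;        // never terminate
      else if (frontier == 0) bounds[it] = 0.0;
      else bounds[it] = (frontier - 0.5) * G.dx;            // between nodes
    }
    for (int j = 0; j < H; ++j) { V[G.half + j] = Vh[j]; V[G.half - j] = Vh[j]; }
  }
  return V[G.half];
}

// [[Rcpp::export]]
List cpp_solve_policy(double kappa, NumericVector coh, NumericVector prior,
                      double dx, double xmax, double dt, double tmax,
                      double term_cost, double cancel_cost,
                      double Rc, double Re, double Rcancel,
                      NumericVector pcancel,
                      double rho_lo, double rho_hi, double rho_tol) {
  PolicyGrid G;
  G.dx = dx; G.dt = dt;
  G.half = (int)std::round(xmax / dx);
  G.N = 2 * G.half + 1;
  G.T = (int)std::round(tmax / dt);
  G.K = coh.size();
  G.coh.assign(coh.begin(), coh.end());
  G.prior.assign(prior.begin(), prior.end());
  G.fk.resize(G.K); G.ak.resize(G.K);
  for (int k = 0; k < G.K; ++k) G.fk[k] = std::exp(kappa * G.coh[k] * dx);

  // discretised one-step Gaussian transition kernels (rows sum to one)
  const double sd = std::sqrt(dt);
  G.wband = (int)std::ceil(5.0 * sd / dx);
  G.g.assign(G.K, std::vector<double>(2 * G.wband + 1));
  for (int k = 0; k < G.K; ++k) {
    double mu = kappa * G.coh[k] * dt, tot = 0.0;
    for (int b = -G.wband; b <= G.wband; ++b) {
      double z = (b * dx - mu) / sd;
      double w = std::exp(-0.5 * z * z);
      G.g[k][b + G.wband] = w; tot += w;
    }
    for (size_t b = 0; b < G.g[k].size(); ++b) G.g[k][b] /= tot;
  }

  std::vector<double> pc;
  if (pcancel.size() > 0) pc.assign(pcancel.begin(), pcancel.end());
  std::vector<double> bounds(G.T, 0.0);

  // bisection on rho: V(s0; rho) is decreasing in rho
  double lo = rho_lo, hi = rho_hi;
  double vlo = backward_value(G, kappa, lo, term_cost, cancel_cost, Rc, Re,
                              Rcancel, pc, false, bounds);
  double vhi = backward_value(G, kappa, hi, term_cost, cancel_cost, Rc, Re,
                              Rcancel, pc, false, bounds);
  if (vlo < 0 || vhi > 0)
    stop("bisection bracket does not contain the optimal earning rate: V(s0) = %g at rho = %g, %g at rho = %g",
         vlo, lo, vhi, hi);
  double mid = 0.5 * (lo + hi), vmid = 0.0;
  while (hi - lo > rho_tol) {
    mid = 0.5 * (lo + hi);
    vmid = backward_value(G, kappa, mid, term_cost, cancel_cost, Rc, Re,
                          Rcancel, pc, false, bounds);
    if (vmid > 0) lo = mid; else hi = mid;
  }
  mid = 0.5 * (lo + hi);
  double v0 = backward_value(G, kappa, mid, term_cost, cancel_cost, Rc, Re,
                             Rcancel, pc, true, bounds);
  return List::create(_["rho"] = mid, _["value_origin"] = v0,
                      _["bounds"] = NumericVector(bounds.begin(), bounds.end()),
                      _["n_x"] = G.N, _["n_t"] = G.T);
}
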