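// Euler-Maruyama simulation of bounded drift-diffusion decisions.
// All randomness is drawn from R's RNG so a single set.seed() controls it.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Simulate first passage through symmetric time-varying bounds for a batch
// of trials. drift: per-trial drift rate kappa*coh. The bound is supplied on
// its own grid (bvals every bdt seconds, linear interpolation, last value
// held beyond its support). Returns choice (+1 upper / -1 lower / 0 if no
// crossing by tmax), decision time, and optionally the decision-variable
// value of still-undecided trials at time snapshot_t (NA otherwise).
// [[Rcpp::export]]
List cpp_sim_trials(NumericVector drift, double dt, NumericVector bvals,
                    double bdt, double tmax, double snapshot_t) {
  const int n = drift.size();
  const int steps = (int)std::ceil(tmax / dt);
  const int nb = bvals.size();

  // precompute the bound at every simulation step
  std::vector<double> B(steps + 1);
  for (int i = 0; i <= steps; ++i) {
    double t = i * dt;
    double u = t / bdt;
    int j = (int)std::floor(u);
    if (j >= nb - 1) B[i] = bvals[nb - 1];
    else {
      double f = u - j;
      B[i] = (1.0 - f) * bvals[j] + f * bvals[j + 1];
    }
  }
  int snap_step = snapshot_t >= 0 ? (int)std::round(snapshot_t / dt) : -1;

  IntegerVector choice(n);
  NumericVector td(n), xsnap(n, NA_REAL);
  const double sdt = std::sqrt(dt);

  for (int i = 0; i < n; ++i) {
    double x = 0.0;
    int ch = 0;
    double t_dec = NA_REAL;
    if (B[0] <= 0.0) { // degenerate bound at t = 0: immediate random choice
      ch = (unif_rand() < 0.5) ? 1 : -1;
      t_dec = 0.0;
    } else {
      for (int s = 1; s <= steps; ++s) {
        x += drift[i] * dt + sdt * norm_rand();
        if (snap_step == s) xsnap[i] = x;
        double b = B[s];
        if (x >= b) { ch = 1; t_dec = s * dt; break; }
        if (x <= -b) { ch = -1; t_dec = s * dt; break; }
      }
    }
    if (ch != 0 && snap_step >= 0 && !(t_dec > snapshot_t)) xsnap[i] = NA_REAL;
    choice[i] = ch;
    td[i] = t_dec;
  }
  return List::create(_["choice"] = choice, _["td"] = td,
                      _["x_snapshot"] = xsnap);
}
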