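#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the resource-capped activation dynamics for a
// full trajectory. Node order matches the host cache (protein-id order); the
// parasite, when present, is an extra node with three fixed links. All state
// is clamped to [0,1] after each unit step. The resource cap scales positive
// deltas (parasite included) so their sum never exceeds the limit.
//
// dev_detector / par_* indices are 1-based; 0 disables the corresponding
// feature (no developmental input, non-disrupting parasite, no infection).
// [[Rcpp::export]]
List run_life_cpp(NumericMatrix K, NumericMatrix I, IntegerVector out_deg,
                  NumericVector state0, int n_steps, double limit,
                  double use_coef,
                  int dev_detector, NumericVector dev_values,
                  LogicalVector dev_active,
                  int infection_step, double par_init,
                  int par_detector, double par_detector_coef,
                  int par_target, double par_target_coef,
                  double par_self,
                  int par_effector, double par_effector_coef) {
  const int n = state0.size();
  NumericMatrix states(n_steps, n);
  NumericVector par_series(n_steps, NA_REAL);
  std::vector<double> p(state0.begin(), state0.end());
  std::vector<double> up(n), down(n), delta(n);
  // row-major copies so the j-loop walks contiguous memory
  std::vector<double> Kr(n * n), Ir(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      Kr[i * n + j] = K(i, j);
      Ir[i * n + j] = I(i, j);
    }
  double* states_ptr = REAL(states);
  const int* dev_act = LOGICAL(dev_active);
  const double* dev_val = REAL(dev_values);
  double V = NA_REAL;
  bool infected = false;
  const int par_links = (par_target > 0) ? 3 : 2;

  for (int t = 0; t < n_steps; ++t) {
    if (infection_step > 0 && (t + 1) == infection_step) {
      infected = true;
      V = par_init;
    }
    for (int i = 0; i < n; ++i) {
      double u = 0.0, d = 0.0;
      const double* Ki = &Kr[i * n];
      const double* Ii = &Ir[i * n];
      for (int j = 0; j < n; ++j) {
        u += Ki[j] * p[j];
        d += Ii[j] * p[j];
      }
      up[i] = u;
      down[i] = d;
    }
    if (dev_detector > 0 && dev_act[t])
      up[dev_detector - 1] += dev_val[t];  // fixed +1 link from signal node

    double dV = 0.0;
    if (infected) {
      up[par_detector - 1] += par_detector_coef * V;
      if (par_target > 0) {
        if (par_target_coef >= 0.0) up[par_target - 1] += par_target_coef * V;
        else down[par_target - 1] -= par_target_coef * V;
      }
      dV = (1.0 - V) * par_self * V
         - V * std::fabs(par_effector_coef) * p[par_effector - 1]
         - use_coef * par_links;
    }

    double pos_sum = 0.0;
    for (int i = 0; i < n; ++i) {
      int deg = out_deg[i];
      if (infected && i == (par_effector - 1)) deg += 1;
      delta[i] = (1.0 - p[i]) * up[i] - p[i] * down[i] - use_coef * deg;
      if (delta[i] > 0.0) pos_sum += delta[i];
    }
    if (infected && dV > 0.0) pos_sum += dV;

    if (pos_sum > limit) {
      const double scale = limit / pos_sum;
      for (int i = 0; i < n; ++i)
        if (delta[i] > 0.0) delta[i] *= scale;
      if (infected && dV > 0.0) dV *= scale;
    }

    for (int i = 0; i < n; ++i) {
      p[i] += delta[i];
      if (p[i] < 0.0) p[i] = 0.0;
      if (p[i] > 1.0) p[i] = 1.0;
      states_ptr[(size_t)i * n_steps + t] = p[i];
    }
    if (infected) {
      V += dV;
      if (V < 0.0) V = 0.0;
      if (V > 1.0) V = 1.0;
      par_series[t] = V;
    }
  }
  return List::create(_["states"] = states, _["parasite"] = par_series);
}
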