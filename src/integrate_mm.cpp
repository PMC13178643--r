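#include <Rcpp.h>
using namespace Rcpp;

// Michaelis-Menten clearance with instantaneous pulsed release.
//
// State equation between pulses:  dC/dt = -vmax * C / (km_app + C)
// At each pulse time the concentration jumps by `dap` (release per pulse).
//
// Fixed-step classical RK4 at `dt` internal resolution; the state is sampled
// (zero-order hold at the most recent internal step) onto `times`, which must
// be non-decreasing. Pulse times are snapped to the nearest internal step so
// the jump is applied exactly once.

static inline double mm_rate(double c, double vmax, double km) {
  return -vmax * c / (km + c);
}

// [[Rcpp::export]]
NumericVector mm_integrate_cpp(NumericVector times, NumericVector pulse_times,
                               double dap, double vmax, double km_app,
                               double dt) {
  const int n = times.size();
  NumericVector out(n);
  if (n == 0) return out;

  double t0 = times[0];
  double t_end = times[n - 1];
  if (t0 > 0) t0 = 0.0;  // always integrate from session start

  // pulse bookkeeping: snap to grid index
  const int n_steps = (int)std::ceil((t_end - t0) / dt) + 1;
  std::vector<long long> pulse_idx(pulse_times.size());
  for (int i = 0; i < pulse_times.size(); ++i)
    pulse_idx[i] = (long long)std::llround((pulse_times[i] - t0) / dt);

  double c = 0.0;
  int out_i = 0, pulse_i = 0;
  for (long long step = 0; step <= n_steps; ++step) {
    double t = t0 + step * dt;
    // apply any pulse scheduled at this step (before sampling)
    while (pulse_i < (int)pulse_idx.size() && pulse_idx[pulse_i] == step) {
      c += dap;
      ++pulse_i;
    }
    // emit samples whose time has been reached
    while (out_i < n && times[out_i] <= t + 1e-12) {
      out[out_i] = c;
      ++out_i;
    }
    if (out_i >= n) break;
    // RK4 step
    double k1 = mm_rate(c, vmax, km_app);
    double k2 = mm_rate(c + 0.5 * dt * k1, vmax, km_app);
    double k3 = mm_rate(c + 0.5 * dt * k2, vmax, km_app);
    double k4 = mm_rate(c + dt * k3, vmax, km_app);
    c += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (c < 0.0) c = 0.0;  // clearance cannot push concentration negative
    if (!std::isfinite(c))
      stop("non-finite state during integration (vmax=%f, km_app=%f, dap=%f)",
           vmax, km_app, dap);
  }
  return out;
}
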