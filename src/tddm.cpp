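#include <Rcpp.h>
using namespace Rcpp;

// Euler simulation of first-passage times for a two-stage drift process:
// the drift is drift_early until switch_time, drift_late afterwards.
// Absorption at 0 (avoid) or threshold (engage); start at start_bias *
// threshold. Walks still alive at max_t are truncated and classified by
// which boundary they are closer to. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
DataFrame tddm_simulate_cpp(int n, double drift_early, double drift_late,
                            double switch_time, double threshold,
                            double start_bias, double ndt, double dt,
                            double noise_sd, double max_t) {
  IntegerVector choice(n);
  NumericVector rt(n);
  LogicalVector truncated(n);
  const double sdt = noise_sd * std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = start_bias * threshold;
    double t = 0.0;
    int ch = 0;
    bool tr = false;
    for (;;) {
      const double drift = (t < switch_time) ? drift_early : drift_late;
      x += drift * dt + sdt * norm_rand();
      t += dt;
      if (x >= threshold) { ch = 1; break; }
      if (x <= 0.0) { ch = 0; break; }
      if (t >= max_t) { ch = (x >= 0.5 * threshold) ? 1 : 0; tr = true; break; }
    }
    choice[i] = ch;
    rt[i] = t + ndt;
    truncated[i] = tr;
  }
  return DataFrame::create(_["choice"] = choice, _["rt"] = rt,
                           _["truncated"] = truncated);
}
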