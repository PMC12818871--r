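// Adapting Markov spiking process: per-step hazard equal to the requested
// rate minus a spike-triggered adaptation state, with a mean-field gain
// that makes the long-run emitted rate match the requested rate.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".adapting_markov")]]
NumericVector adapting_markov(NumericVector rate_hz, double dt_ms,
                              double tau_adapt_ms, double incr_hz,
                              double seed) {
  const int n = rate_hz.size();
  std::mt19937_64 rng((unsigned long) seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double dec = std::exp(-dt_ms / tau_adapt_ms);
  const double load = incr_hz * tau_adapt_ms / 1000.0; // stationary a / rate
  if (load >= 1.0) stop("adaptation increment too large for rate matching");
  const double gain = 1.0 / (1.0 - load);
  double a = 0.0;
  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    double r = rate_hz[i];
    if (r < 0.0) stop("negative input rate at step %d; truncate first", i + 1);
    double h = gain * (r - a);
    if (h > 0.0) {
      double p = h * dt_ms / 1000.0;
      if (unif(rng) < p) {
        out.push_back((i + 1) * dt_ms);
        a += incr_hz;
      }
    }
    a *= dec;
  }
  return wrap(out);
}
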