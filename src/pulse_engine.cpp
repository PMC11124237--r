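// Pulse-train synthesis and threshold counting on 1 ns sampled signals.
//
// Counting semantics (both behaviors):
//  - an upward crossing is sample[t-1] < threshold <= sample[t] (the sample
//    before the first one is implicitly zero); ties count as above;
//  - NP-like: a crossing with no active analysis window opens a window of
//    tau_np samples and yields exactly one count; crossings during the
//    window are ignored; after it closes a fresh upward crossing is
//    required (the signal must first fall below threshold);
//  - P-like: every upward crossing yields one count; a prolonged excursion
//    above threshold yields no further counts (paralyzable character);
//  - registered energy = maximum sample over the first tau_pd samples from
//    the crossing (no interpolation).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_synthesize(int n_samples, NumericVector times,
                             NumericVector energies, NumericVector pulse) {
  NumericVector sig(n_samples);
  const int np = pulse.size();
  const int n = times.size();
  for (int i = 0; i < n; ++i) {
    const int t0 = (int)std::floor(times[i]);
    const double e = energies[i];
    int j0 = t0 < 0 ? -t0 : 0;
    int j1 = std::min(np, n_samples - t0);
    for (int j = j0; j < j1; ++j) sig[t0 + j] += e * pulse[j];
  }
  return sig;
}

static void scan_signal(const std::vector<double>& sig, double threshold,
                        int tau_pd, int tau_np, bool paralyzable,
                        double t_offset, double t_max,
                        std::vector<double>& out_t,
                        std::vector<double>& out_e) {
  const int n = (int)sig.size();
  double prev = 0.0;
  long window_end = -1;
  for (int t = 0; t < n; ++t) {
    const double cur = sig[t];
    if (prev < threshold && cur >= threshold) {
      if (paralyzable || (long)t >= window_end) {
        double emax = 0.0;
        const int hi = std::min(t + tau_pd, n);
        for (int q = t; q < hi; ++q) emax = std::max(emax, sig[q]);
        const double abst = t_offset + t;
        if (abst < t_max) {
          out_t.push_back(abst);
          out_e.push_back(emax);
        }
        if (!paralyzable) window_end = (long)t + tau_np;
      }
    }
    prev = cur;
  }
}

// [[Rcpp::export]]
List cpp_count_signal(NumericVector signal, double threshold, int tau_pd,
                      int tau_np, bool paralyzable) {
  std::vector<double> sig(signal.begin(), signal.end());
  std::vector<double> out_t, out_e;
  scan_signal(sig, threshold, tau_pd, tau_np, paralyzable, 0.0,
              R_PosInf, out_t, out_e);
  return List::create(_["time"] = wrap(out_t), _["energy"] = wrap(out_e));
}

// Event-driven counting for one pixel: events separated by more than the
// pulse support plus both windows cannot interact, so the signal is
// synthesized and scanned cluster by cluster. Cost scales with the number
// of events, not with the exposure duration. `times` must be ascending.
// [[Rcpp::export]]
List cpp_count_events(NumericVector times, NumericVector energies,
                      NumericVector pulse, double threshold, int tau_pd,
                      int tau_np, bool paralyzable, double duration) {
  const int n = times.size();
  std::vector<double> out_t, out_e;
  const int support = pulse.size();
  const long tail = (long)support + tau_np + tau_pd + 2;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n &&
           (long)std::floor(times[j + 1]) <=
               (long)std::floor(times[j]) + tail)
      ++j;
    const long start = (long)std::floor(times[i]);
    const long end = (long)std::floor(times[j]) + tail;
    const int len = (int)(end - start + 1);
    std::vector<double> sig(len, 0.0);
    for (int k = i; k <= j; ++k) {
      const int off = (int)((long)std::floor(times[k]) - start);
      const double e = energies[k];
      const int hi = std::min(support, len - off);
      for (int p = 0; p < hi; ++p) sig[off + p] += e * pulse[p];
    }
    scan_signal(sig, threshold, tau_pd, tau_np, paralyzable,
                (double)start, duration, out_t, out_e);
    i = j + 1;
  }
  return List::create(_["time"] = wrap(out_t), _["energy"] = wrap(out_e));
}
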