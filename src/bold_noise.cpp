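#include <Rcpp.h>
using namespace Rcpp;

// Assemble one run's BOLD matrix: baseline + signal + AR(1) noise + slow
// sinusoidal drift, generating (and discarding) n_discard leading volumes.
// Uses R's RNG (one runif phase per voxel, then one rnorm innovation per
// voxel x generated volume), so results are reproducible under set.seed().
// [[Rcpp::export(name = ".assembleRunData")]]
NumericMatrix assembleRunData(const NumericMatrix& signal,
                              int n_discard, double sd_e, double phi,
                              double drift_amp,
                              const NumericVector& cos_wt,
                              const NumericVector& sin_wt,
                              double baseline) {
  const int V = signal.nrow();
  const int n_vol = signal.ncol();
  const int n_gen = n_vol + n_discard;
  if (cos_wt.size() != n_gen || sin_wt.size() != n_gen) {
    stop("drift phase tables must have n_vol + n_discard entries");
  }
  NumericMatrix out(V, n_vol);
  RNGScope scope;
  for (int v = 0; v < V; ++v) {
    const double phase = R::runif(0.0, 2.0 * M_PI);
    const double sp = std::sin(phase), cp = std::cos(phase);
    double prev = 0.0;
    for (int t = 0; t < n_gen; ++t) {
      const double cur = R::rnorm(0.0, sd_e) + phi * prev;
      prev = cur;
      if (t >= n_discard) {
        const int k = t - n_discard;
        out(v, k) = baseline + signal(v, k) + cur +
          drift_amp * (sp * cos_wt[t] + cp * sin_wt[t]);
      }
    }
  }
  return out;
}
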