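#include <Rcpp.h>
using namespace Rcpp;

// Fused assembly of one strobed-trial movie: per-pixel calcium transient +
// shared per-frame channel baselines (hemodynamic artifact included) +
// Gaussian shot noise, quantized to the 12-bit range and interleaved
// fluorescence-first. A single pass avoids the intermediate full-frame
// matrices that dominate runtime in plain R. Noise is drawn from R's RNG,
// so results are reproducible under set.seed().
//
// base_f, base_r: per-frame channel baselines in counts (length n60 each).
// kern_counts:    transient kernel in counts per unit percent amplitude
//                 (length n60; zero-length when the trial has no transient).
// sig_pix:        0-based pixel indices carrying a transient.
// sig_amp:        percent amplitude per entry of sig_pix.
// P:              number of pixels.
// noise_f/r:      noise SD in counts per channel.
// [[Rcpp::export]]
IntegerMatrix assemble_strobed_cpp(NumericVector base_f, NumericVector base_r,
                                   NumericVector kern_counts,
                                   IntegerVector sig_pix, NumericVector sig_amp,
                                   int P, double noise_f, double noise_r) {
  const int n60 = base_f.size();
  if (base_r.size() != n60) stop("channel baselines differ in length");
  const bool has_sig = kern_counts.size() > 0;
  if (has_sig && kern_counts.size() != n60) stop("kernel length mismatch");
  IntegerMatrix out(2 * n60, P);
  std::vector<double> amp_of(P, 0.0);
  for (int k = 0; k < sig_pix.size(); ++k) {
    int p = sig_pix[k];
    if (p < 0 || p >= P) stop("transient pixel index out of range");
    amp_of[p] += sig_amp[k];
  }
  for (int p = 0; p < P; ++p) {
    const double a = has_sig ? amp_of[p] : 0.0;
    int* col = &out(0, p);
    for (int t = 0; t < n60; ++t) {
      double vf = base_f[t] + (a != 0.0 ? a * kern_counts[t] : 0.0);
      double vr = base_r[t];
      if (noise_f > 0) vf += noise_f * norm_rand();
      if (noise_r > 0) vr += noise_r * norm_rand();
      int qf = (int)(vf + 0.5);
      int qr = (int)(vr + 0.5);
      col[2 * t] = qf < 0 ? 0 : (qf > 4095 ? 4095 : qf);
      col[2 * t + 1] = qr < 0 ? 0 : (qr > 4095 ? 4095 : qr);
    }
  }
  return out;
}
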