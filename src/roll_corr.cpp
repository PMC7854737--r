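#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window Pearson correlation with O(1) window updates.
// Running sums are rebuilt from scratch every RESYNC windows so that
// floating-point drift stays bounded on long recordings; correctness of the
// incremental path is guarded by a naive-recomputation test in the suite.
static const int RESYNC = 65536;

// [[Rcpp::export]]
NumericVector roll_corr_cpp(NumericVector a, NumericVector b, int window, int step) {
  const int n = a.size();
  if (b.size() != n) stop("signals must have equal length");
  if (window < 2) stop("window must be at least 2 samples");
  if (window > n) stop("window exceeds signal length");
  if (step < 1) stop("step must be positive");

  const int nout = (n - window) / step + 1;
  NumericVector out(nout);
  int n_degenerate = 0;

  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  bool fresh = true;
  for (int t = 0; t < nout; ++t) {
    const int start = t * step;
    if (fresh || step != 1 || (t % RESYNC) == 0) {
      sa = sb = saa = sbb = sab = 0;
      for (int k = start; k < start + window; ++k) {
        sa += a[k]; sb += b[k];
        saa += a[k] * a[k]; sbb += b[k] * b[k];
        sab += a[k] * b[k];
      }
      fresh = false;
    } else {
      const double ao = a[start - 1], bo = b[start - 1];
      const double an = a[start + window - 1], bn = b[start + window - 1];
      sa += an - ao; sb += bn - bo;
      saa += an * an - ao * ao; sbb += bn * bn - bo * bo;
      sab += an * bn - ao * bo;
    }
    const double va = saa - sa * sa / window;
    const double vb = sbb - sb * sb / window;
    // relative guard: a window is degenerate when its variance is zero up to
    // cancellation error in the sums
    const double ga = 1e-12 * (std::abs(saa) + sa * sa / window);
    const double gb = 1e-12 * (std::abs(sbb) + sb * sb / window);
    if (va <= ga || vb <= gb) {
      out[t] = 0.0;
      ++n_degenerate;
    } else {
      double r = (sab - sa * sb / window) / std::sqrt(va * vb);
      if (r > 1.0) r = 1.0; else if (r < -1.0) r = -1.0;
      out[t] = r;
    }
  }
  out.attr("n_degenerate") = n_degenerate;
  return out;
}
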