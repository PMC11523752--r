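#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR/FIR filter, single forward pass.
// b, a are the numerator/denominator polynomials (a[0] need not be 1).
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  if (na < 1 || a[0] == 0.0) stop("a[1] must be non-zero");
  int ns = std::max(nb, na) - 1;
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  std::vector<double> z(ns, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (ns > 0 ? z[0] : 0.0);
    for (int j = 0; j < ns - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (ns > 0) z[ns - 1] = bb[ns] * xi - aa[ns] * yi;
    y[i] = yi;
  }
  return y;
}

static void iir_pass(const std::vector<double>& bb,
                     const std::vector<double>& aa, int ns,
                     double* x, int n, bool reverse) {
  std::vector<double> z(ns, 0.0);
  int i0 = reverse ? n - 1 : 0, step = reverse ? -1 : 1;
  for (int k = 0, i = i0; k < n; ++k, i += step) {
    double xi = x[i];
    double yi = bb[0] * xi + (ns > 0 ? z[0] : 0.0);
    for (int j = 0; j < ns - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (ns > 0) z[ns - 1] = bb[ns] * xi - aa[ns] * yi;
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering with reflective end padding of
// `npad` samples to suppress edge transients.
// [[Rcpp::export]]
NumericVector zerophase_filter(NumericVector b, NumericVector a,
                               NumericVector x, int npad) {
  int nb = b.size(), na = a.size(), n = x.size();
  if (na < 1 || a[0] == 0.0) stop("a[1] must be non-zero");
  if (npad > n - 1) npad = n - 1;
  if (npad < 0) npad = 0;
  int ns = std::max(nb, na) - 1;
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  int nt = n + 2 * npad;
  std::vector<double> xp(nt);
  for (int i = 0; i < npad; ++i) xp[i] = 2 * x[0] - x[npad - i];
  for (int i = 0; i < n; ++i) xp[npad + i] = x[i];
  for (int i = 0; i < npad; ++i) xp[npad + n + i] = 2 * x[n - 1] - x[n - 2 - i];
  iir_pass(bb, aa, ns, xp.data(), nt, false);
  iir_pass(bb, aa, ns, xp.data(), nt, true);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) y[i] = xp[npad + i];
  return y;
}

// Polyphase upsampling by integer factor L with a symmetric FIR kernel h
// of length 2*K*L + 1 (K taps per side at the input rate), h centred at
// index K*L. Output has length n*L; output sample (i-1)*L + 1 coincides
// with input sample i when h is an interpolating (Nyquist) kernel.
// [[Rcpp::export]]
NumericVector polyphase_upsample(NumericVector x, int L, NumericVector h, int K) {
  int n = x.size();
  if ((int)h.size() != 2 * K * L + 1) stop("kernel length must be 2*K*L + 1");
  NumericVector y(n * L);
  int c = K * L; // centre index of h
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    if (xi == 0.0) continue;
    // contribution of x[i] to outputs at positions i*L + d, |d| <= K*L
    int lo = std::max(-c, -i * L);
    int hi = std::min(c, (n - 1 - i) * L + L - 1);
    double *yp = &y[0] + i * L;
    for (int d = lo; d <= hi; ++d) yp[d] = yp[d] + xi * h[c + d];
  }
  return y;
}
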