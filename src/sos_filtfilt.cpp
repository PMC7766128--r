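#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase (forward-backward) filtering of each column of x through a
// cascade of biquad sections, with odd-reflection padding of npad samples
// at both ends.  Direct form II transposed, zero initial conditions --
// the single hot loop of the package, kept in C++ so the 2 s decoding
// windows and the synthetic-EEG generator stay fast.

static void run_sections(std::vector<double>& v, const NumericMatrix& sos,
                         bool reverse) {
  const int ns = sos.nrow();
  const int n = (int)v.size();
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    if (!reverse) {
      for (int i = 0; i < n; ++i) {
        const double xi = v[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        v[i] = yi;
      }
    } else {
      for (int i = n - 1; i >= 0; --i) {
        const double xi = v[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        v[i] = yi;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix sos_filtfilt_cpp(NumericMatrix x, NumericMatrix sos,
                               int npad) {
  const int n = x.nrow(), m = x.ncol();
  if (n <= npad) stop("input too short for the requested padding");
  NumericMatrix out(n, m);
  std::vector<double> v(n + 2 * npad);
  for (int j = 0; j < m; ++j) {
    // odd reflection about the first and last samples
    const double x0 = x(0, j), xn = x(n - 1, j);
    for (int i = 0; i < npad; ++i) v[i] = 2.0 * x0 - x(npad - i, j);
    for (int i = 0; i < n; ++i) v[npad + i] = x(i, j);
    for (int i = 0; i < npad; ++i)
      v[npad + n + i] = 2.0 * xn - x(n - 2 - i, j);
    run_sections(v, sos, false);   // forward pass
    run_sections(v, sos, true);    // backward pass (time-reversed)
    for (int i = 0; i < n; ++i) out(i, j) = v[npad + i];
  }
  return out;
}
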