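#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter pass over a raw buffer.
// b and a have equal length nf; a[0] == 1 assumed; z is the state
// (length nf - 1) and is updated in place.
static inline void df2t_pass(const double* b, const double* a, int nf,
                             const double* x, double* y, int n,
                             double* z) {
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
}

// Single filter pass with explicit initial state (exported for tests).
// [[Rcpp::export(name = ".df2t_filter")]]
NumericVector df2t_filter(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  const int n = x.size(), nf = b.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  df2t_pass(REAL(b), REAL(a), nf, REAL(x), REAL(y), n, z.data());
  return y;
}

// Odd-symmetric reflection of the middle section of the working buffer
// into its pad regions (buffer is nch x (n + 2 pad), sample-major
// columns: column i holds all channels at sample i).
static void reflect_pads(double* w, int nch, int n, int pad) {
  const double* x = w + (size_t)nch * pad;  // first middle sample
  for (int i = 0; i < pad; ++i) {
    const double* refl = x + (size_t)nch * (pad - i);
    double* dst = w + (size_t)nch * i;
    const double* reflt = x + (size_t)nch * (n - 2 - i);
    double* dstt = w + (size_t)nch * (pad + n + i);
    const double* head = x;
    const double* tail = x + (size_t)nch * (n - 1);
    for (int ch = 0; ch < nch; ++ch) {
      dst[ch] = 2.0 * head[ch] - refl[ch];
      dstt[ch] = 2.0 * tail[ch] - reflt[ch];
    }
  }
}

// One zero-phase (forward-backward) application of a single filter over
// the padded buffer. The recursion runs sample-major across all
// channels at once: per-channel IIR recursions are independent, so
// interleaving them hides the floating-point latency of the serial
// dependency chain; states are stored structure-of-arrays so the
// channel loop vectorises, with the order-4 and biquad cases unrolled.
static void filtfilt_buffer(const double* bp, const double* ap,
                            const double* zp, int nf,
                            double* w, int nch, int m) {
  const int ns = nf - 1;
  std::vector<double> z((size_t)nch * ns);
  for (int dir = 0; dir < 2; ++dir) {
    const bool forward = dir == 0;
    const double* first = w + (size_t)nch * (forward ? 0 : (m - 1));
    for (int j = 0; j < ns; ++j)
      for (int ch = 0; ch < nch; ++ch)
        z[(size_t)j * nch + ch] = zp[j] * first[ch];
    double* z0 = z.data();
    if (ns == 4) {
      double* z1 = z0 + nch; double* z2 = z1 + nch; double* z3 = z2 + nch;
      const double b0 = bp[0], b1 = bp[1], b2 = bp[2], b3 = bp[3],
        b4 = bp[4];
      const double a1 = ap[1], a2 = ap[2], a3 = ap[3], a4 = ap[4];
      for (int s = 0; s < m; ++s) {
        double* col = w + (size_t)nch * (forward ? s : (m - 1 - s));
        for (int ch = 0; ch < nch; ++ch) {
          const double xi = col[ch];
          const double yi = b0 * xi + z0[ch];
          z0[ch] = b1 * xi + z1[ch] - a1 * yi;
          z1[ch] = b2 * xi + z2[ch] - a2 * yi;
          z2[ch] = b3 * xi + z3[ch] - a3 * yi;
          z3[ch] = b4 * xi - a4 * yi;
          col[ch] = yi;
        }
      }
    } else if (ns == 2) {
      double* z1 = z0 + nch;
      const double b0 = bp[0], b1 = bp[1], b2 = bp[2];
      const double a1 = ap[1], a2 = ap[2];
      for (int s = 0; s < m; ++s) {
        double* col = w + (size_t)nch * (forward ? s : (m - 1 - s));
        for (int ch = 0; ch < nch; ++ch) {
          const double xi = col[ch];
          const double yi = b0 * xi + z0[ch];
          z0[ch] = b1 * xi + z1[ch] - a1 * yi;
          z1[ch] = b2 * xi - a2 * yi;
          col[ch] = yi;
        }
      }
    } else {
      for (int s = 0; s < m; ++s) {
        double* col = w + (size_t)nch * (forward ? s : (m - 1 - s));
        for (int ch = 0; ch < nch; ++ch) {
          const double xi = col[ch];
          const double yi = bp[0] * xi + z0[ch];
          for (int j = 0; j < ns - 1; ++j)
            z0[(size_t)j * nch + ch] = bp[j + 1] * xi +
              z0[(size_t)(j + 1) * nch + ch] - ap[j + 1] * yi;
          z0[(size_t)(ns - 1) * nch + ch] = bp[nf - 1] * xi -
            ap[nf - 1] * yi;
          col[ch] = yi;
        }
      }
    }
  }
}

// Apply a sequence of zero-phase filters to the rows of X with a single
// padded working buffer: the signal is reflected into the pads before
// every filter (so each filter sees reflection of the *current*
// signal), filtered forward-backward in place, and copied out once at
// the end. Keeping one buffer for the whole chain bounds peak memory at
// roughly two copies of X regardless of the number of filters.
// bs/as/zis are per-filter coefficient and steady-state-initialisation
// vectors; pad is the largest pad any filter in the chain requires.
// [[Rcpp::export(name = ".filtfilt_chain")]]
NumericMatrix filtfilt_chain(List bs, List as, List zis,
                             NumericMatrix X, int pad) {
  const int nch = X.nrow(), n = X.ncol();
  if (pad >= n) pad = n - 1;
  const int m = n + 2 * pad;
  NumericMatrix W(nch, m);
  double* w = REAL(W);
  std::copy(REAL(X), REAL(X) + (size_t)nch * n, w + (size_t)nch * pad);
  const int nfilt = bs.size();
  for (int f = 0; f < nfilt; ++f) {
    NumericVector b = bs[f], a = as[f], zi = zis[f];
    reflect_pads(w, nch, n, pad);
    filtfilt_buffer(REAL(b), REAL(a), REAL(zi), b.size(), w, nch, m);
  }
  NumericMatrix Y(nch, n);
  std::copy(w + (size_t)nch * pad, w + (size_t)nch * (pad + n), REAL(Y));
  return Y;
}
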