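#include <Rcpp.h>
using namespace Rcpp;

// One IIR section, direct form II transposed, in place over a buffer.
static void df2t(const std::vector<double>& b, const std::vector<double>& a,
                 double* x, const int n) {
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na) - 1;
  std::vector<double> z(ns, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (ns > 0 ? z[0] : 0.0);
    for (int k = 0; k < ns; ++k) {
      const double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      const double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      const double znext = (k + 1 < ns) ? z[k + 1] : 0.0;
      z[k] = bk * xi + znext - ak * yi;
    }
    x[i] = yi;
  }
}

static void reverse_buf(double* x, const int n) {
  for (int i = 0, j = n - 1; i < j; ++i, --j) std::swap(x[i], x[j]);
}

// Zero-phase (forward-backward) application of a cascade of IIR sections to
// every column of X, with odd-symmetric edge reflection of `npad` samples.
// `sections` is a list of list(b=, a=), a[0] == 1 after normalization.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(const NumericMatrix& X, const List& sections,
                           const int npad) {
  const int n = X.nrow(), nc = X.ncol();
  const int p = std::min(npad, n - 1);
  const int m = n + 2 * p;
  NumericMatrix out(n, nc);

  std::vector<std::vector<double> > bs, as;
  for (int s = 0; s < sections.size(); ++s) {
    List sec = sections[s];
    NumericVector bv = sec["b"], av = sec["a"];
    std::vector<double> b(bv.begin(), bv.end());
    std::vector<double> a(av.begin(), av.end());
    const double a0 = a[0];
    for (size_t k = 0; k < b.size(); ++k) b[k] /= a0;
    for (size_t k = 0; k < a.size(); ++k) a[k] /= a0;
    bs.push_back(b);
    as.push_back(a);
  }

  std::vector<double> buf(m);
  for (int c = 0; c < nc; ++c) {
    const double* xc = &X(0, c);
    for (int i = 0; i < p; ++i) buf[i] = 2.0 * xc[0] - xc[p - i];
    for (int i = 0; i < n; ++i) buf[p + i] = xc[i];
    for (int i = 0; i < p; ++i) buf[p + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];
    for (size_t s = 0; s < bs.size(); ++s) {
      df2t(bs[s], as[s], buf.data(), m);
      reverse_buf(buf.data(), m);
      df2t(bs[s], as[s], buf.data(), m);
      reverse_buf(buf.data(), m);
    }
    for (int i = 0; i < n; ++i) out(i, c) = buf[p + i];
  }
  return out;
}
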