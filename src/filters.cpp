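#include <Rcpp.h>
using namespace Rcpp;

// Direct form II transposed IIR filter with initial state. a[0] must be 1;
// zi has length max(len(a), len(b)) - 1 (pass numeric(0) to start at rest).
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nw = std::max(nb, na) - 1;
  int n = x.size();
  NumericVector y(n);
  std::vector<double> w(nw, 0.0);
  if (zi.size() == nw)
    for (int j = 0; j < nw; ++j) w[j] = zi[j];
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nw > 0 ? w[0] : 0.0);
    for (int j = 0; j < nw; ++j) {
      double wj1 = (j + 1 < nw) ? w[j + 1] : 0.0;
      double bj = (j + 1 < nb) ? b[j + 1] : 0.0;
      double aj = (j + 1 < na) ? a[j + 1] : 0.0;
      w[j] = wj1 + bj * xi - aj * yi;
    }
    y[i] = yi;
  }
  return y;
}
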