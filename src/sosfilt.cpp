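#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections, direct form II transposed, with explicit
// state so that chunked (streaming) and whole-record filtering are identical.
// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1.
// zi:  n_sections x 2 state matrix (modified in-place semantics via return).
// [[Rcpp::export]]
List sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  int ns = sos.nrow(), n = x.size();
  if (zi.nrow() != ns || zi.ncol() != 2)
    stop("state matrix must be n_sections x 2");
  NumericVector y(n);
  NumericMatrix zf(clone(zi));
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns);
  for (int s = 0; s < ns; ++s) {
    double a0 = sos(s, 3);
    b0[s] = sos(s, 0) / a0; b1[s] = sos(s, 1) / a0; b2[s] = sos(s, 2) / a0;
    a1[s] = sos(s, 4) / a0; a2[s] = sos(s, 5) / a0;
  }
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    for (int s = 0; s < ns; ++s) {
      double w = b0[s] * v + zf(s, 0);
      zf(s, 0) = b1[s] * v - a1[s] * w + zf(s, 1);
      zf(s, 1) = b2[s] * v - a2[s] * w;
      v = w;
    }
    y[i] = v;
  }
  return List::create(_["y"] = y, _["zf"] = zf);
}

// Greedy refractory scan over a probability series: emit a detection at index i
// (1-based) when p[i] >= threshold and i is at least `refractory` samples after
// the previous detection. Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector refractory_scan_cpp(NumericVector p, double threshold,
                                  int refractory, int start_after) {
  std::vector<int> out;
  int n = p.size();
  int next_ok = start_after; // 0-based index of first eligible sample
  for (int i = next_ok; i < n; ++i) {
    if (p[i] >= threshold) {
      out.push_back(i + 1);
      i += refractory - 1; // loop ++ makes the next eligible i + refractory
    }
  }
  return wrap(out);
}
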