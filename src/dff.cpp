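#include <Rcpp.h>
using namespace Rcpp;

// Percent dF/F in one pass: out(t, p) = (F(t, p) - F0[p]) / F0[p] * 100,
// with pixels whose baseline is at or below eps masked to zero. Accepts the
// integer matrices produced by the acquisition path as well as numeric
// input, avoiding the intermediate copies a plain-R sweep would make.
// [[Rcpp::export]]
NumericMatrix dff_percent_cpp(SEXP values, NumericVector f0, double eps) {
  const bool is_int = TYPEOF(values) == INTSXP;
  if (!is_int && TYPEOF(values) != REALSXP) stop("values must be numeric");
  SEXP dim = Rf_getAttrib(values, R_DimSymbol);
  if (Rf_isNull(dim) || Rf_length(dim) != 2) stop("values must be a matrix");
  const int T = INTEGER(dim)[0], P = INTEGER(dim)[1];
  if (f0.size() != P) stop("f0 length must equal the pixel count");
  NumericMatrix out(T, P);
  const int* iv = is_int ? INTEGER(values) : nullptr;
  const double* dv = is_int ? nullptr : REAL(values);
  for (int p = 0; p < P; ++p) {
    double* o = &out(0, p);
    const double b = f0[p];
    const R_xlen_t off = (R_xlen_t)p * T;
    if (b <= eps) {
      for (int t = 0; t < T; ++t) o[t] = 0.0;
    } else {
      const double s = 100.0 / b;
      if (is_int) {
        for (int t = 0; t < T; ++t) o[t] = ((double)iv[off + t] - b) * s;
      } else {
        for (int t = 0; t < T; ++t) o[t] = (dv[off + t] - b) * s;
      }
    }
  }
  return out;
}
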