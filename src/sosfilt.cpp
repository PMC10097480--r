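#include <Rcpp.h>
using namespace Rcpp;

// Single biquad section, direct-form II transposed.
// b, a: length-3 coefficient vectors with a[0] == 1.
// zi: length-2 initial state (already scaled by the caller).
// [[Rcpp::export]]
NumericVector biquad_filter(NumericVector b, NumericVector a,
                            NumericVector x, NumericVector zi) {
    const R_xlen_t n = x.size();
    NumericVector y(n);
    const double b0 = b[0], b1 = b[1], b2 = b[2];
    const double a1 = a[1], a2 = a[2];
    double z1 = zi[0], z2 = zi[1];
    for (R_xlen_t i = 0; i < n; ++i) {
        const double xi = x[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        y[i] = yi;
    }
    return y;
}
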