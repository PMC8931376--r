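#include <Rcpp.h>
using namespace Rcpp;

// Time derivative of the stacked EMU mass-isotopologue state.
//
// The state x concatenates the MID vectors (length size+1) of every simulated
// EMU. Each production channel deposits flux * (convolution of its source
// MIDs) into its target EMU; sources are either slices of x or fixed boundary
// MIDs. dx = (inflow - outflow * x) / pool, with outflow equal to the summed
// channel fluxes of the target so that each MID stays on the simplex.
//
// [[Rcpp::export]]
NumericVector emu_deriv_cpp(NumericVector x,
                            IntegerVector emu_off,
                            IntegerVector emu_len,
                            NumericVector pool,
                            NumericVector phi,
                            IntegerVector ch_target,
                            NumericVector ch_flux,
                            IntegerVector ch_src_start,
                            IntegerVector ch_src_count,
                            IntegerVector src_kind,
                            IntegerVector src_off,
                            IntegerVector src_len,
                            NumericVector fixed_vals) {
  const int n = x.size();
  const int n_emu = emu_off.size();
  const int n_ch = ch_target.size();
  NumericVector dx(n);   // accumulates inflow, then converted in place

  double buf1[64], buf2[64];

  for (int c = 0; c < n_ch; ++c) {
    const double fl = ch_flux[c];
    if (fl <= 0.0) continue;
    const int s0 = ch_src_start[c];
    const int ns = ch_src_count[c];

    // first source
    int len = src_len[s0];
    const double *src = (src_kind[s0] == 0) ? &x[0] + src_off[s0]
                                            : &fixed_vals[0] + src_off[s0];
    for (int t = 0; t < len; ++t) buf1[t] = src[t];
    double *cur = buf1, *nxt = buf2;

    for (int k = 1; k < ns; ++k) {
      const int sk = s0 + k;
      const int len2 = src_len[sk];
      const double *s2 = (src_kind[sk] == 0) ? &x[0] + src_off[sk]
                                             : &fixed_vals[0] + src_off[sk];
      const int lout = len + len2 - 1;
      for (int t = 0; t < lout; ++t) nxt[t] = 0.0;
      for (int a = 0; a < len; ++a) {
        const double va = cur[a];
        if (va == 0.0) continue;
        for (int b = 0; b < len2; ++b) nxt[a + b] += va * s2[b];
      }
      double *tmp = cur; cur = nxt; nxt = tmp;
      len = lout;
    }

    const int e = ch_target[c];
    const int off = emu_off[e];
    for (int t = 0; t < len; ++t) dx[off + t] += fl * cur[t];
  }

  for (int e = 0; e < n_emu; ++e) {
    const int off = emu_off[e];
    const int len = emu_len[e];
    const double inv_c = 1.0 / pool[e];
    const double ph = phi[e];
    for (int t = 0; t < len; ++t) {
      dx[off + t] = (dx[off + t] - ph * x[off + t]) * inv_c;
    }
  }
  return dx;
}
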