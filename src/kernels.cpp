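// Hot elementwise kernels of the FFT-based masked-NCC engine.  Each runs
// one pass over full-volume spectra; the surrounding logic stays in R.

#include <Rcpp.h>
using namespace Rcpp;

// Split a packed transform Z = F(a) + i F(b) (a, b real) into the two
// Hermitian halves using the precomputed index-reversal permutation
// (1-based linear indices of -k for each k).
// [[Rcpp::export]]
List hermitian_split(ComplexVector Z, IntegerVector flip) {
  R_xlen_t n = Z.size();
  ComplexVector Fa(n), Fb(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    Rcomplex z = Z[i];
    Rcomplex zf = Z[flip[i] - 1];
    Fa[i].r = 0.5 * (z.r + zf.r);
    Fa[i].i = 0.5 * (z.i - zf.i);
    // (Z - conj(Zflip)) / (2i)
    Fb[i].r = 0.5 * (z.i + zf.i);
    Fb[i].i = 0.5 * (zf.r - z.r);
  }
  return List::create(_["a"] = Fa, _["b"] = Fb);
}

// Q1 = Ff * conj(Ft) + i * (Ff * conj(Fm)); Q2 = Ff2 * conj(Fm).
// One inverse FFT of Q1 yields corr(f, t) in its real part and
// corr(f, m) in its imaginary part; Q2 yields corr(f^2, m).
// [[Rcpp::export]]
List spectrum_products(ComplexVector Ff, ComplexVector Ff2,
                       ComplexVector Ft, ComplexVector Fm) {
  R_xlen_t n = Ff.size();
  ComplexVector Q1(n), Q2(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double fr = Ff[i].r, fi = Ff[i].i;
    double tr = Ft[i].r, ti = -Ft[i].i;
    double mr = Fm[i].r, mi = -Fm[i].i;
    double p1r = fr * tr - fi * ti, p1i = fr * ti + fi * tr;
    double p2r = fr * mr - fi * mi, p2i = fr * mi + fi * mr;
    Q1[i].r = p1r - p2i;
    Q1[i].i = p1i + p2r;
    double gr = Ff2[i].r, gi = Ff2[i].i;
    Q2[i].r = gr * mr - gi * mi;
    Q2[i].i = gr * mi + gi * mr;
  }
  return List::create(_["Q1"] = Q1, _["Q2"] = Q2);
}

// ncc = corr_t / (n_mask * local_sd) with a zero-variance guard, clamped
// to [-1, 1].  W packs corr_t (real part) and corr_m (imaginary part);
// C2 holds corr_f2m in its real part.  Both are unnormalized inverse
// DFTs: divide by the volume size `nvox`.
// [[Rcpp::export]]
NumericVector ncc_combine(ComplexVector W, ComplexVector C2,
                          double nvox, double nmask, double eps_sd) {
  R_xlen_t n = W.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double corr_t = W[i].r / nvox;
    double mu = W[i].i / (nvox * nmask);
    double var = C2[i].r / (nvox * nmask) - mu * mu;
    double denom = nmask * std::sqrt(var > 0 ? var : 0);
    double v = denom > nmask * eps_sd ? corr_t / denom : 0.0;
    out[i] = v > 1.0 ? 1.0 : (v < -1.0 ? -1.0 : v);
  }
  return out;
}

// Elementwise max update: best = max(best, x), recording which entries
// changed into `orient` as label `o`.
// [[Rcpp::export]]
void best_update(NumericVector best, IntegerVector orient,
                 NumericVector x, int o) {
  R_xlen_t n = best.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] > best[i]) {
      best[i] = x[i];
      orient[i] = o;
    }
  }
}

// Pack two real vectors into one complex vector (a + i b).
// [[Rcpp::export]]
ComplexVector pack_complex(NumericVector a, NumericVector b) {
  R_xlen_t n = a.size();
  ComplexVector z(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    z[i].r = a[i];
    z[i].i = b[i];
  }
  return z;
}
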