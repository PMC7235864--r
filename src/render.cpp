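#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Finishing pass of the phantom renderer: adds the jaw-arch band, applies
// Poisson mottle (variance proportional to intensity) and additive
// Gaussian noise, and quantises half-up to 8 bits — one pass instead of a
// chain of full-size temporaries. Uses R's RNG (caller set.seed()s).
// [[Rcpp::export(name = ".render_finish_cpp")]]
IntegerMatrix render_finish_cpp(const NumericMatrix& img,
                                const NumericVector& arch,
                                double band_amp, double band_sigma,
                                bool poisson, double noise_sigma) {
  const int h = img.nrow(), w = img.ncol();
  const double inv2s2 = 1.0 / (2.0 * band_sigma * band_sigma);
  const double cutoff = 4.0 * band_sigma;
  IntegerMatrix out(h, w);
  RNGScope scope;
  for (int j = 0; j < w; ++j) {
    const double aj = arch[j];
    for (int i = 0; i < h; ++i) {
      double v = img(i, j);
      const double dr = (i + 1) - aj;
      if (std::fabs(dr) < cutoff)
        v += band_amp * std::exp(-dr * dr * inv2s2);
      if (v < 0.0) v = 0.0;
      if (poisson) v = R::rpois(v);
      if (noise_sigma > 0.0) v += R::rnorm(0.0, noise_sigma);
      int q = (int)std::floor(v + 0.5);
      out(i, j) = q < 0 ? 0 : (q > 255 ? 255 : q);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".blend_cpp")]]
IntegerMatrix blend_cpp(const IntegerMatrix& gx, const IntegerMatrix& gy,
                        double wx, double wy) {
  const int n = gx.size();
  IntegerMatrix out(gx.nrow(), gx.ncol());
  for (int i = 0; i < n; ++i) {
    int ax = gx[i] < 0 ? -gx[i] : gx[i];
    int ay = gy[i] < 0 ? -gy[i] : gy[i];
    if (ax > 255) ax = 255;
    if (ay > 255) ay = 255;
    int v = (int)std::floor(wx * ax + wy * ay + 0.5);
    out[i] = v < 0 ? 0 : (v > 255 ? 255 : v);
  }
  return out;
}
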