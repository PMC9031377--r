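#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;

// Discrete-time Fourier sums between uniform grids.
//
// Both the frequency and time grids used by the sharpening algorithms are
// uniform, so each output sample is evaluated with a complex-rotator
// recurrence: exp(i*w*(k+1)) = exp(i*w*k) * exp(i*w).  One complex multiply
// per input sample replaces a sincos call; the unit-modulus drift after n
// steps is O(n * eps), negligible for the grid sizes used here (< 2^13).

// y[m] = scale * sum_k x[k] * exp(sign * 2i*pi * f[m] * t[k])
// with t[k] = t0 + k*dt (k = 0..n-1) and f[m] = f0 + m*df (m = 0..nout-1).
// [[Rcpp::export]]
ComplexVector cpp_dtft_uniform(const ComplexVector x,
                               const double t0, const double dt,
                               const int n,
                               const double f0, const double df,
                               const int nout,
                               const double sign, const double scale) {
  if (x.size() != n) stop("length(x) must equal n");
  const double twopi = 2.0 * M_PI;
  std::vector< std::complex<double> > xs(n);
  for (int k = 0; k < n; ++k)
    xs[k] = std::complex<double>(x[k].r, x[k].i);

  ComplexVector out(nout);
  for (int m = 0; m < nout; ++m) {
    const double f = f0 + m * df;
    const double wstep = sign * twopi * f * dt;
    const std::complex<double> rot(std::cos(wstep), std::sin(wstep));
    std::complex<double> p(1.0, 0.0);
    std::complex<double> acc(0.0, 0.0);
    for (int k = 0; k < n; ++k) {
      acc += xs[k] * p;
      p *= rot;
    }
    const double w0 = sign * twopi * f * t0;
    acc *= std::complex<double>(std::cos(w0), std::sin(w0)) * scale;
    out[m].r = acc.real();
    out[m].i = acc.imag();
  }
  return out;
}
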