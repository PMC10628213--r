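#include <Rcpp.h>
#include <complex>

using namespace Rcpp;

typedef std::complex<double> cd;

// Specular reflectivity of a layered medium by the Abeles transfer matrix.
//
// sld   : scattering length densities (A^-2) of fronting, slabs..., backing
//         (length n + 2)
// d     : slab thicknesses (A), length n
// sigma : interfacial rms roughnesses (A), length n + 1; sigma[i] belongs to
//         the interface between layer i and layer i+1 (0-based), i.e. to the
//         fronting side of slab i+1; the last entry is the slab/backing
//         interface. Nevot-Croce damping exp(-2 k_i k_{i+1} sigma^2).
//
// q is the momentum transfer measured in the fronting medium. Absorption is
// neglected (real optical profile), so k_z in every layer is purely real
// (propagating) or purely imaginary (evanescent); the kernel exploits this
// to replace complex exp/sqrt with real exp and sincos.
// [[Rcpp::export(name = ".abelesKernel", rng = false)]]
NumericVector abeles_kernel(NumericVector q, NumericVector sld,
                            NumericVector d, NumericVector sigma) {
  const int nq = q.size();
  const int nlay = sld.size();        // n + 2
  const int nint = nlay - 1;          // n + 1 interfaces
  if (d.size() != nlay - 2)
    stop("length(d) must equal length(sld) - 2");
  if (sigma.size() != nint)
    stop("length(sigma) must equal length(sld) - 1");

  NumericVector R(nq);
  std::vector<double> kre(nlay), kim(nlay);

  for (int iq = 0; iq < nq; ++iq) {
    const double kz0 = q[iq] / 2.0;
    const double kz0sq = kz0 * kz0;
    for (int j = 0; j < nlay; ++j) {
      // continuity of the in-plane wavevector; one component is always 0
      const double x = kz0sq - 4.0 * M_PI * (sld[j] - sld[0]);
      if (x >= 0.0) { kre[j] = std::sqrt(x); kim[j] = 0.0; }
      else          { kre[j] = 0.0; kim[j] = std::sqrt(-x); }
    }
    cd M11(1.0, 0.0), M12(0.0, 0.0), M21(0.0, 0.0), M22(1.0, 0.0);
    for (int i = 0; i < nint; ++i) {
      const cd ka(kre[i], kim[i]), kb(kre[i + 1], kim[i + 1]);
      cd r = (ka - kb) / (ka + kb);
      if (sigma[i] > 0.0) {
        // w = -2 ka kb sigma^2; exp(w) with cheap paths for the pure cases
        const double s2 = 2.0 * sigma[i] * sigma[i];
        const double wre = -s2 * (kre[i] * kre[i + 1] - kim[i] * kim[i + 1]);
        const double wim = -s2 * (kre[i] * kim[i + 1] + kim[i] * kre[i + 1]);
        const double ew = std::exp(wre);
        if (wim == 0.0) r *= ew;
        else r *= cd(ew * std::cos(wim), ew * std::sin(wim));
      }
      // characteristic matrix of interface i with the phase of layer i
      // (beta = i k_i d_i, zero for the fronting medium)
      cd ep(1.0, 0.0), em(1.0, 0.0);
      if (i > 0) {
        const double dd = d[i - 1];
        const double att = std::exp(-kim[i] * dd);   // evanescent decay
        const double c = std::cos(kre[i] * dd), s = std::sin(kre[i] * dd);
        ep = cd(att * c, att * s);
        em = cd(c / att, -s / att);
      }
      const cd m11 = ep, m12 = r * ep, m21 = r * em, m22 = em;
      const cd n11 = M11 * m11 + M12 * m21;
      const cd n12 = M11 * m12 + M12 * m22;
      const cd n21 = M21 * m11 + M22 * m21;
      const cd n22 = M21 * m12 + M22 * m22;
      M11 = n11; M12 = n12; M21 = n21; M22 = n22;
    }
    R[iq] = std::norm(M21 / M11);
  }
  return R;
}
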