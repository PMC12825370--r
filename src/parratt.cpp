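#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Parratt recursion for |r|^2 of a slab stack with Nevot-Croce damping.
// d, rho: one entry per slab (possibly empty); sigma: one entry per
// interface, air side first (length = slabs + 1). Absorption neglected.
// [[Rcpp::export]]
NumericVector parratt_recursion_cpp(NumericVector d, NumericVector rho,
                                    NumericVector sigma, double rho_air,
                                    double rho_subphase, NumericVector qz) {
  const double r_e = 2.8179403e-5;            // classical electron radius, A
  const double fourpire = 4.0 * M_PI * r_e;
  const int nsl = rho.size();
  const int n_int = nsl + 1;
  if (sigma.size() != n_int) stop("need one sigma per interface");
  if (d.size() != nsl) stop("d and rho must have equal length");

  std::vector<double> levels(nsl + 2);
  levels[0] = rho_air;
  for (int i = 0; i < nsl; ++i) levels[i + 1] = rho[i];
  levels[nsl + 1] = rho_subphase;

  const int nq = qz.size();
  NumericVector out(nq);
  std::vector< std::complex<double> > k(nsl + 2);

  for (int iq = 0; iq < nq; ++iq) {
    const double kz0sq = qz[iq] * qz[iq] / 4.0;
    for (int j = 0; j < nsl + 2; ++j) {
      const double arg = kz0sq - fourpire * (levels[j] - rho_air);
      k[j] = std::sqrt(std::complex<double>(arg, 0.0));
    }
    std::complex<double> X(0.0, 0.0);
    for (int j = n_int - 1; j >= 0; --j) {   // interface j: media j | j+1
      const std::complex<double> kj = k[j], kj1 = k[j + 1];
      const std::complex<double> rj =
        (kj - kj1) / (kj + kj1) *
        std::exp(-2.0 * kj * kj1 * sigma[j] * sigma[j]);
      std::complex<double> Xp = X;
      if (j <= n_int - 2)                     // medium j+1 is slab j
        Xp = X * std::exp(std::complex<double>(0.0, 2.0) * kj1 * d[j]);
      X = (rj + Xp) / (1.0 + rj * Xp);
    }
    out[iq] = std::norm(X);
  }
  return out;
}
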