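#include <Rcpp.h>
#include <complex>

using namespace Rcpp;
typedef std::complex<double> cd;

// Closed-form exponential of a 2x2 complex matrix via its eigenvalues:
// exp(A) = ((e1 - e2) A + (l1 e2 - l2 e1) I) / (l1 - l2), with a first-order
// fallback when the eigenvalues are (near-)degenerate.
static void expm2(const cd A[4], cd E[4]) {
  cd a = A[0], b = A[1], c = A[2], d = A[3];
  cd tr = a + d;
  cd det = a * d - b * c;
  cd disc = std::sqrt(tr * tr - 4.0 * det);
  cd l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);
  cd dl = l1 - l2;
  if (std::abs(dl) < 1e-12 * (std::abs(l1) + std::abs(l2) + 1.0)) {
    cd l = 0.5 * tr;
    cd el = std::exp(l);
    E[0] = el * (1.0 + (a - l)); E[1] = el * b;
    E[2] = el * c;               E[3] = el * (1.0 + (d - l));
  } else {
    cd f = (std::exp(l1) - std::exp(l2)) / dl;
    cd g = (l1 * std::exp(l2) - l2 * std::exp(l1)) / dl;
    E[0] = f * a + g; E[1] = f * b;
    E[2] = f * c;     E[3] = f * d + g;
  }
}

// Two-site in-phase Bloch-McConnell CPMG propagation.
//
// The transverse magnetization (M_A, M_B) evolves under
//   A = [ -(R2A + kAB)          kBA            ]
//       [    kAB          -(R2B + kBA) + i*dw  ]
// during free precession; ideal 180-degree refocusing pulses act as
// complex conjugation.  One echo unit is (tau - 180 - tau) with
// tau = TCPMG / (2 n) for n echoes, i.e. nuCPMG = n / (2 TCPMG) ... here
// the caller supplies nu and n = 2 * nu * TCPMG echo units are applied.
// Detection is the modulus of the summed transverse amplitude at TCPMG,
// started from the population-weighted equilibrium (pA, pB).
//
// [[Rcpp::export(name = ".cpmg_r2eff_cpp")]]
NumericVector cpmg_r2eff_cpp(double pb, double kex, double dw_rad,
                             double r2a, double r2b,
                             NumericVector nu, double tcpmg) {
  int m = nu.size();
  NumericVector out(m);
  double pa = 1.0 - pb;
  double kab = pb * kex, kba = pa * kex;
  for (int k = 0; k < m; ++k) {
    double ne_real = 2.0 * nu[k] * tcpmg;
    int n = (int)std::lround(ne_real);
    if (n < 1 || std::fabs(ne_real - n) > 1e-6) {
      stop("nu_cpmg = %f Hz does not give an integer echo count in t_cpmg = %f s",
           nu[k], tcpmg);
    }
    double tau = tcpmg / (2.0 * n);
    cd A[4] = { cd(-(r2a + kab), 0.0), cd(kba, 0.0),
                cd(kab, 0.0),          cd(-(r2b + kba), dw_rad) };
    cd At[4] = { A[0] * tau, A[1] * tau, A[2] * tau, A[3] * tau };
    cd P[4];
    expm2(At, P);
    cd v0 = cd(pa, 0.0), v1 = cd(pb, 0.0);
    for (int e = 0; e < n; ++e) {
      cd w0 = P[0] * v0 + P[1] * v1;
      cd w1 = P[2] * v0 + P[3] * v1;
      w0 = std::conj(w0); w1 = std::conj(w1);
      v0 = P[0] * w0 + P[1] * w1;
      v1 = P[2] * w0 + P[3] * w1;
    }
    double amp = std::abs(v0 + v1);
    if (amp <= 0.0) stop("magnetization fully decayed; R2eff undefined");
    out[k] = -std::log(amp) / tcpmg;
  }
  return out;
}
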