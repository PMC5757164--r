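// Discrete prolate spheroidal sequences via the symmetric tridiagonal
// formulation: the DPSS of length N and half-bandwidth W are eigenvectors of
// the tridiagonal matrix with
//   diag[i]    = ((N-1-2i)/2)^2 * cos(2*pi*W),   i = 0..N-1
//   offdiag[i] = i*(N-i)/2,                      i = 1..N-1
// ordered by decreasing eigenvalue. The K largest eigenpairs are computed
// with LAPACK's bisection (dstebz) and inverse iteration with cluster
// reorthogonalisation (dstein); the top eigenvalues become strongly
// clustered relative to ||T|| ~ N^2/4 for long tapers, which these routines
// are designed to handle.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".dpss_tridiag")]]
NumericMatrix dpss_tridiag(int n, double W, int K) {
  if (n < 2 || K < 1 || K > n) stop("invalid DPSS size");
  if (!(W > 0.0 && W < 0.5)) stop("W must lie in (0, 0.5)");
  std::vector<double> d(n), e(n - 1);
  const double c = std::cos(2.0 * M_PI * W);
  for (int i = 0; i < n; ++i) {
    double h = (n - 1.0 - 2.0 * i) / 2.0;
    d[i] = h * h * c;
  }
  for (int i = 1; i < n; ++i)
    e[i - 1] = static_cast<double>(i) * (n - i) / 2.0;  // avoid int overflow

  int il = n - K + 1, iu = n, m = 0, nsplit = 0, info = 0;
  double vl = 0.0, vu = 0.0, abstol = 1e-300;  // tiny -> most accurate
  std::vector<double> w(n), work(4 * n);
  std::vector<int> iblock(n), isplit(n), iwork(3 * n);
  F77_CALL(dstebz)("I", "B", &n, &vl, &vu, &il, &iu, &abstol, d.data(),
                   e.data(), &m, &nsplit, w.data(), iblock.data(),
                   isplit.data(), work.data(), iwork.data(), &info
                   FCONE FCONE);
  if (info != 0 || m != K) stop("tridiagonal eigenvalue computation failed");

  std::vector<double> z(static_cast<size_t>(n) * K);
  std::vector<double> work2(5 * n);
  std::vector<int> iwork2(n), ifail(K);
  F77_CALL(dstein)(&n, d.data(), e.data(), &m, w.data(), iblock.data(),
                   isplit.data(), z.data(), &n, work2.data(), iwork2.data(),
                   ifail.data(), &info);
  if (info != 0) stop("tridiagonal inverse iteration failed");

  // dstein returns columns in ascending eigenvalue order; taper k is the
  // (k+1)-th largest, so reverse. Sign convention: symmetric tapers have a
  // positive mean, antisymmetric tapers a positive leading lobe.
  NumericMatrix tapers(n, K);
  for (int k = 0; k < K; ++k) {
    const double* v = &z[static_cast<size_t>(n) * (K - 1 - k)];
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += v[i];
    bool flip;
    if (std::fabs(s) > 1e-7) {
      flip = (s < 0);
    } else {
      double t = 0.0;
      for (int i = 0; i < n / 2; ++i) t += v[i];
      flip = (t < 0);
    }
    for (int i = 0; i < n; ++i) tapers(i, k) = flip ? -v[i] : v[i];
  }
  return tapers;
}
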