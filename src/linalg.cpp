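// Dense linear-algebra kernels used by the state-space tools.
// Polynomial routes (char-poly + root finding) are numerically unsafe at the
// eigenvalue spreads this model produces (~1e6), so transmission zeros are
// computed from the system pencil with the QZ algorithm and Lyapunov
// equations with the Bartels-Stewart solver, both via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Transmission zeros of a SISO/MIMO state-space model (A, B, C, D):
// generalized eigenvalues of the Rosenbrock pencil
//   [ A  B ]        [ I  0 ]
//   [ C  D ]  - s * [ 0  0 ].
// Infinite eigenvalues (|beta| ~ 0) are dropped by the R wrapper, which
// receives alpha and beta separately.
// [[Rcpp::export]]
List cpp_pencil_zeros(const arma::mat& A, const arma::mat& B,
                      const arma::mat& C, const arma::mat& D) {
  const arma::uword n = A.n_rows, m = B.n_cols, p = C.n_rows;
  arma::mat M(n + p, n + m), N(n + p, n + m, arma::fill::zeros);
  M.submat(0, 0, n - 1, n - 1) = A;
  M.submat(0, n, n - 1, n + m - 1) = B;
  M.submat(n, 0, n + p - 1, n - 1) = C;
  M.submat(n, n, n + p - 1, n + m - 1) = D;
  N.submat(0, 0, n - 1, n - 1).eye();

  arma::cx_mat AA, BB, Q, Z;
  // qz() gives generalized Schur form: alpha_i = AA(i,i), beta_i = BB(i,i)
  bool ok = arma::qz(AA, BB, Q, Z, arma::cx_mat(M, arma::zeros(arma::size(M))),
                     arma::cx_mat(N, arma::zeros(arma::size(N))));
  if (!ok) stop("QZ decomposition failed on the system pencil");
  arma::cx_vec alpha = AA.diag();
  arma::cx_vec beta = BB.diag();
  return List::create(_["alpha"] = alpha, _["beta"] = beta);
}

// Solve the continuous Lyapunov equation A X + X A' + Q = 0 for X.
// [[Rcpp::export]]
arma::mat cpp_lyap(const arma::mat& A, const arma::mat& Q) {
  arma::mat X;
  bool ok = arma::syl(X, A, A.t(), Q);
  if (!ok) stop("Lyapunov solve failed (is the system asymptotically stable?)");
  return X;
}
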