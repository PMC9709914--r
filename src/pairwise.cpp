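// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Minimal least-squares rmsd between two centered n_a x 3 coordinate sets,
// restricted to proper rotations (determinant +1). Uses the singular values
// of the 3x3 correlation matrix; the smallest one changes sign when the
// unconstrained optimum would be a reflection.
static double kabsch_rmsd(const arma::mat& A, const arma::mat& B) {
  arma::mat H = A.t() * B; // 3x3
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U) * arma::det(V);
  arma::mat C = arma::eye(3, 3);
  C(2, 2) = d < 0 ? -1.0 : 1.0;
  arma::mat R = U * C * V.t();
  // evaluate the residual explicitly: the singular-value shortcut
  // (G_A + G_B - 2 * trace) cancels catastrophically near rmsd 0
  arma::mat res = A * R - B;
  return std::sqrt(arma::accu(res % res) / A.n_rows);
}

// coords: N x (3*n_atoms), one frame per row, atom-major (x1,y1,z1,x2,...).
// Returns the symmetric N x N matrix of pairwise fitted rmsds.
// [[Rcpp::export]]
NumericMatrix pairwise_rmsd_fit_cpp(NumericMatrix coords, int n_atoms) {
  const int N = coords.nrow();
  std::vector<arma::mat> C(N);
  for (int i = 0; i < N; ++i) {
    arma::mat M(n_atoms, 3);
    for (int a = 0; a < n_atoms; ++a)
      for (int c = 0; c < 3; ++c) M(a, c) = coords(i, 3 * a + c);
    M.each_row() -= arma::mean(M, 0);
    C[i] = M;
  }
  NumericMatrix out(N, N);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double r = kabsch_rmsd(C[i], C[j]);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}
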