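// Pairwise minimal backbone RMSD after optimal rigid-body superposition
// (Kabsch). Frames are centred once; for each pair the 3x3 cross-covariance
// is decomposed and the RMSD follows from the singular values, with the
// usual determinant sign correction for improper rotations.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// X: natoms x 3 x nframes cube of selected coordinates (Angstrom).
// [[Rcpp::export]]
arma::mat pairwise_rmsd_cpp(const arma::cube& X) {
  const arma::uword n = X.n_slices;
  const arma::uword natoms = X.n_rows;
  std::vector<arma::mat> centred(n);
  arma::vec G(n);
  for (arma::uword f = 0; f < n; ++f) {
    arma::mat M = X.slice(f);
    arma::rowvec c = arma::mean(M, 0);
    M.each_row() -= c;
    centred[f] = M;
    G(f) = arma::accu(M % M);
  }
  arma::mat out(n, n, arma::fill::zeros);
  arma::mat C(3, 3), U, V;
  arma::vec s;
  for (arma::uword i = 0; i + 1 < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      C = centred[i].t() * centred[j];
      if (!arma::svd(U, s, V, C)) {
        Rcpp::stop("SVD failed for frame pair (%d, %d)", (int)i + 1, (int)j + 1);
      }
      double sgn = (arma::det(C) < 0.0) ? -1.0 : 1.0;
      double D = s(0) + s(1) + sgn * s(2);
      double msd = (G(i) + G(j) - 2.0 * D) / (double)natoms;
      if (msd < 0.0) msd = 0.0;  // numerical guard near identity
      double r = std::sqrt(msd);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}
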