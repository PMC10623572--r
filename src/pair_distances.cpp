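// Distance-feature kernels: per-frame distances for all residue pairs with
// a mean-distance filter. Two passes: means first, then values for the
// surviving pairs only, so memory stays proportional to the output.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// A, B: npts x 3 x nframes cubes of point coordinates (e.g. Calpha).
// ia, ib: 0-based pair index vectors into A and B respectively.
// [[Rcpp::export]]
Rcpp::List pair_distance_filter_cpp(const arma::cube& A, const arma::cube& B,
                                    const arma::uvec& ia, const arma::uvec& ib,
                                    double maxMean) {
  const arma::uword np = ia.n_elem;
  const arma::uword nf = A.n_slices;
  std::vector<arma::uword> keep;
  keep.reserve(np / 4 + 1);
  for (arma::uword p = 0; p < np; ++p) {
    double acc = 0.0;
    for (arma::uword f = 0; f < nf; ++f) {
      double dx = A(ia(p), 0, f) - B(ib(p), 0, f);
      double dy = A(ia(p), 1, f) - B(ib(p), 1, f);
      double dz = A(ia(p), 2, f) - B(ib(p), 2, f);
      acc += std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    if (acc / (double)nf <= maxMean) keep.push_back(p);
  }
  arma::mat vals(nf, keep.size());
  for (size_t k = 0; k < keep.size(); ++k) {
    const arma::uword p = keep[k];
    for (arma::uword f = 0; f < nf; ++f) {
      double dx = A(ia(p), 0, f) - B(ib(p), 0, f);
      double dy = A(ia(p), 1, f) - B(ib(p), 1, f);
      double dz = A(ia(p), 2, f) - B(ib(p), 2, f);
      vals(f, k) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  arma::uvec kept(keep);
  return Rcpp::List::create(Rcpp::Named("values") = vals,
                            Rcpp::Named("nKept") = (int)keep.size(),
                            Rcpp::Named("kept") = kept + 1);
}
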