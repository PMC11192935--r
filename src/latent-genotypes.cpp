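#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

// Latent-Gaussian genotype generation, the hot loop of the simulator.
// Draws an n x m standard-normal matrix from a dedicated Mersenne
// Twister stream (seeded explicitly by the caller, so a given seed
// reproduces the same cohort), imposes the LD structure through the
// Cholesky factor L (upper triangular, Z <- Z * L), and cuts each
// column at the Hardy-Weinberg quantiles: below z0 -> 0 copies,
// between -> 1, above z1 -> 2 effect alleles.
// [[Rcpp::export]]
Rcpp::NumericMatrix latent_genotypes_cpp(const int n, const arma::mat& L,
                                         const arma::vec& z0,
                                         const arma::vec& z1,
                                         const unsigned int seed) {
  const arma::uword m = L.n_cols;
  std::mt19937_64 eng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  arma::mat Z(n, m);
  double* z = Z.memptr();
  const arma::uword total = static_cast<arma::uword>(n) * m;
  for (arma::uword k = 0; k < total; ++k) z[k] = gauss(eng);
  Z = Z * L;
  Rcpp::NumericMatrix G(n, m);
  for (arma::uword j = 0; j < m; ++j) {
    const double a = z0(j), b = z1(j);
    double* col = &G(0, j);
    const double* zc = Z.colptr(j);
    for (int i = 0; i < n; ++i) {
      col[i] = (zc[i] > a) + (zc[i] > b);
    }
  }
  return G;
}
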