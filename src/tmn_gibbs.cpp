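#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Draw from N(mean, sd^2) truncated to [0, Inf) by the inverse-CDF method.
// Uses the complementary-CDF formulation in log space, which stays accurate
// when the lower bound sits many standard deviations above the mean (where
// naive accept-reject has near-zero acceptance).
static double rtnorm_lower0(double mean, double sd) {
  double alpha = -mean / sd;                 // standardized lower bound
  double u = unif_rand();
  double logq = R::pnorm(alpha, 0.0, 1.0, /*lower*/ 0, /*log_p*/ 1); // log P(Z>alpha)
  double z = R::qnorm(std::log1p(-u) + logq, 0.0, 1.0, /*lower*/ 0, /*log_p*/ 1);
  if (z < alpha) z = alpha;                  // guard against roundoff
  double x = mean + sd * z;
  return x < 0.0 ? 0.0 : x;
}

// [[Rcpp::export]]
NumericVector rtnorm0_cpp(int n, double mean, double sd) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_lower0(mean, sd);
  return out;
}

// One coordinate update of the truncated matrix-normal Gibbs sweep.
// Precision of vec(V) (column-major) is L %x% (G / sigma2); the conditional
// of V[i,j] given the rest is univariate normal truncated at 0 with
//   var  = sigma2 / (G[i,i] * L[j,j])
//   mean = M[i,j] + D[i,j] - (G D L)[i,j] / (G[i,i] * L[j,j])
// where D = V - M. Maintaining R2 = D * L makes (G D L)[i,j] an O(c) dot
// product and the post-update refresh of R2 an O(p) row operation.
static inline void update_coord(int i, int j, int c, int p,
                                double* V, double* D, double* R2,
                                const double* M, const double* G,
                                const double* L, double sigma2) {
  double gii = G[i + (size_t)i * c];
  double ljj = L[j + (size_t)j * p];
  double cross = 0.0;
  const double* r2col = R2 + (size_t)j * c;
  const double* gcol = G + (size_t)i * c;   // G symmetric: row i == col i
  for (int k = 0; k < c; ++k) cross += gcol[k] * r2col[k];
  double denom = gii * ljj;
  double mu = M[i + (size_t)j * c] + D[i + (size_t)j * c] - cross / denom;
  double sd = std::sqrt(sigma2 / denom);
  if (!R_finite(mu) || !R_finite(sd))
    stop("non-finite conditional parameters in the TMN Gibbs sweep");
  double xnew = rtnorm_lower0(mu, sd);
  double delta = xnew - V[i + (size_t)j * c];
  if (delta != 0.0) {
    V[i + (size_t)j * c] = xnew;
    D[i + (size_t)j * c] += delta;
    const double* lrow = L + (size_t)j;     // row j of L, stride p (symmetric)
    double* r2row = R2 + (size_t)i;
    for (int l = 0; l < p; ++l) r2row[(size_t)l * c] += delta * lrow[(size_t)l * p];
  }
}

static void run_sweeps(int sweeps, bool random_scan, int c, int p,
                       double* V, double* D, double* R2,
                       const double* M, const double* G, const double* L,
                       double sigma2, std::vector<int>& idx) {
  int n = c * p;
  for (int s = 0; s < sweeps; ++s) {
    if (random_scan) {
      for (int k = n - 1; k > 0; --k) {
        int r = (int)std::floor(unif_rand() * (k + 1));
        if (r > k) r = k;
        std::swap(idx[k], idx[r]);
      }
    }
    for (int k = 0; k < n; ++k) {
      int q = idx[k];
      update_coord(q % c, q / c, c, p, V, D, R2, M, G, L, sigma2);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix tmn_gibbs_sweeps_cpp(NumericMatrix V0, NumericMatrix M,
                                   NumericMatrix G, NumericMatrix L,
                                   double sigma2, int sweeps,
                                   bool random_scan) {
  int c = V0.nrow(), p = V0.ncol();
  NumericMatrix V = clone(V0);
  NumericMatrix D(c, p), R2(c, p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < c; ++i) D(i, j) = V(i, j) - M(i, j);
  // R2 = D * L
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < c; ++i) {
      double acc = 0.0;
      for (int l = 0; l < p; ++l) acc += D(i, l) * L(l, j);
      R2(i, j) = acc;
    }
  // fixed scan order is row-major over (i, j); idx holds column-major codes
  std::vector<int> idx(c * p);
  for (int k = 0; k < c * p; ++k) idx[k] = (k / p) + (k % p) * c;
  run_sweeps(sweeps, random_scan, c, p, REAL(V), REAL(D), REAL(R2),
             REAL(M), REAL(G), REAL(L), sigma2, idx);
  return V;
}

// Long chain helper for diagnostics/tests: returns cp x n_draws matrix of
// vectorized states, taking `thin` sweeps between stored draws.
// [[Rcpp::export]]
NumericMatrix tmn_gibbs_chain_cpp(NumericMatrix V0, NumericMatrix M,
                                  NumericMatrix G, NumericMatrix L,
                                  double sigma2, int n_draws, int thin) {
  int c = V0.nrow(), p = V0.ncol();
  NumericMatrix V = clone(V0);
  NumericMatrix D(c, p), R2(c, p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < c; ++i) D(i, j) = V(i, j) - M(i, j);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < c; ++i) {
      double acc = 0.0;
      for (int l = 0; l < p; ++l) acc += D(i, l) * L(l, j);
      R2(i, j) = acc;
    }
  std::vector<int> idx(c * p);
  for (int k = 0; k < c * p; ++k) idx[k] = (k / p) + (k % p) * c;
  NumericMatrix out(c * p, n_draws);
  for (int d = 0; d < n_draws; ++d) {
    run_sweeps(thin, false, c, p, REAL(V), REAL(D), REAL(R2),
               REAL(M), REAL(G), REAL(L), sigma2, idx);
    for (int k = 0; k < c * p; ++k) out(k, d) = V[k];
  }
  return out;
}
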