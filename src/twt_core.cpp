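// Batch kernels for the Three-Way Test: parametric-bootstrap sampling of
// truncated quadratic forms and the per-replication Wald-Z + test
// evaluation used by the simulation engine. All randomness comes from
// R's RNG so set.seed() governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double P_EPS_DEFAULT = 1e-14;

// indices of z ordered by decreasing |z|, ties by ascending index
static arma::uvec order_desc_abs(const arma::vec& z) {
  arma::uvec idx = arma::regspace<arma::uvec>(0, z.n_elem - 1);
  std::stable_sort(idx.begin(), idx.end(),
                   [&z](arma::uword a, arma::uword b) {
                     return std::abs(z[a]) > std::abs(z[b]);
                   });
  return idx;
}

// truncated quadratic forms for nested kept-counts ks (ascending),
// via one Cholesky of the permuted covariance: the factor of each
// leading principal block is the leading block of the full factor.
static arma::vec trunc_stats_nested(const arma::vec& z,
                                    const arma::mat& kron,
                                    const arma::uvec& ks) {
  arma::uvec ord = order_desc_abs(z);
  arma::mat P = kron.submat(ord, ord);
  arma::mat U;
  if (!arma::chol(U, P))
    stop("permuted Kronecker correlation is not positive definite");
  arma::vec w = arma::solve(arma::trimatl(U.t()), z.elem(ord));
  arma::vec cums = arma::cumsum(arma::square(w));
  arma::vec out(ks.n_elem);
  for (arma::uword i = 0; i < ks.n_elem; ++i) out[i] = cums[ks[i] - 1];
  return out;
}

// cap for tan-transform inputs: p-values at 1 contribute a bounded
// negative term instead of -Inf (matches .clipTan on the R side)
static const double TAN_CAP = 1.0 - 1e-6;

static inline double clip_tan(double p, double eps) {
  if (p < eps) return eps;
  if (p > TAN_CAP) return TAN_CAP;
  return p;
}

// Cauchy combination with uniform weights
static double cct(const arma::vec& p, double eps) {
  double s = 0.0;
  for (arma::uword i = 0; i < p.n_elem; ++i)
    s += std::tan((0.5 - clip_tan(p[i], eps)) * M_PI);
  s /= p.n_elem;
  double out = 0.5 - std::atan(s) / M_PI;
  if (out < eps) out = eps;
  if (out > 1.0) out = 1.0;
  return out;
}

static inline double genchi2_surv(double x, double a, double b, double d) {
  double q = (x - b) / a;
  if (q <= 0.0) return 1.0;
  return R::pchisq(q, d, 0, 0);
}

// draws vec(Z) ~ N(0, kron(theta, rho)) as Z = Lrho * E * Lrho' shapes:
// Z (q x m) = cholRho.t() * E * cholTheta with E iid standard normal.
static arma::mat draw_null_z(arma::uword q, arma::uword m,
                             const arma::mat& cholThetaU,
                             const arma::mat& cholRhoU) {
  arma::mat E(q, m);
  for (arma::uword j = 0; j < m; ++j)
    for (arma::uword i = 0; i < q; ++i) E(i, j) = ::norm_rand();
  return cholRhoU.t() * E * cholThetaU;
}

// [[Rcpp::export]]
arma::mat cpp_null_trunc_samples(const arma::mat& cholThetaU,
                                 const arma::mat& cholRhoU,
                                 const arma::mat& kron,
                                 const arma::uvec& ks, int B) {
  const arma::uword m = cholThetaU.n_cols, q = cholRhoU.n_cols;
  arma::mat out(B, ks.n_elem);
  for (int b = 0; b < B; ++b) {
    arma::mat Z = draw_null_z(q, m, cholThetaU, cholRhoU);
    out.row(b) = trunc_stats_nested(arma::vectorise(Z), kron, ks).t();
    if (b % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_trunc_stats(const arma::vec& z, const arma::mat& kron,
                          const arma::uvec& ks) {
  return trunc_stats_nested(z, kron, ks);
}

// One replication of the individual-data pipeline: phenotypes from the
// linear model (fixed mean part Ymean, correlated errors), Wald Z for
// every trait x SNP regression adjusted on the fixed covariate basis Qc
// (orthonormal, includes intercept), using the residualization identity
// t_k = (g~' y~) / sqrt(gnorm2 * RSS / df).
static arma::mat one_rep_waldz(const arma::mat& Ymean,
                               const arma::mat& cholRhoGenU,
                               const arma::mat& Qc, const arma::mat& Gres,
                               const arma::vec& gnorm2, double df) {
  const arma::uword n = Ymean.n_rows, q = Ymean.n_cols,
    m = Gres.n_cols;
  arma::mat E(n, q);
  for (arma::uword j = 0; j < q; ++j)
    for (arma::uword i = 0; i < n; ++i) E(i, j) = ::norm_rand();
  arma::mat Y = Ymean + E * cholRhoGenU;
  arma::mat Yres = Y - Qc * (Qc.t() * Y);
  arma::mat cross = Gres.t() * Yres;              // m x q
  arma::rowvec ynorm2 = arma::sum(arma::square(Yres), 0);
  arma::mat Z(q, m);
  for (arma::uword k = 0; k < m; ++k) {
    for (arma::uword j = 0; j < q; ++j) {
      double c = cross(k, j);
      double rss = ynorm2[j] - c * c / gnorm2[k];
      Z(j, k) = c / std::sqrt(gnorm2[k] * rss / df);
    }
  }
  return Z;
}

// quadratic-form p-values for all columns of X against corr with upper
// Cholesky factor U (stat = ||U^-T x||^2), chi-square df = nrow(X)
static arma::vec quad_pvals(const arma::mat& X, const arma::mat& U) {
  arma::mat W = arma::solve(arma::trimatl(U.t()), X);
  arma::rowvec stats = arma::sum(arma::square(W), 0);
  arma::vec p(X.n_cols);
  for (arma::uword i = 0; i < X.n_cols; ++i)
    p[i] = R::pchisq(stats[i], (double)X.n_rows, 0, 0);
  return p;
}

// [[Rcpp::export]]
arma::mat cpp_simulate_pvalues(const arma::mat& Ymean,
                               const arma::mat& cholRhoGenU,
                               const arma::mat& Qc,
                               const arma::mat& Gres,
                               const arma::vec& gnorm2,
                               const arma::mat& cholThetaHatU,
                               const arma::mat& cholRhoHatU,
                               const arma::mat& kronHat,
                               const arma::uvec& ks,
                               const arma::vec& ga, const arma::vec& gb,
                               const arma::vec& gd,
                               int nrep, double pfloor) {
  const arma::uword q = Ymean.n_cols, m = Gres.n_cols;
  const arma::uword M = q * m, nEta = ks.n_elem;
  if (ks[nEta - 1] != M)
    stop("last truncation size must be M (eta = 1)");
  if (ga.n_elem != nEta - 1)
    stop("need generalized chi-square parameters for every eta < 1");
  const double df = (double)Ymean.n_rows - (double)Qc.n_cols - 1.0;
  arma::mat out(nrep, 4);
  for (int r = 0; r < nrep; ++r) {
    arma::mat Z = one_rep_waldz(Ymean, cholRhoGenU, Qc, Gres, gnorm2, df);
    arma::vec pj = quad_pvals(Z.t(), cholThetaHatU);  // rows vs theta
    arma::vec pk = quad_pvals(Z, cholRhoHatU);        // cols vs rho
    double P1 = cct(pj, pfloor);
    double P2 = cct(pk, pfloor);
    arma::vec tstats = trunc_stats_nested(arma::vectorise(Z), kronHat, ks);
    arma::vec peta(nEta);
    for (arma::uword i = 0; i + 1 < nEta; ++i)
      peta[i] = genchi2_surv(tstats[i], ga[i], gb[i], gd[i]);
    peta[nEta - 1] = R::pchisq(tstats[nEta - 1], (double)M, 0, 0);
    double P3 = cct(peta, pfloor);
    arma::vec comps = {P1, P2, P3};
    out(r, 0) = P1;
    out(r, 1) = P2;
    out(r, 2) = P3;
    out(r, 3) = cct(comps, pfloor);
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_simulate_zdraws(const arma::mat& Ymean,
                              const arma::mat& cholRhoGenU,
                              const arma::mat& Qc,
                              const arma::mat& Gres,
                              const arma::vec& gnorm2,
                              int nrep) {
  const arma::uword q = Ymean.n_cols, m = Gres.n_cols;
  const double df = (double)Ymean.n_rows - (double)Qc.n_cols - 1.0;
  arma::mat out(q * m, nrep);
  for (int r = 0; r < nrep; ++r) {
    arma::mat Z = one_rep_waldz(Ymean, cholRhoGenU, Qc, Gres, gnorm2, df);
    out.col(r) = arma::vectorise(Z);
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Component p-values on externally supplied null Z draws with known
// covariance factors (used for probability-integral-transform checks):
// returns per draw (p1..pq row p-values | p[1..m] col p-values |
// p~eta for all eta | P1 P2 P3 TWT).
// [[Rcpp::export]]
arma::mat cpp_twt_pvalues_batch(const arma::mat& zdraws, int q, int m,
                                const arma::mat& cholThetaU,
                                const arma::mat& cholRhoU,
                                const arma::mat& kron,
                                const arma::uvec& ks,
                                const arma::vec& ga, const arma::vec& gb,
                                const arma::vec& gd, double pfloor) {
  const arma::uword M = (arma::uword)q * (arma::uword)m;
  const arma::uword nEta = ks.n_elem;
  if (zdraws.n_rows != M) stop("zdraws must have q*m rows");
  arma::mat out(zdraws.n_cols, q + m + nEta + 4);
  for (arma::uword r = 0; r < zdraws.n_cols; ++r) {
    arma::mat Z = arma::reshape(zdraws.col(r), q, m);
    arma::vec pj = quad_pvals(Z.t(), cholThetaU);
    arma::vec pk = quad_pvals(Z, cholRhoU);
    arma::vec tstats = trunc_stats_nested(zdraws.col(r), kron, ks);
    arma::vec peta(nEta);
    for (arma::uword i = 0; i + 1 < nEta; ++i)
      peta[i] = genchi2_surv(tstats[i], ga[i], gb[i], gd[i]);
    peta[nEta - 1] = R::pchisq(tstats[nEta - 1], (double)M, 0, 0);
    double P1 = cct(pj, pfloor), P2 = cct(pk, pfloor),
      P3 = cct(peta, pfloor);
    arma::vec comps = {P1, P2, P3};
    arma::uword off = 0;
    for (int j = 0; j < q; ++j) out(r, off++) = pj[j];
    for (int k = 0; k < m; ++k) out(r, off++) = pk[k];
    for (arma::uword i = 0; i < nEta; ++i) out(r, off++) = peta[i];
    out(r, off++) = P1;
    out(r, off++) = P2;
    out(r, off++) = P3;
    out(r, off) = cct(comps, pfloor);
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
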