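// Compiled FIML kernels for the two-group twin models.
//
// Pattern statistics (n, idx, ybar, S) are prepared in R (R/fiml.R); each
// kernel rebuilds the model-implied moments from the unconstrained parameter
// vector and accumulates n * (p log 2pi + log|Sigma_o| + tr(Sigma_o^{-1} M))
// per pattern, M = S + (ybar - mu_o)(ybar - mu_o)'.  Non-PD implied
// covariances return NA and are treated as infinite by the R optimizer.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static double stats_neg2ll(const List& stats, const arma::vec& mu,
                           const arma::mat& Sigma, bool& ok) {
  double val = 0.0;
  for (int i = 0; i < stats.size(); ++i) {
    List p = stats[i];
    double n = as<double>(p["n"]);
    arma::uvec idx = as<arma::uvec>(p["idx"]) - 1;
    arma::vec ybar = as<arma::vec>(p["ybar"]);
    arma::mat S = as<arma::mat>(p["S"]);
    arma::mat So = Sigma.submat(idx, idx);
    So = 0.5 * (So + So.t());          // guard fp asymmetry
    if (!So.is_finite()) { ok = false; return NA_REAL; }
    arma::mat R;
    if (!arma::chol(R, So)) { ok = false; return NA_REAL; }
    double logdet = 2.0 * arma::accu(arma::log(R.diag()));
    arma::vec d = ybar - mu.elem(idx);
    arma::mat M = S + d * d.t();
    arma::mat Rinv = arma::inv(arma::trimatu(R));
    arma::mat Sinv = Rinv * Rinv.t();
    double tr = arma::accu(Sinv % M);
    val += n * (idx.n_elem * std::log(2.0 * M_PI) + logdet + tr);
  }
  return val;
}

// 2x2 covariance from (log v1, log v2, atanh r)
static arma::mat cov2(double l1, double l2, double z) {
  double v1 = std::exp(l1), v2 = std::exp(l2);
  double c = std::tanh(z) * std::sqrt(v1 * v2);
  arma::mat m(2, 2);
  m(0, 0) = v1; m(1, 1) = v2; m(0, 1) = c; m(1, 0) = c;
  return m;
}

// lag covariance (6x6, wave-major blocks) of one within-person stream
static arma::mat lag_cov(const arma::mat& V1, const arma::mat& B1,
                         const arma::mat& B2, const arma::mat& U2,
                         const arma::mat& U3) {
  arma::mat V2 = B1 * V1 * B1.t() + U2;
  arma::mat V3 = B2 * V2 * B2.t() + U3;
  arma::mat C21 = B1 * V1;          // Cov(w2, w1)
  arma::mat C31 = B2 * C21;         // Cov(w3, w1)
  arma::mat C32 = B2 * V2;          // Cov(w3, w2)
  arma::mat W(6, 6);
  W.submat(0, 0, 1, 1) = V1;
  W.submat(2, 2, 3, 3) = V2;
  W.submat(4, 4, 5, 5) = V3;
  W.submat(2, 0, 3, 1) = C21; W.submat(0, 2, 1, 3) = C21.t();
  W.submat(4, 0, 5, 1) = C31; W.submat(0, 4, 1, 5) = C31.t();
  W.submat(4, 2, 5, 3) = C32; W.submat(2, 4, 3, 5) = C32.t();
  return W;
}

// theta layout (0-based): 0-2 VA_ri, 3-5 VE_ri, 6-9 B1 (row-major),
// 10-13 B2, 14-16 SA_w1, 17-19 SE_w1, 20-22 SA_u2, 23-25 SE_u2,
// 26-28 SA_u3, 29-31 SE_u3, 32-37 mu (wave-major, trait-minor)
static void riclpm_build(const arma::vec& th, arma::mat& Sigma_mz,
                         arma::mat& Sigma_dz, arma::vec& mu12) {
  arma::mat VA = cov2(th(0), th(1), th(2));
  arma::mat VE = cov2(th(3), th(4), th(5));
  arma::mat B1(2, 2), B2(2, 2);
  B1(0, 0) = th(6);  B1(0, 1) = th(7);  B1(1, 0) = th(8);  B1(1, 1) = th(9);
  B2(0, 0) = th(10); B2(0, 1) = th(11); B2(1, 0) = th(12); B2(1, 1) = th(13);
  arma::mat WA = lag_cov(cov2(th(14), th(15), th(16)), B1, B2,
                         cov2(th(20), th(21), th(22)),
                         cov2(th(26), th(27), th(28)));
  arma::mat WE = lag_cov(cov2(th(17), th(18), th(19)), B1, B2,
                         cov2(th(23), th(24), th(25)),
                         cov2(th(29), th(30), th(31)));
  arma::mat ones33 = arma::ones<arma::mat>(3, 3);
  arma::mat KA = arma::kron(ones33, VA);
  arma::mat KE = arma::kron(ones33, VE);
  arma::mat Sw = KA + KE + WA + WE;
  arma::mat TA = KA + WA;           // cross-twin building block (A only)
  Sigma_mz.set_size(12, 12);
  Sigma_dz.set_size(12, 12);
  Sigma_mz.submat(0, 0, 5, 5) = Sw;  Sigma_mz.submat(6, 6, 11, 11) = Sw;
  Sigma_mz.submat(0, 6, 5, 11) = TA; Sigma_mz.submat(6, 0, 11, 5) = TA.t();
  Sigma_dz.submat(0, 0, 5, 5) = Sw;  Sigma_dz.submat(6, 6, 11, 11) = Sw;
  Sigma_dz.submat(0, 6, 5, 11) = 0.5 * TA;
  Sigma_dz.submat(6, 0, 11, 5) = 0.5 * TA.t();
  mu12.set_size(12);
  for (int j = 0; j < 6; ++j) { mu12(j) = th(32 + j); mu12(6 + j) = th(32 + j); }
}

// [[Rcpp::export]]
List riclpm_moments_cpp(const arma::vec& theta) {
  arma::mat Smz, Sdz; arma::vec mu;
  riclpm_build(theta, Smz, Sdz, mu);
  return List::create(_["Sigma_mz"] = Smz, _["Sigma_dz"] = Sdz, _["mu"] = mu);
}

// [[Rcpp::export]]
double riclpm_neg2ll_cpp(const arma::vec& theta, const List& stats_mz,
                         const List& stats_dz) {
  arma::mat Smz, Sdz; arma::vec mu;
  riclpm_build(theta, Smz, Sdz, mu);
  bool ok = true;
  double v1 = stats_neg2ll(stats_mz, mu, Smz, ok);
  if (!ok) return NA_REAL;
  double v2 = stats_neg2ll(stats_dz, mu, Sdz, ok);
  if (!ok) return NA_REAL;
  return v1 + v2;
}

// fill an m x m lower-triangular matrix from column-major packed entries
static arma::mat unpack_lt(const arma::vec& th, int offset, int m) {
  arma::mat L(m, m, arma::fill::zeros);
  int k = offset;
  for (int j = 0; j < m; ++j)
    for (int i = j; i < m; ++i) L(i, j) = th(k++);
  return L;
}

// theta layout: a (m(m+1)/2, column-major), [c if ace], e, means male (m),
// means female (m).  groups: list of list(r, s1, s2, stats=list of patterns)
// [[Rcpp::export]]
double cholesky_neg2ll_cpp(const arma::vec& theta, int m, bool ace,
                           const List& groups) {
  int nlt = m * (m + 1) / 2;
  arma::mat a = unpack_lt(theta, 0, m);
  arma::mat c = ace ? unpack_lt(theta, nlt, m)
                    : arma::mat(m, m, arma::fill::zeros);
  arma::mat e = unpack_lt(theta, ace ? 2 * nlt : nlt, m);
  int moff = (ace ? 3 : 2) * nlt;
  arma::vec mean_m = theta.subvec(moff, moff + m - 1);
  arma::vec mean_f = theta.subvec(moff + m, moff + 2 * m - 1);
  arma::mat A = a * a.t(), C = c * c.t(), E = e * e.t();
  arma::mat within = A + C + E;
  double val = 0.0;
  for (int g = 0; g < groups.size(); ++g) {
    List grp = groups[g];
    double r = as<double>(grp["r"]);
    int s1 = as<int>(grp["s1"]), s2 = as<int>(grp["s2"]);
    arma::mat cross = r * A + C;
    arma::mat Sigma(2 * m, 2 * m);
    Sigma.submat(0, 0, m - 1, m - 1) = within;
    Sigma.submat(m, m, 2 * m - 1, 2 * m - 1) = within;
    Sigma.submat(0, m, m - 1, 2 * m - 1) = cross;
    Sigma.submat(m, 0, 2 * m - 1, m - 1) = cross.t();
    arma::vec mu(2 * m);
    mu.subvec(0, m - 1) = s1 == 0 ? mean_m : mean_f;
    mu.subvec(m, 2 * m - 1) = s2 == 0 ? mean_m : mean_f;
    bool ok = true;
    double v = stats_neg2ll(as<List>(grp["stats"]), mu, Sigma, ok);
    if (!ok) return NA_REAL;
    val += v;
  }
  return val;
}
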