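// Core numerics for the pleiotropy vs. separate-QTL test.
//
// All routines work in the eigenbasis of the kinship matrix K = U D U'.
// After rotating phenotypes and designs by U', the 2n x 2n covariance
// Vg (x) K + Ve (x) I becomes block diagonal with per-subject 2x2 blocks
// S_i = d_i * Vg + Ve, so every likelihood evaluation is O(n) instead of
// O(n^3).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LN10 = 2.302585092994045684;

namespace {

struct Weights {
  vec w11, w12, w22;  // entries of S_i^{-1}
  double logdet;      // sum_i log|S_i|
};

Weights make_weights(const vec& d, const mat& Vg, const mat& Ve) {
  const uword n = d.n_elem;
  Weights W;
  W.w11.set_size(n);
  W.w12.set_size(n);
  W.w22.set_size(n);
  double ld = 0.0;
  for (uword i = 0; i < n; ++i) {
    const double s11 = d(i) * Vg(0, 0) + Ve(0, 0);
    const double s12 = d(i) * Vg(0, 1) + Ve(0, 1);
    const double s22 = d(i) * Vg(1, 1) + Ve(1, 1);
    const double det = s11 * s22 - s12 * s12;
    if (!(det > 0.0) || !(s11 > 0.0)) {
      Rcpp::stop("per-subject covariance block is not positive definite (subject %d)",
                 (int)(i + 1));
    }
    ld += std::log(det);
    W.w11(i) = s22 / det;
    W.w12(i) = -s12 / det;
    W.w22(i) = s11 / det;
  }
  W.logdet = ld;
  return W;
}

// clamp eigenvalues of a symmetric 2x2 at `floor` to preserve PSD
mat psd_floor(const mat& V, double floor_ev) {
  vec ev;
  mat Q;
  eig_sym(ev, Q, symmatu(V));
  ev = clamp(ev, floor_ev, datum::inf);
  return Q * diagmat(ev) * Q.t();
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
Rcpp::List cpp_gls_pair(const arma::mat& X1, const arma::mat& X2,
                        const arma::mat& Yr, const arma::vec& d,
                        const arma::mat& Vg, const arma::mat& Ve) {
  const uword n = Yr.n_rows;
  const uword p1 = X1.n_cols, p2 = X2.n_cols;
  Weights W = make_weights(d, Vg, Ve);
  const vec y1 = Yr.col(0), y2 = Yr.col(1);
  const vec u1 = W.w11 % y1 + W.w12 % y2;
  const vec u2 = W.w12 % y1 + W.w22 % y2;

  mat C(p1 + p2, p1 + p2);
  C.submat(0, 0, p1 - 1, p1 - 1) = X1.t() * (X1.each_col() % W.w11);
  C.submat(0, p1, p1 - 1, p1 + p2 - 1) = X1.t() * (X2.each_col() % W.w12);
  C.submat(p1, 0, p1 + p2 - 1, p1 - 1) =
      C.submat(0, p1, p1 - 1, p1 + p2 - 1).t();
  C.submat(p1, p1, p1 + p2 - 1, p1 + p2 - 1) =
      X2.t() * (X2.each_col() % W.w22);
  vec rhs(p1 + p2);
  rhs.subvec(0, p1 - 1) = X1.t() * u1;
  rhs.subvec(p1, p1 + p2 - 1) = X2.t() * u2;

  vec beta;
  const bool ok = solve(beta, C, rhs,
                        solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) Rcpp::stop("design matrix is rank-deficient under the GLS inner product");

  const double yWy = dot(y1, u1) + dot(y2, u2);
  const double quad = yWy - dot(rhs, beta);
  const double ll =
      -0.5 * (2.0 * n * std::log(2.0 * datum::pi) + W.logdet + quad);

  return Rcpp::List::create(Rcpp::Named("beta1") = beta.subvec(0, p1 - 1),
                            Rcpp::Named("beta2") = beta.subvec(p1, p1 + p2 - 1),
                            Rcpp::Named("loglik10") = ll / LN10);
}

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_scan_grid(const arma::cube& Pr, const arma::mat& Cov,
                        const arma::mat& Yr, const arma::vec& d,
                        const arma::mat& Vg, const arma::mat& Ve) {
  const uword n = Pr.n_rows, k = Pr.n_cols, m = Pr.n_slices;
  const uword c = Cov.n_cols;
  const uword p = k + c, q = m * k + c;

  Weights W = make_weights(d, Vg, Ve);
  const vec y1 = Yr.col(0), y2 = Yr.col(1);
  const vec u1 = W.w11 % y1 + W.w12 % y2;
  const vec u2 = W.w12 % y1 + W.w22 % y2;

  // all candidate columns at once: one weighted crossproduct per weight
  mat Xall(n, q);
  for (uword j = 0; j < m; ++j) Xall.cols(j * k, j * k + k - 1) = Pr.slice(j);
  if (c > 0) Xall.cols(m * k, q - 1) = Cov;
  const mat G11 = Xall.t() * (Xall.each_col() % W.w11);
  const mat G12 = Xall.t() * (Xall.each_col() % W.w12);
  const mat G22 = Xall.t() * (Xall.each_col() % W.w22);
  const vec R1 = Xall.t() * u1;
  const vec R2 = Xall.t() * u2;
  const double yWy = dot(y1, u1) + dot(y2, u2);
  const double cst = 2.0 * n * std::log(2.0 * datum::pi) + W.logdet;

  uvec covidx;
  if (c > 0) covidx = regspace<uvec>(m * k, q - 1);

  mat out(m, m);
  mat C(2 * p, 2 * p);
  vec rhs(2 * p), beta;
  for (uword i = 0; i < m; ++i) {
    const uvec I1 = (c > 0)
                        ? join_cols(regspace<uvec>(i * k, i * k + k - 1), covidx)
                        : regspace<uvec>(i * k, i * k + k - 1);
    for (uword j = 0; j < m; ++j) {
      const uvec I2 =
          (c > 0) ? join_cols(regspace<uvec>(j * k, j * k + k - 1), covidx)
                  : regspace<uvec>(j * k, j * k + k - 1);
      C.submat(0, 0, p - 1, p - 1) = G11(I1, I1);
      C.submat(0, p, p - 1, 2 * p - 1) = G12(I1, I2);
      C.submat(p, 0, 2 * p - 1, p - 1) = G12(I2, I1);
      C.submat(p, p, 2 * p - 1, 2 * p - 1) = G22(I2, I2);
      rhs.subvec(0, p - 1) = R1(I1);
      rhs.subvec(p, 2 * p - 1) = R2(I2);
      const bool ok = solve(beta, C, rhs,
                            solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) {
        Rcpp::stop("rank-deficient design at position pair (%d, %d)",
                   (int)(i + 1), (int)(j + 1));
      }
      const double quad = yWy - dot(rhs, beta);
      out(i, j) = -0.5 * (cst + quad) / LN10;
    }
  }
  return out;
}

// EM-REML for the bivariate mixed model in the rotated basis.
//
// Missing data are the polygenic effects g (rotated: g_i ~ N(0, d_i Vg))
// and, under REML, the fixed effects with a flat prior.  Writing
// P = S^{-1} - S^{-1} X (X'S^{-1}X)^{-1} X'S^{-1} and t = P y, the E-step
// needs only the per-subject 2x2 diagonal blocks P_ii, and the M-step is
//   Vg <- Vg + Vg [ (1/n) sum_i d_i (t_i t_i' - P_ii) ] Vg
//   Ve <- Ve + Ve [ (1/n) sum_i     (t_i t_i' - P_ii) ] Ve
// which keeps the restricted likelihood nondecreasing.
//
//' @noRd
// [[Rcpp::export]]
Rcpp::List cpp_reml_em(const arma::mat& Yr, const arma::mat& Xr,
                       const arma::vec& d, arma::mat Vg, arma::mat Ve,
                       int maxit, double tol, double vfloor) {
  const uword n = Yr.n_rows;
  const uword p0 = Xr.n_cols;
  const vec y1 = Yr.col(0), y2 = Yr.col(1);

  std::vector<double> trace;
  trace.reserve(64);
  double ll_prev = -datum::inf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < maxit; ++iter) {
    Weights W = make_weights(d, Vg, Ve);

    // GLS at the current variance components
    mat C(2 * p0, 2 * p0);
    C.submat(0, 0, p0 - 1, p0 - 1) = Xr.t() * (Xr.each_col() % W.w11);
    C.submat(0, p0, p0 - 1, 2 * p0 - 1) = Xr.t() * (Xr.each_col() % W.w12);
    C.submat(p0, 0, 2 * p0 - 1, p0 - 1) =
        C.submat(0, p0, p0 - 1, 2 * p0 - 1).t();
    C.submat(p0, p0, 2 * p0 - 1, 2 * p0 - 1) =
        Xr.t() * (Xr.each_col() % W.w22);
    vec rhs(2 * p0);
    rhs.subvec(0, p0 - 1) = Xr.t() * (W.w11 % y1 + W.w12 % y2);
    rhs.subvec(p0, 2 * p0 - 1) = Xr.t() * (W.w12 % y1 + W.w22 % y2);

    mat Cinv;
    if (!inv_sympd(Cinv, symmatu(C))) {
      if (!inv(Cinv, C)) Rcpp::stop("null design matrix is rank-deficient");
    }
    const vec beta = Cinv * rhs;
    double lndetC, signC;
    log_det(lndetC, signC, C);

    const vec e1 = y1 - Xr * beta.subvec(0, p0 - 1);
    const vec e2 = y2 - Xr * beta.subvec(p0, 2 * p0 - 1);
    const vec t1 = W.w11 % e1 + W.w12 % e2;
    const vec t2 = W.w12 % e1 + W.w22 % e2;
    const double quad = dot(e1, t1) + dot(e2, t2);

    const double ll =
        -0.5 * ((2.0 * n - 2.0 * p0) * std::log(2.0 * datum::pi) + W.logdet +
                lndetC + quad);
    trace.push_back(ll / LN10);

    if (iter > 0 && std::fabs(ll - ll_prev) <= tol * (std::fabs(ll_prev) + 1.0)) {
      converged = true;
      break;
    }
    ll_prev = ll;

    // per-subject diagonal blocks of P = W - W Z Cinv Z' W
    const mat A11 = Cinv.submat(0, 0, p0 - 1, p0 - 1);
    const mat A12 = Cinv.submat(0, p0, p0 - 1, 2 * p0 - 1);
    const mat A22 = Cinv.submat(p0, p0, 2 * p0 - 1, 2 * p0 - 1);
    const vec h11 = sum((Xr * A11) % Xr, 1);
    const vec h12 = sum((Xr * A12) % Xr, 1);
    const vec h22 = sum((Xr * A22) % Xr, 1);

    const vec a11 = W.w11 % h11 + W.w12 % h12;
    const vec a12 = W.w11 % h12 + W.w12 % h22;
    const vec a21 = W.w12 % h11 + W.w22 % h12;
    const vec a22 = W.w12 % h12 + W.w22 % h22;
    const vec P11 = W.w11 - (a11 % W.w11 + a12 % W.w12);
    const vec P12 = W.w12 - (a11 % W.w12 + a12 % W.w22);
    const vec P22 = W.w22 - (a21 % W.w12 + a22 % W.w22);

    mat Se(2, 2), Sg(2, 2);
    Se(0, 0) = accu(t1 % t1 - P11);
    Se(0, 1) = Se(1, 0) = accu(t1 % t2 - P12);
    Se(1, 1) = accu(t2 % t2 - P22);
    Sg(0, 0) = accu(d % (t1 % t1 - P11));
    Sg(0, 1) = Sg(1, 0) = accu(d % (t1 % t2 - P12));
    Sg(1, 1) = accu(d % (t2 % t2 - P22));

    Vg = psd_floor(symmatu(Vg + Vg * (Sg / (double)n) * Vg), vfloor);
    Ve = psd_floor(symmatu(Ve + Ve * (Se / (double)n) * Ve), vfloor);
  }

  return Rcpp::List::create(
      Rcpp::Named("Vg") = Vg, Rcpp::Named("Ve") = Ve,
      Rcpp::Named("ll10_trace") = trace,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iter") = (int)trace.size());
}
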