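// ADMM solver for the combined l1/l2-norm soft-margin SVM
//
//   min_{w,theta}  (1-lambda) * [ alpha * sum_{j in P} y_j + (1-alpha) * sum_{j in N} z_j ]
//                + lambda * [ gamma * ||w||_1 + (1-gamma) * ||w||_2 ]
//
// with hinge slacks y_j = (1 - (w'x_j - theta))_+ for positives and
// z_j = (1 + (w'x_j - theta))_+ for negatives. Splitting variables:
// u = B beta (signed margins, B = diag(labels) [X, -1], beta = (w, theta))
// and v = beta. Both proximal maps are closed form; the penalty prox is a
// soft-threshold followed by a group (l2-norm) shrinkage on the weight
// coordinates (theta passes through), which returns exact zeros.
// The beta-update solves (I + B'B) beta = rhs; when the feature count
// exceeds the training-sample count this is done through the Woodbury
// identity with a k x k Cholesky factor, otherwise with an (s+1) x (s+1)
// factor. Over-relaxation plus residual-balanced rho adaptation, frozen
// after `adapt_until` iterations (unbounded adaptation can cycle on
// ill-conditioned instances).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List admm_combined_svm(const arma::mat& X, const arma::vec& y,
                             double lambda, double alpha, double gamma,
                             double rho, int max_iter,
                             double tol_abs, double tol_rel,
                             double over_relax, int adapt_until) {
  const uword k = X.n_rows, s = X.n_cols, d = s + 1;
  mat B(k, d);
  B.cols(0, s - 1) = X.each_col() % y;
  B.col(s) = -y;

  const bool woodbury = (d > 2 * k);
  mat R;  // chol of (I_k + B B') in Woodbury mode, of (I_d + B'B) otherwise
  if (woodbury)
    R = chol(eye<mat>(k, k) + B * B.t());
  else
    R = chol(eye<mat>(d, d) + B.t() * B);

  vec cw(k);
  for (uword j = 0; j < k; ++j)
    cw(j) = (1.0 - lambda) * (y(j) > 0 ? alpha : 1.0 - alpha);

  const double k1 = lambda * gamma;          // l1 weight
  const double k2 = lambda * (1.0 - gamma);  // l2-norm weight

  vec u(k, fill::zeros), v(d, fill::zeros);
  vec p(k, fill::zeros), q(d, fill::zeros);  // scaled duals
  vec beta(d, fill::zeros);
  double rp = datum::inf, rd = datum::inf;
  bool converged = false;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    vec rhs = B.t() * (u - p) + (v - q);
    if (woodbury) {
      vec t = B * rhs;
      beta = rhs - B.t() * solve(trimatu(R), solve(trimatl(R.t()), t));
    } else {
      beta = solve(trimatu(R), solve(trimatl(R.t()), rhs));
    }
    vec Bb = B * beta;

    vec uh = over_relax * Bb + (1.0 - over_relax) * u;
    vec vh = over_relax * beta + (1.0 - over_relax) * v;

    // prox of the weighted hinge, coordinatewise
    vec au = uh + p;
    vec u_new(k);
    for (uword j = 0; j < k; ++j) {
      const double a = au(j), c = cw(j) / rho;
      u_new(j) = (a >= 1.0) ? a : ((a <= 1.0 - c) ? a + c : 1.0);
    }

    // prox of k1*||.||_1 + k2*||.||_2 on the weight block; theta untouched
    vec av = vh + q;
    vec v_new(d);
    double nv2 = 0.0;
    for (uword i = 0; i < s; ++i) {
      const double a = av(i);
      const double sv = (a > k1 / rho) ? a - k1 / rho
                        : ((a < -k1 / rho) ? a + k1 / rho : 0.0);
      v_new(i) = sv;
      nv2 += sv * sv;
    }
    const double nv = std::sqrt(nv2);
    if (nv > 0.0) {
      const double shrink = std::max(0.0, 1.0 - (k2 / rho) / nv);
      for (uword i = 0; i < s; ++i) v_new(i) *= shrink;
    }
    v_new(s) = av(s);

    p += uh - u_new;
    q += vh - v_new;

    rp = std::sqrt(accu(square(Bb - u_new)) + accu(square(beta - v_new)));
    vec dvec = B.t() * (u_new - u) + (v_new - v);
    rd = rho * norm(dvec, 2);
    u = u_new;
    v = v_new;

    const double ep = std::sqrt(double(k + d)) * tol_abs +
      tol_rel * std::max(std::sqrt(accu(square(Bb)) + accu(square(beta))),
                         std::sqrt(accu(square(u)) + accu(square(v))));
    vec dd = B.t() * p + q;
    const double ed = std::sqrt(double(d)) * tol_abs +
      tol_rel * rho * norm(dd, 2);
    if (rp < ep && rd < ed) { converged = true; break; }

    if (it <= adapt_until && it % 25 == 0) {
      if (rp > 10.0 * rd)      { rho *= 2.0; p /= 2.0; q /= 2.0; }
      else if (rd > 10.0 * rp) { rho /= 2.0; p *= 2.0; q *= 2.0; }
    }
  }

  vec w = v.subvec(0, s - 1);
  return Rcpp::List::create(
    Rcpp::Named("w") = w,
    Rcpp::Named("theta") = beta(s),
    Rcpp::Named("iterations") = std::min(it, max_iter),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("primal_residual") = rp,
    Rcpp::Named("dual_residual") = rd,
    Rcpp::Named("rho") = rho);
}
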