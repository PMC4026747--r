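// Penalized least-squares solvers on centered data.
//
// All routines work with the Gram formulation: given A = Xc'Xc and b = Xc'Yc,
// the quadratic loss is 1/2 beta'A beta - b'beta (+ const).  Coordinate
// descent handles separable L1 terms; an ADMM splitting handles pairwise
// fused terms; the non-convex truncated-L1 fits run a difference-of-convex
// outer loop around these with a monotone-acceptance guard on the true
// objective.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// quadratic part of the objective: 1/2||Yc - Xc beta||^2 given yty = Yc'Yc
static inline double qloss(const mat& A, const vec& b, double yty, const vec& beta) {
  return 0.5 * (yty - 2.0 * dot(b, beta) + dot(beta, A * beta));
}

// Cyclic coordinate descent for
//   1/2 beta'A beta - b'beta + sum_j w_j |beta_j|
// Columns with A_jj == 0 (monomorphic after centering) stay at zero.
static int cd_solve(const mat& A, const vec& b, const vec& w, vec& beta,
                    double tol, int max_iter) {
  const uword k = A.n_rows;
  vec Ab = A * beta;          // running A %*% beta
  int it = 0;
  for (; it < max_iter; ++it) {
    double delta = 0.0;
    for (uword j = 0; j < k; ++j) {
      double ajj = A(j, j);
      double old = beta(j);
      double nb;
      if (ajj <= 1e-300) {
        nb = 0.0;
      } else {
        double g = b(j) - (Ab(j) - ajj * old);
        nb = soft(g, w(j)) / ajj;
      }
      if (nb != old) {
        Ab += A.col(j) * (nb - old);
        beta(j) = nb;
        double d = std::abs(nb - old);
        if (d > delta) delta = d;
      }
    }
    if (delta < tol) { ++it; break; }
  }
  return it;
}

// [[Rcpp::export]]
Rcpp::List cpp_wlasso(const arma::mat& A, const arma::vec& b, const arma::vec& w,
                      const arma::vec& beta_init, double tol, int max_iter) {
  vec beta = beta_init;
  int it = cd_solve(A, b, w, beta, tol, max_iter);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = it < max_iter);
}

// Warm-started path over a lambda sequence (as given).
// [[Rcpp::export]]
arma::mat cpp_lasso_path(const arma::mat& A, const arma::vec& b,
                         const arma::vec& lambdas, double tol, int max_iter) {
  const uword k = A.n_rows, L = lambdas.n_elem;
  mat out(k, L, fill::zeros);
  vec beta(k, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    vec w(k); w.fill(lambdas(l));
    cd_solve(A, b, w, beta, tol, max_iter);
    out.col(l) = beta;
  }
  return out;
}

// ADMM for
//   1/2 beta'A beta - b'beta + sum_j w_j|beta_j| + sum_p pw_p |beta_i(p) - r_p beta_j(p)|
// Splitting z1 = beta, z2 = D beta with D the signed pairwise-difference matrix.
static int admm_solve(const mat& A, const vec& b, const vec& w,
                      const uvec& pi, const uvec& pj, const vec& pw, const vec& pr,
                      vec& beta, double rho, double tol, int max_iter) {
  const uword k = A.n_rows, P = pi.n_elem;
  mat D(P, k, fill::zeros);
  for (uword p = 0; p < P; ++p) {
    D(p, pi(p)) += 1.0;
    D(p, pj(p)) -= pr(p);
  }
  mat M = A + rho * (eye(k, k) + D.t() * D);
  mat R_ = chol(M);
  vec z1 = beta, u1(k, fill::zeros);
  vec z2 = D * beta, u2(P, fill::zeros);
  int it = 0;
  for (; it < max_iter; ++it) {
    vec rhs = b + rho * (z1 - u1) + rho * (D.t() * (z2 - u2));
    beta = solve(trimatu(R_), solve(trimatl(R_.t()), rhs));
    vec Db = D * beta;
    vec z1n(k), z2n(P);
    for (uword j = 0; j < k; ++j) z1n(j) = soft(beta(j) + u1(j), w(j) / rho);
    for (uword p = 0; p < P; ++p) z2n(p) = soft(Db(p) + u2(p), pw(p) / rho);
    double pri = std::sqrt(accu(square(beta - z1n)) + accu(square(Db - z2n)));
    double dua = rho * std::sqrt(accu(square(z1n - z1)) + accu(square(z2n - z2)));
    u1 += beta - z1n;
    u2 += Db - z2n;
    z1 = z1n; z2 = z2n;
    if (pri < tol && dua < tol) { ++it; break; }
  }
  beta = z1;   // z1 carries exact zeros from the shrinkage step
  return it;
}

// [[Rcpp::export]]
Rcpp::List cpp_gflasso(const arma::mat& A, const arma::vec& b, double yty,
                       double lambda1, double lambda2,
                       const arma::uvec& pi, const arma::uvec& pj, const arma::vec& pr,
                       const arma::vec& beta_init, double rho, double tol, int max_iter) {
  const uword k = A.n_rows, P = pi.n_elem;
  vec w(k); w.fill(lambda1);
  vec pw(P); pw.fill(lambda2);
  vec beta = beta_init;
  int it = admm_solve(A, b, w, pi, pj, pw, pr, beta, rho, tol, max_iter);
  double obj = qloss(A, b, yty, beta) + lambda1 * accu(abs(beta));
  for (uword p = 0; p < P; ++p) obj += lambda2 * std::abs(beta(pi(p)) - pr(p) * beta(pj(p)));
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = it < max_iter);
}

static inline double tlp(double x, double tau) {
  double v = std::abs(x) / tau;
  return v < 1.0 ? v : 1.0;
}

static double obj_tlp_s(const mat& A, const vec& b, double yty,
                        double lambda1, double tau, const vec& beta) {
  double o = qloss(A, b, yty, beta);
  for (uword j = 0; j < beta.n_elem; ++j) o += lambda1 * tlp(beta(j), tau);
  return o;
}

static double obj_tlp_sg(const mat& A, const vec& b, double yty,
                         double lambda1, double lambda2, double tau,
                         const uvec& pi, const uvec& pj, const vec& beta) {
  double o = obj_tlp_s(A, b, yty, lambda1, tau, beta);
  for (uword p = 0; p < pi.n_elem; ++p)
    o += lambda2 * tlp(std::abs(beta(pi(p))) - std::abs(beta(pj(p))), tau);
  return o;
}

// TLP-S: DC outer loop around weighted-lasso inner solves.
// Surrogate at iterate m:  (l1/tau)|beta_j| - (l1/tau) sign(m_j) I(|m_j|>tau) beta_j,
// absorbed into the linear term of the quadratic.
// [[Rcpp::export]]
Rcpp::List cpp_tlp_s(const arma::mat& A, const arma::vec& b, double yty,
                     double lambda1, double tau, const arma::vec& beta_init,
                     double tol_inner, double tol_outer,
                     int max_outer, int max_inner) {
  const uword k = A.n_rows;
  vec beta = beta_init;
  vec best = beta;
  double best_obj = obj_tlp_s(A, b, yty, lambda1, tau, beta);
  vec w(k); w.fill(lambda1 / tau);
  int outer = 0; bool conv = false;
  for (; outer < max_outer; ++outer) {
    vec beff = b;
    for (uword j = 0; j < k; ++j)
      if (std::abs(beta(j)) > tau)
        beff(j) += (lambda1 / tau) * (beta(j) >= 0 ? 1.0 : -1.0);
    cd_solve(A, beff, w, beta, tol_inner, max_inner);
    double obj = obj_tlp_s(A, b, yty, lambda1, tau, beta);
    if (obj < best_obj - tol_outer) {
      best_obj = obj; best = beta;
    } else {
      if (obj < best_obj) { best_obj = obj; best = beta; }
      conv = true; ++outer; break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = best,
                            Rcpp::Named("objective") = best_obj,
                            Rcpp::Named("iterations") = outer,
                            Rcpp::Named("converged") = conv || outer < max_outer);
}

// TLP-SG: DC outer loop; signs fixed at the current iterate turn the
// |.|-difference grouping term into a signed fused term handled by ADMM;
// the concave halves of both truncated penalties are linearized.  A
// monotone-acceptance guard keeps the best iterate of the true objective.
// [[Rcpp::export]]
Rcpp::List cpp_tlp_sg(const arma::mat& A, const arma::vec& b, double yty,
                      double lambda1, double lambda2, double tau,
                      const arma::uvec& pi, const arma::uvec& pj,
                      const arma::vec& beta_init, double rho,
                      double tol_inner, double tol_outer,
                      int max_outer, int max_inner) {
  const uword k = A.n_rows, P = pi.n_elem;
  vec beta = beta_init;
  vec best = beta;
  double best_obj = obj_tlp_sg(A, b, yty, lambda1, lambda2, tau, pi, pj, beta);
  vec w(k); w.fill(lambda1 / tau);
  vec pw(P); pw.fill(lambda2 / tau);
  int outer = 0; bool conv = false;
  for (; outer < max_outer; ++outer) {
    vec s(k);
    for (uword j = 0; j < k; ++j) s(j) = beta(j) >= 0 ? 1.0 : -1.0;
    vec beff = b;
    for (uword j = 0; j < k; ++j)
      if (std::abs(beta(j)) > tau) beff(j) += (lambda1 / tau) * s(j);
    vec pr(P);
    for (uword p = 0; p < P; ++p) {
      pr(p) = s(pi(p)) * s(pj(p));
      double d = std::abs(beta(pi(p))) - std::abs(beta(pj(p)));
      if (std::abs(d) > tau) {
        // linearized slope of -(l2/tau) max(|d|-tau, 0) w.r.t. beta
        double g = (lambda2 / tau) * (d >= 0 ? 1.0 : -1.0);
        beff(pi(p)) += g * s(pi(p));
        beff(pj(p)) -= g * s(pj(p));
      }
    }
    admm_solve(A, beff, w, pi, pj, pw, pr, beta, rho, tol_inner, max_inner);
    double obj = obj_tlp_sg(A, b, yty, lambda1, lambda2, tau, pi, pj, beta);
    if (obj < best_obj - tol_outer) {
      best_obj = obj; best = beta;
    } else {
      if (obj < best_obj) { best_obj = obj; best = beta; }
      conv = true; ++outer; break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = best,
                            Rcpp::Named("objective") = best_obj,
                            Rcpp::Named("iterations") = outer,
                            Rcpp::Named("converged") = conv || outer < max_outer);
}
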