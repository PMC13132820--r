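// Core numerical kernels for two-block sparse PLS:
// soft-thresholding, projection onto {w : ||w||_2 = 1, ||w||_1 <= c},
// and the alternating power iteration on the cross-product matrix.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec soft(const vec& w, double delta) {
  return sign(w) % clamp(abs(w) - delta, 0.0, datum::inf);
}

// Scaled soft-threshold: s(delta) = soft(w, delta) / ||soft(w, delta)||_2.
// ||s(delta)||_1 decreases from ||w/||w||_2||_1 toward 1 as delta grows;
// bisect delta until ||s||_1 is within tol of the l1 budget c.
static vec l1l2_project_impl(const vec& w, double c, double tol, double* delta_out) {
  double nw = norm(w, 2);
  if (nw == 0.0) { if (delta_out) *delta_out = 0.0; return zeros<vec>(w.n_elem); }
  vec s = w / nw;
  if (norm(s, 1) <= c + tol) { if (delta_out) *delta_out = 0.0; return s; }
  double lo = 0.0, hi = abs(w).max();
  double delta = 0.0;
  for (int it = 0; it < 200; ++it) {
    delta = 0.5 * (lo + hi);
    vec st = soft(w, delta);
    double n2 = norm(st, 2);
    double l1 = (n2 > 0.0) ? norm(st / n2, 1) : 1.0;
    if (std::abs(l1 - c) <= tol) break;
    if (l1 > c) lo = delta; else hi = delta;
  }
  vec st = soft(w, delta);
  double n2 = norm(st, 2);
  if (delta_out) *delta_out = delta;
  if (n2 == 0.0) return zeros<vec>(w.n_elem);
  return st / n2;
}

// [[Rcpp::export]]
arma::vec cpp_soft_threshold(const arma::vec& w, double delta) {
  return soft(w, delta);
}

// [[Rcpp::export]]
Rcpp::List cpp_l1l2_project(const arma::vec& w, double c, double tol) {
  double delta = 0.0;
  vec s = l1l2_project_impl(w, c, tol, &delta);
  return Rcpp::List::create(Rcpp::Named("w") = s,
                            Rcpp::Named("delta") = delta,
                            Rcpp::Named("zero") = (norm(s, 2) == 0.0));
}

// Alternating soft-thresholded power iteration on M = X^T Y.
// Initialization: leading right singular vector of M (deterministic).
// Convergence: ||u - u_prev||_2 + ||v - v_prev||_2 < tol.
// [[Rcpp::export]]
Rcpp::List cpp_spls_fit(const arma::mat& M, double cu, double cv,
                        double proj_tol, double conv_tol, int maxit) {
  mat U, V;
  vec sv;
  bool ok = svd_econ(U, sv, V, M);
  if (!ok) Rcpp::stop("SVD of the cross-product matrix failed");
  vec v = V.col(0);
  vec u = zeros<vec>(M.n_rows);
  std::vector<double> objective;
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= maxit; ++iter) {
    vec u_new = l1l2_project_impl(M * v, cu, proj_tol, nullptr);
    vec v_new = l1l2_project_impl(M.t() * u_new, cv, proj_tol, nullptr);
    objective.push_back(dot(u_new, M * v_new));
    double change = norm(u_new - u, 2) + norm(v_new - v, 2);
    u = u_new; v = v_new;
    if (change < conv_tol) { converged = true; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("u") = u,
      Rcpp::Named("v") = v,
      Rcpp::Named("iterations") = std::min(iter, maxit),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("objective") = objective);
}
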