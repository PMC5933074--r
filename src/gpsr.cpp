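#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gradient-projection solver for the penalized sparse coding problem
//   min_x  0.5 * ||y - A x||^2 + tau * ||x||_1
// on the positive split x = u - v (u, v >= 0), with a Barzilai-Borwein
// step proposal and an exact line search along the projected direction
// (the objective is quadratic along the segment, so the minimizing step
// is closed form and the iteration is monotone by construction).
//
// Two backends share the iteration:
//  * Gram mode: works on G = A'A and c = A'y; per-iteration cost O(M^2).
//    Wins when the dictionary has fewer columns than rows and when G is
//    cached across many queries (the self-training stream).
//  * Matrix mode: works on A directly; per-iteration cost O(N*M).
//    Wins for wide, short dictionaries (random-subspace members).

namespace {

struct GpsrTrace {
  std::vector<double> obj;
  int n_iter = 0;
  bool converged = false;
};

// One monotone BB iteration loop. Callbacks provide gradient updates.
//  mulG(d) must return G*d (Gram of A applied to a length-M vector).
template <typename MulG>
void gpsr_iterate(vec& u, vec& v, vec& grad, double f_quad_const,
                  const vec& c, double tau, double tol, int max_iter,
                  MulG mulG, GpsrTrace& tr) {
  const double alpha_min = 1e-30, alpha_max = 1e30;
  double alpha = 1.0;
  vec x = u - v;
  // grad holds G*x - c on entry
  double f = 0.5 * dot(x, grad - c) + f_quad_const;
  double F = f + tau * (accu(u) + accu(v));
  tr.obj.push_back(F);
  for (int k = 0; k < max_iter; ++k) {
    vec gu = grad + tau;
    vec gv = -grad + tau;
    vec unew = u - alpha * gu;
    unew.transform([](double z) { return z > 0.0 ? z : 0.0; });
    vec vnew = v - alpha * gv;
    vnew.transform([](double z) { return z > 0.0 ? z : 0.0; });
    vec du = unew - u;
    vec dv = vnew - v;
    double gd = dot(gu, du) + dot(gv, dv);
    if (gd >= -1e-18 * std::max(1.0, std::abs(F))) {
      // projected direction gives no descent: stationary point
      tr.converged = true;
      tr.n_iter = k;
      return;
    }
    vec dx = du - dv;
    vec Gdx = mulG(dx);
    double curv = dot(dx, Gdx);
    double lambda = 1.0;
    if (curv > 0.0) lambda = std::min(1.0, -gd / curv);
    u += lambda * du;
    v += lambda * dv;
    grad += lambda * Gdx;
    // shave the overlap min(u, v): leaves x unchanged, shrinks the l1 term
    vec m = arma::min(u, v);
    if (accu(m) > 0.0) { u -= m; v -= m; }
    x = u - v;
    double Fprev = F;
    f = 0.5 * dot(x, grad - c) + f_quad_const;
    F = f + tau * (accu(u) + accu(v));
    if (F > Fprev) F = Fprev;  // guard against roundoff in the trace
    tr.obj.push_back(F);
    // BB step for the next proposal (lambda^2 cancels in the ratio)
    double dz2 = dot(du, du) + dot(dv, dv);
    alpha = (curv > 0.0) ? std::min(alpha_max, std::max(alpha_min, dz2 / curv))
                         : alpha_max;
    if (std::abs(Fprev - F) <= tol * std::max(std::abs(Fprev), 1e-12)) {
      tr.converged = true;
      tr.n_iter = k + 1;
      return;
    }
  }
  tr.n_iter = max_iter;
  tr.converged = false;
}

// Continuation for very small penalties: GPSR converges slowly when tau is
// a tiny fraction of tau_max = ||c||_inf, so warm-start through a short
// geometric tau sequence first. Only the final (true-tau) stage contributes
// the reported trace and iteration count.
template <typename MulG>
void gpsr_solve(vec& u, vec& v, vec& grad, double f_quad_const, const vec& c,
                double tau, double tol, int max_iter, MulG mulG,
                GpsrTrace& tr) {
  double tau_max = c.n_elem > 0 ? arma::abs(c).max() : 0.0;
  if (tau_max > 0.0 && tau < 0.02 * tau_max) {
    double floor_tau = std::max(tau, 1e-6 * tau_max);
    double tau_j = 0.25 * tau_max;
    int stages = 0;
    while (tau_j > floor_tau && stages < 12) {
      GpsrTrace scratch;
      gpsr_iterate(u, v, grad, f_quad_const, c, tau_j,
                   std::max(tol * 1e3, 1e-4), 50, mulG, scratch);
      tau_j *= 0.25;
      ++stages;
    }
  }
  gpsr_iterate(u, v, grad, f_quad_const, c, tau, tol, max_iter, mulG, tr);
}

Rcpp::List pack(const vec& u, const vec& v, const GpsrTrace& tr) {
  vec x = u - v;
  return Rcpp::List::create(
      Rcpp::Named("x") = x,
      Rcpp::Named("objective_trace") = tr.obj,
      Rcpp::Named("n_iter") = tr.n_iter,
      Rcpp::Named("converged") = tr.converged);
}

}  // namespace

// One voting step of the random-subspace sparse ensemble: every member
// codes its subspace view of the query against its own dictionary slice and
// votes by the maximal per-class average coefficient. Dictionaries of all
// members share the column layout (labels li, 1-based class indices, first
// mcols columns active). X holds per-member warm starts (Mmax x L) and is
// updated in place. Returns 1-based vote class indices.
// [[Rcpp::export]]
Rcpp::IntegerVector rse_srcave_votes_cpp(const arma::cube& A,
                                         const arma::umat& subsets,
                                         const arma::vec& y, int mcols,
                                         const arma::ivec& li,
                                         const arma::vec& counts,
                                         double tau_scale, double tau_fixed,
                                         double tol, int max_iter,
                                         Rcpp::NumericMatrix X) {
  const uword L = A.n_slices, m = (uword)mcols, K = counts.n_elem;
  Rcpp::IntegerVector votes(L);
  for (uword l = 0; l < L; ++l) {
    const mat& Al = A.slice(l);
    auto Ablk = Al.cols(0, m - 1);
    vec ysub(subsets.n_rows);
    for (uword j = 0; j < subsets.n_rows; ++j) ysub[j] = y[subsets(j, l) - 1];
    vec c = Ablk.t() * ysub;
    double tau = tau_fixed >= 0 ? tau_fixed
                                : tau_scale * arma::abs(c).max();
    if (!std::isfinite(tau)) tau = 0.0;
    vec x(m);
    for (uword j = 0; j < m; ++j) x[j] = X(j, l);
    vec u = x, v = -x;
    u.transform([](double z) { return z > 0.0 ? z : 0.0; });
    v.transform([](double z) { return z > 0.0 ? z : 0.0; });
    vec grad = Ablk.t() * (Ablk * x) - c;
    GpsrTrace tr;
    gpsr_solve(u, v, grad, 0.5 * dot(ysub, ysub), c, tau, tol, max_iter,
               [&](const vec& d) -> vec { return Ablk.t() * (Ablk * d); },
               tr);
    x = u - v;
    for (uword j = 0; j < m; ++j) X(j, l) = x[j];
    vec avg(K, fill::zeros);
    for (uword j = 0; j < m; ++j) avg[li[j] - 1] += x[j];
    avg /= counts;
    votes[l] = (int)avg.index_max() + 1;
  }
  return votes;
}

// Gram-mode solver. G may be larger than the active problem: only the
// leading mcols x mcols block is used (supports a preallocated, growing
// Gram cache without copies on the R side).
// [[Rcpp::export]]
Rcpp::List gpsr_gram_cpp(const arma::mat& G, const arma::vec& c, double yty,
                         double tau, double tol, int max_iter,
                         Rcpp::Nullable<Rcpp::NumericVector> x0 = R_NilValue) {
  const uword m = c.n_elem;
  if (G.n_rows < m || G.n_cols < m)
    Rcpp::stop("Gram matrix smaller than coefficient dimension");
  vec x(m, fill::zeros);
  if (x0.isNotNull()) {
    Rcpp::NumericVector x0v(x0);
    if ((uword)x0v.size() != m) Rcpp::stop("warm start has wrong length");
    x = vec(x0v.begin(), m);
  }
  vec u = x, v = -x;
  u.transform([](double z) { return z > 0.0 ? z : 0.0; });
  v.transform([](double z) { return z > 0.0 ? z : 0.0; });
  auto Gblk = G.submat(0, 0, m - 1, m - 1);
  vec grad = Gblk * x - c;
  GpsrTrace tr;
  gpsr_solve(u, v, grad, 0.5 * yty, c, tau, tol, max_iter,
             [&](const vec& d) -> vec { return Gblk * d; }, tr);
  return pack(u, v, tr);
}

// Matrix-mode solver (products with A and A' each iteration). Only the
// leading mcols columns of A are used when mcols > 0, so a preallocated,
// growing dictionary can be passed without copies.
// [[Rcpp::export]]
Rcpp::List gpsr_mat_cpp(const arma::mat& A, const arma::vec& y, double tau,
                        double tol, int max_iter,
                        Rcpp::Nullable<Rcpp::NumericVector> x0 = R_NilValue,
                        int mcols = -1) {
  const uword m = mcols > 0 ? (uword)mcols : A.n_cols;
  if (m > A.n_cols) Rcpp::stop("mcols exceeds dictionary width");
  vec x(m, fill::zeros);
  if (x0.isNotNull()) {
    Rcpp::NumericVector x0v(x0);
    if ((uword)x0v.size() != m) Rcpp::stop("warm start has wrong length");
    x = vec(x0v.begin(), m);
  }
  vec u = x, v = -x;
  u.transform([](double z) { return z > 0.0 ? z : 0.0; });
  v.transform([](double z) { return z > 0.0 ? z : 0.0; });
  auto Ablk = A.cols(0, m - 1);
  vec c = Ablk.t() * y;
  vec grad = Ablk.t() * (Ablk * x) - c;
  GpsrTrace tr;
  gpsr_solve(u, v, grad, 0.5 * dot(y, y), c, tau, tol, max_iter,
             [&](const vec& d) -> vec { return Ablk.t() * (Ablk * d); }, tr);
  return pack(u, v, tr);
}
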