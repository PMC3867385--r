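// Dense bounded-variable revised simplex.
//
// Solves   min  c'x   s.t.  A x = b,  lb <= x <= ub
// starting from a caller-supplied feasible basis.  Both linear programs
// assembled by the package (the 1-norm SVM primal and its dual) admit a
// trivial feasible starting basis, so no phase-1 is needed.
//
// Pricing is Dantzig (most negative reduced cost); after `blandAfter`
// iterations it switches to Bland's rule, which guarantees termination
// under degeneracy.  The basis inverse is maintained by product-form
// updates and refactorized periodically for numerical hygiene.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List cpp_bounded_simplex(const arma::mat& A,
                               const arma::vec& b,
                               const arma::vec& cost,
                               const arma::vec& lb,
                               const arma::vec& ub,
                               const arma::uvec& basis0, // 1-based
                               double tol = 1e-9,
                               int maxit = 50000) {
  const uword m = A.n_rows, nv = A.n_cols;
  if (basis0.n_elem != m) Rcpp::stop("basis0 must have one entry per row");

  uvec basis = basis0 - 1;
  std::vector<bool> isBasic(nv, false);
  for (uword i = 0; i < m; ++i) isBasic[basis[i]] = true;

  // nonbasic bound status: true = at upper bound
  std::vector<bool> atUpper(nv, false);
  vec x(nv);
  for (uword j = 0; j < nv; ++j) x[j] = lb[j]; // nonbasic start at lower

  mat Binv;
  if (!inv(Binv, A.cols(basis)))
    Rcpp::stop("initial basis is singular");

  // basic values
  vec rhs = b;
  for (uword j = 0; j < nv; ++j)
    if (!isBasic[j] && x[j] != 0.0) rhs -= A.col(j) * x[j];
  vec xB = Binv * rhs;

  const int blandAfter = std::max(2000, (int)(20 * (m + nv)));
  const int refactorEvery = 100;
  int status = 1; // 1 = maxit
  int it = 0;

  for (it = 0; it < maxit; ++it) {
    if (it > 0 && it % refactorEvery == 0) {
      if (!inv(Binv, A.cols(basis))) { status = 3; break; }
      rhs = b;
      for (uword j = 0; j < nv; ++j)
        if (!isBasic[j] && x[j] != 0.0) rhs -= A.col(j) * x[j];
      xB = Binv * rhs;
    }

    // multipliers and reduced costs (vectorized pricing)
    vec cB(m);
    for (uword i = 0; i < m; ++i) cB[i] = cost[basis[i]];
    vec piv = Binv.t() * cB;
    vec redc = cost - (piv.t() * A).t();

    // entering variable
    sword q = -1;
    double best = tol;
    const bool bland = it >= blandAfter;
    for (uword j = 0; j < nv; ++j) {
      if (isBasic[j]) continue;
      if (lb[j] == ub[j]) continue; // fixed variable never enters
      double viol = atUpper[j] ? redc[j] : -redc[j];
      if (viol > (bland ? tol : best)) {
        q = (sword)j;
        if (bland) break;
        best = viol;
      }
    }
    if (q < 0) { status = 0; break; } // optimal

    const double sgn = atUpper[q] ? -1.0 : 1.0; // direction of x_q
    vec aq = Binv * A.col((uword)q);
    vec d = sgn * aq; // xB moves by -t*d

    // ratio test
    double tmax = ub[q] - lb[q]; // bound flip distance (may be inf)
    sword leave = -1;
    bool leaveToUpper = false;
    for (uword i = 0; i < m; ++i) {
      uword bi = basis[i];
      if (d[i] > tol) {
        double tl = (xB[i] - lb[bi]) / d[i];
        if (tl < tmax - 1e-12) { tmax = tl; leave = (sword)i; leaveToUpper = false; }
      } else if (d[i] < -tol) {
        if (std::isfinite(ub[bi])) {
          double tl = (ub[bi] - xB[i]) / (-d[i]);
          if (tl < tmax - 1e-12) { tmax = tl; leave = (sword)i; leaveToUpper = true; }
        }
      }
    }
    if (!std::isfinite(tmax)) { status = 2; break; } // unbounded

    if (tmax < 0) tmax = 0; // degenerate step
    xB -= tmax * d;
    x[q] += sgn * tmax;

    if (leave < 0) {
      atUpper[q] = !atUpper[q]; // bound flip, basis unchanged
      continue;
    }

    uword lv = basis[leave];
    x[lv] = leaveToUpper ? ub[lv] : lb[lv];
    atUpper[lv] = leaveToUpper;
    isBasic[lv] = false;
    isBasic[q] = true;
    basis[leave] = (uword)q;
    xB[leave] = x[q];

    // product-form update of Binv
    double pivel = aq[leave];
    if (std::abs(pivel) < 1e-12) { // numerically bad pivot: refactorize
      if (!inv(Binv, A.cols(basis))) { status = 3; break; }
      rhs = b;
      for (uword j = 0; j < nv; ++j)
        if (!isBasic[j] && x[j] != 0.0) rhs -= A.col(j) * x[j];
      xB = Binv * rhs;
      continue;
    }
    rowvec Brow = Binv.row(leave) / pivel;
    Binv -= aq * Brow;
    Binv.row(leave) = Brow;
  }

  for (uword i = 0; i < m; ++i) x[basis[i]] = xB[i];
  vec cB(m);
  for (uword i = 0; i < m; ++i) cB[i] = cost[basis[i]];
  vec piv = Binv.t() * cB;

  return Rcpp::List::create(
    Rcpp::Named("x") = x,
    Rcpp::Named("obj") = dot(cost, x),
    Rcpp::Named("pi") = piv,
    Rcpp::Named("basis") = basis + 1,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("status") = status);
}
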