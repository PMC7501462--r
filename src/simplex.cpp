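// Bounded-variable two-phase primal simplex for dense LPs:
//   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
// Small genome-scale toy models (m, n in the hundreds) only; dense algebra
// via Armadillo. Bland's rule engages after a run of degenerate pivots, so
// termination is guaranteed. Feasibility tolerance 1e-9 (model convention).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <limits>

using namespace arma;

static const double INF = std::numeric_limits<double>::infinity();

enum VarState { BASIC = 0, NB_LB = 1, NB_UB = 2, NB_FREE = 3 };

struct SimplexResult {
  int status;        // 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
  vec x;
  double obj;
  uvec basis;
  vec duals;         // row duals y at optimum
  vec reduced;       // reduced costs of all columns at optimum
  int iterations;
};

// One simplex run on the full (structural + artificial) problem with
// objective cc (maximization). Mutates x, state, basis in place.
static int simplex_iterate(const mat& A, const vec& b, const vec& cc,
                           const vec& lb, const vec& ub,
                           vec& x, ivec& state, uvec& basis,
                           vec& y_out, vec& d_out, int& iter_total,
                           int max_iter, double tol) {
  const uword m = A.n_rows, N = A.n_cols;
  const double dtol = 1e-9;   // reduced-cost tolerance
  const double ftol = 1e-9;   // ratio-test / feasibility tolerance
  int degenerate_run = 0;
  bool bland = false;

  mat B(m, m);
  for (int it = 0; it < max_iter; ++it, ++iter_total) {
    // refresh basis matrix and (periodically) basic values
    for (uword k = 0; k < m; ++k) B.col(k) = A.col(basis(k));
    if (it % 40 == 0) {
      vec rhs = b;
      for (uword j = 0; j < N; ++j)
        if (state(j) != BASIC && x(j) != 0.0) rhs -= A.col(j) * x(j);
      vec xB;
      if (!solve(xB, B, rhs)) return 1; // singular basis: treat as failure
      for (uword k = 0; k < m; ++k) x(basis(k)) = xB(k);
    }

    // pricing
    vec cB(m);
    for (uword k = 0; k < m; ++k) cB(k) = cc(basis(k));
    vec y;
    if (!solve(y, B.t(), cB)) return 1;
    vec d = cc - A.t() * y;

    int q = -1;
    double best = dtol;
    for (uword j = 0; j < N; ++j) {
      if (state(j) == BASIC) continue;
      bool improving =
        (state(j) == NB_LB && d(j) > dtol) ||
        (state(j) == NB_UB && d(j) < -dtol) ||
        (state(j) == NB_FREE && std::fabs(d(j)) > dtol);
      if (!improving) continue;
      if (bland) { q = (int)j; break; }
      if (std::fabs(d(j)) > best) { best = std::fabs(d(j)); q = (int)j; }
    }
    if (q < 0) { y_out = y; d_out = d; return 0; } // optimal

    // direction of movement for entering variable
    double sgn = (state(q) == NB_UB) ? -1.0
               : (state(q) == NB_FREE && d(q) < 0) ? -1.0 : 1.0;
    vec w;
    if (!solve(w, B, A.col((uword)q))) return 1;

    // ratio test: how far can x_q move?
    double tmax = INF;
    if (state(q) == NB_LB && std::isfinite(ub(q))) tmax = ub(q) - lb(q);
    if (state(q) == NB_UB && std::isfinite(lb(q))) tmax = ub(q) - lb(q);
    int leave = -1;        // position in basis
    int leave_to = NB_LB;  // which bound the leaving variable hits
    double t = tmax;
    bool entering_flips = std::isfinite(tmax);

    for (uword k = 0; k < m; ++k) {
      double delta = -sgn * w(k);          // rate of change of basic var k
      uword jb = basis(k);
      double lim = INF;
      int to = NB_LB;
      if (delta > ftol) {
        if (std::isfinite(ub(jb))) { lim = (ub(jb) - x(jb)) / delta; to = NB_UB; }
      } else if (delta < -ftol) {
        if (std::isfinite(lb(jb))) { lim = (lb(jb) - x(jb)) / delta; to = NB_LB; }
      } else continue;
      if (lim < -ftol) lim = 0.0;          // numerical: already at bound
      bool better = lim < t - ftol ||
        (lim < t + ftol && leave >= 0 &&
         (bland ? jb < basis((uword)leave)
                : std::fabs(delta) > std::fabs(-sgn * w((uword)leave))));
      if (leave < 0 && lim < t - ftol) better = true;
      if (better) { t = lim; leave = (int)k; leave_to = to; entering_flips = false; }
    }
    if (!std::isfinite(t)) return 2;       // unbounded direction

    if (t < 0) t = 0;
    if (t < ftol) ++degenerate_run; else degenerate_run = 0;
    if (degenerate_run > 60) bland = true;

    // apply step
    x((uword)q) += sgn * t;
    for (uword k = 0; k < m; ++k) x(basis(k)) -= sgn * t * w(k);

    if (entering_flips || leave < 0) {
      // bound flip: entering variable moved to its other bound
      state(q) = (state(q) == NB_LB) ? NB_UB : NB_LB;
      x((uword)q) = (state(q) == NB_LB) ? lb(q) : ub(q);
    } else {
      uword jl = basis((uword)leave);
      state(jl) = leave_to;
      x(jl) = (leave_to == NB_LB) ? lb(jl) : ub(jl);
      basis((uword)leave) = (uword)q;
      state(q) = BASIC;
    }
  }
  return 3;
}

static SimplexResult solve_lp(const mat& A, const vec& b, const vec& c,
                              const vec& lb, const vec& ub, bool maximize,
                              int max_iter) {
  const uword m = A.n_rows, n = A.n_cols;
  const uword N = n + m;
  SimplexResult res;
  res.iterations = 0;

  // quick bound sanity
  for (uword j = 0; j < n; ++j)
    if (lb(j) > ub(j) + 1e-12) { res.status = 1; res.x = zeros(n); res.obj = datum::nan; return res; }

  mat Af(m, N, fill::zeros);
  Af.cols(0, n - 1) = A;
  for (uword i = 0; i < m; ++i) Af(i, n + i) = 1.0;

  vec lbf(N), ubf(N), x(N, fill::zeros);
  ivec state(N);
  for (uword j = 0; j < n; ++j) {
    lbf(j) = lb(j); ubf(j) = ub(j);
    if (std::isfinite(lb(j)) &&
        (!std::isfinite(ub(j)) || std::fabs(lb(j)) <= std::fabs(ub(j)))) {
      x(j) = lb(j); state(j) = NB_LB;
    } else if (std::isfinite(ub(j))) {
      x(j) = ub(j); state(j) = NB_UB;
    } else {
      x(j) = 0.0; state(j) = NB_FREE;
    }
  }
  vec r = b - Af.cols(0, n - 1) * x.subvec(0, n - 1);
  uvec basis(m);
  vec c1(N, fill::zeros);
  for (uword i = 0; i < m; ++i) {
    uword ja = n + i;
    x(ja) = r(i);
    if (r(i) >= 0) { lbf(ja) = 0.0; ubf(ja) = INF; c1(ja) = -1.0; }
    else           { lbf(ja) = -INF; ubf(ja) = 0.0; c1(ja) = 1.0; }
    basis(i) = ja;
    state(ja) = BASIC;
  }

  vec y, d;
  // phase 1
  int st = simplex_iterate(Af, b, c1, lbf, ubf, x, state, basis, y, d,
                           res.iterations, max_iter, 1e-9);
  double infeas = 0.0;
  for (uword i = 0; i < m; ++i) infeas += std::fabs(x(n + i));
  if (st == 3) { res.status = 3; res.x = x.subvec(0, n - 1); res.obj = datum::nan; return res; }
  if (st == 1 || infeas > 1e-7) {
    res.status = 1; res.x = x.subvec(0, n - 1); res.obj = datum::nan; return res;
  }

  // phase 2: pin artificials to zero
  for (uword i = 0; i < m; ++i) { lbf(n + i) = 0.0; ubf(n + i) = 0.0; x(n + i) = 0.0; }
  vec c2(N, fill::zeros);
  for (uword j = 0; j < n; ++j) c2(j) = maximize ? c(j) : -c(j);
  st = simplex_iterate(Af, b, c2, lbf, ubf, x, state, basis, y, d,
                       res.iterations, max_iter, 1e-9);
  if (st == 2) { res.status = 2; res.x = x.subvec(0, n - 1); res.obj = datum::nan; return res; }
  if (st != 0) { res.status = st; res.x = x.subvec(0, n - 1); res.obj = datum::nan; return res; }

  res.status = 0;
  res.x = x.subvec(0, n - 1);
  double obj = dot(c, res.x);
  res.obj = obj;
  res.basis = basis;
  if (maximize) { res.duals = y; res.reduced = d.subvec(0, n - 1); }
  else { res.duals = -y; res.reduced = -d.subvec(0, n - 1); }
  return res;
}

//' @noRd
// [[Rcpp::export(name = ".lp_solve_cpp")]]
Rcpp::List lp_solve_cpp(const arma::mat& A, const arma::vec& b,
                        const arma::vec& c, const arma::vec& lb,
                        const arma::vec& ub, bool maximize,
                        int max_iter = 20000) {
  SimplexResult r = solve_lp(A, b, c, lb, ub, maximize, max_iter);
  std::string status =
    r.status == 0 ? "optimal" :
    r.status == 1 ? "infeasible" :
    r.status == 2 ? "unbounded" : "iteration_limit";
  Rcpp::IntegerVector basis;
  if (r.status == 0) {
    basis = Rcpp::IntegerVector(r.basis.n_elem);
    for (uword k = 0; k < r.basis.n_elem; ++k) basis[k] = (int)r.basis(k) + 1;
  }
  return Rcpp::List::create(
    Rcpp::Named("status") = status,
    Rcpp::Named("x") = r.x,
    Rcpp::Named("objective") = r.obj,
    Rcpp::Named("basis") = basis,
    Rcpp::Named("duals") = (r.status == 0) ? Rcpp::wrap(r.duals) : R_NilValue,
    Rcpp::Named("reduced_costs") = (r.status == 0) ? Rcpp::wrap(r.reduced) : R_NilValue,
    Rcpp::Named("iterations") = r.iterations);
}
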