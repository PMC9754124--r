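#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve  min_a 0.5 a'Qa + q'a   s.t.  a >= 0, sum(a) = 1,
// with Q symmetric positive definite, by a primal active-set method.
// Exact (up to linear-solve roundoff) for strictly convex QPs: at most
// one bound enters or leaves the active set per iteration and the
// objective strictly decreases, so the method terminates.
static vec simplex_qp_one(const mat& Q, const vec& q, const double tol) {
  const uword d = Q.n_rows;
  if (d == 1) return vec(1, fill::ones);

  vec a(d);
  a.fill(1.0 / (double)d);               // feasible start, all coords free
  std::vector<bool> active(d, false);    // true = clamped at zero
  const uword maxit = 6 * d + 60;

  for (uword iter = 0; iter < maxit; ++iter) {
    std::vector<uword> fidx;
    for (uword i = 0; i < d; ++i) if (!active[i]) fidx.push_back(i);
    const uword nf = fidx.size();
    const uvec F = conv_to<uvec>::from(fidx);

    // Equality-constrained KKT system on the free set:
    // [Q_FF 1; 1' 0] [a_F; mu] = [-q_F; 1]
    mat K(nf + 1, nf + 1, fill::zeros);
    K.submat(0, 0, nf - 1, nf - 1) = Q.submat(F, F);
    K.submat(0, nf, nf - 1, nf).ones();
    K.submat(nf, 0, nf, nf - 1).ones();
    vec rhs(nf + 1);
    rhs.head(nf) = -q.elem(F);
    rhs(nf) = 1.0;
    vec sol;
    if (!solve(sol, K, rhs, solve_opts::no_approx)) {
      sol = pinv(K) * rhs;               // numerically singular KKT: fall back
    }
    const vec cand = sol.head(nf);
    const double mu = sol(nf);

    if (cand.min() >= -tol) {
      // candidate feasible: accept, then check duals of the clamped bounds
      a.zeros();
      for (uword j = 0; j < nf; ++j) a(F(j)) = std::max(cand(j), 0.0);
      a /= accu(a);
      const vec g = Q * a + q;
      double worst = -tol;
      sword rel = -1;
      for (uword i = 0; i < d; ++i) {
        if (!active[i]) continue;
        const double nu = g(i) + mu;     // KKT multiplier of bound i
        if (nu < worst) { worst = nu; rel = (sword)i; }
      }
      if (rel < 0) return a;             // all multipliers nonnegative: optimal
      active[(uword)rel] = false;
    } else {
      // partial step from the current point toward the candidate until the
      // first coordinate hits zero; clamp that coordinate
      double alpha = 1.0;
      sword blk = -1;
      for (uword j = 0; j < nf; ++j) {
        const double dir = cand(j) - a(F(j));
        if (dir < -1e-15) {
          const double step = a(F(j)) / (-dir);
          if (step < alpha) { alpha = step; blk = (sword)j; }
        }
      }
      for (uword j = 0; j < nf; ++j)
        a(F(j)) += alpha * (cand(j) - a(F(j)));
      if (blk >= 0) {
        a(F((uword)blk)) = 0.0;
        active[F((uword)blk)] = true;
      }
      // keep the iterate exactly on the simplex
      a.transform([](double v) { return v < 0.0 ? 0.0 : v; });
      a /= accu(a);
    }
  }
  return a;  // iteration budget exhausted: return the current feasible point
}

// Column-wise simplex QP: column i of the result solves
//   min 0.5 a'Qa + Qlin(,i)'a   over the probability simplex.
// [[Rcpp::export(name = ".simplexQPcols")]]
arma::mat simplexQPcols(const arma::mat& Q, const arma::mat& Qlin) {
  const uword d = Q.n_rows, n = Qlin.n_cols;
  if (d == 0) Rcpp::stop("empty dictionary: no reference samples");
  if (Qlin.n_rows != d) Rcpp::stop("Q and Qlin dimensions disagree");
  mat A(d, n);
  const double qscale = abs(Q).max();
  for (uword i = 0; i < n; ++i) {
    const double tol = 1e-10 * (1.0 + qscale + abs(Qlin.col(i)).max());
    A.col(i) = simplex_qp_one(Q, Qlin.col(i), tol);
  }
  return A;
}
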