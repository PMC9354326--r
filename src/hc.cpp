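// Score computation and hill-climbing search.
//
// Node scores are BIC-type and decomposable: Gaussian deviance
// n*log(RSS/n) + |pa|*log(n) for continuous nodes (the raw (RSS/n) fit
// term is available as an alternative form), and logistic deviance
// -2*loglik + |pa|*log(n) for binary nodes. The search keeps per-child
// delta tables so that one accepted move only re-scores the affected
// children, and a transitive-closure matrix so the acyclicity check of a
// candidate move is O(1) (adds) or O(p) (reversals).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PCLIP = 1e-10;     // probability clipping for logs
static const double RSS_REL_FLOOR = 1e-10;  // RSS floor: eps * total SS
static const int IRLS_MAXIT = 25;
static const double IRLS_TOL = 1e-8;
static const double RIDGE = 1e-4;

// warning bits accumulated per scoring call
enum WarnBit { WARN_RSS_FLOOR = 1, WARN_SINGULAR = 2,
               WARN_SEPARATION = 4, WARN_SINGLE_CLASS = 8 };

// ---- continuous node: OLS via the centered cross-product matrix ---------

// C is the p x p centered cross-product of the data; RSS of regressing
// node v on parents P (plus intercept) is C(v,v) - C(v,P) C(P,P)^-1 C(P,v).
static double cont_score(const mat& C, int n, uword v, const uvec& P,
                         int form, int& warn) {
  double tot = C(v, v);
  double rss = tot;
  const uword k = P.n_elem;
  if (k > 0) {
    mat Cpp = C.submat(P, P);
    vec cpv = C.submat(P, uvec{v});
    vec b;
    bool ok = solve(b, Cpp, cpv, solve_opts::no_approx);
    if (!ok) {
      b = pinv(Cpp) * cpv;
      warn |= WARN_SINGULAR;
    }
    rss = tot - dot(cpv, b);
  }
  double fl = std::max(RSS_REL_FLOOR * tot, 1e-100);
  if (rss < fl) {
    rss = fl;
    warn |= WARN_RSS_FLOOR;
  }
  double pen = (double)k * std::log((double)n);
  if (form == 1) return rss / n + pen;
  return n * std::log(rss / n) + pen;
}

// ---- binary node: logistic regression by IRLS ----------------------------

// one IRLS pass; returns true on convergence (max coefficient change below
// IRLS_TOL), false on non-convergence, divergence or a singular system
static bool irls(const mat& D, const vec& y, vec& beta, double ridge,
                 int maxit) {
  const uword q = D.n_cols;
  for (int it = 0; it < maxit; ++it) {
    vec eta = D * beta;
    vec p = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(p % (1.0 - p), 1e-10, datum::inf);
    vec z = eta + (y - p) / w;
    mat M = D.t() * (D.each_col() % w);
    if (ridge > 0) {
      for (uword j = 1; j < q; ++j) M(j, j) += ridge;  // intercept unpenalized
    }
    vec rhs = D.t() * (w % z);
    vec bnew;
    if (!solve(bnew, M, rhs, solve_opts::no_approx)) return false;
    if (!bnew.is_finite()) return false;
    double delta = abs(bnew - beta).max();
    beta = bnew;
    if (delta < IRLS_TOL) return true;
    if (abs(beta).max() > 1e3) return false;  // diverging (separation)
  }
  return false;
}

static double binary_deviance(const vec& y, const vec& p) {
  vec pc = clamp(p, PCLIP, 1.0 - PCLIP);
  return -2.0 * accu(y % log(pc) + (1.0 - y) % log(1.0 - pc));
}

static double logit_score(const mat& X, uword v, const uvec& P, int& warn) {
  const uword n = X.n_rows;
  const uword k = P.n_elem;
  vec y = X.col(v);
  double pen = (double)k * std::log((double)n);
  double m = mean(y);
  if (m <= 0.0 || m >= 1.0) {
    // single-class column (e.g. a degenerate bootstrap resample): score
    // the constant model with clipped probability and flag it
    warn |= WARN_SINGLE_CLASS;
    vec p(n, fill::value(m));
    return binary_deviance(y, p) + pen;
  }
  mat D(n, k + 1);
  D.col(0).ones();
  for (uword j = 0; j < k; ++j) D.col(j + 1) = X.col(P(j));
  vec beta(k + 1, fill::zeros);
  bool ok = (k == 0) ? true : irls(D, y, beta, 0.0, IRLS_MAXIT);
  if (k == 0) {
    // closed form: logit of the sample mean
    beta(0) = std::log(m / (1.0 - m));
  } else if (!ok) {
    // separation or non-convergence: refit with a small ridge penalty on
    // the non-intercept coefficients
    warn |= WARN_SEPARATION;
    beta.zeros();
    irls(D, y, beta, RIDGE, 2 * IRLS_MAXIT);
  }
  vec p = 1.0 / (1.0 + exp(-(D * beta)));
  return binary_deviance(y, p) + pen;
}

// ---- dispatch -------------------------------------------------------------

static double node_score(const mat& X, const mat& C, const ivec& kinds,
                         int n, uword v, const uvec& P, int form, int& warn) {
  if (kinds(v) == 0) return cont_score(C, n, v, P, form, warn);
  return logit_score(X, v, P, warn);
}

// [[Rcpp::export]]
Rcpp::List cpp_score_node(const arma::mat& X, const arma::ivec& kinds,
                          int v1, const arma::uvec& parents1, int form) {
  const int n = X.n_rows;
  uword v = (uword)(v1 - 1);
  uvec P = parents1 - 1;
  mat C;
  if (kinds(v) == 0) {
    // centered cross-product restricted to the needed columns
    uvec cols = join_cols(uvec{v}, P);
    mat Xs = X.cols(cols);
    Xs.each_row() -= mean(Xs, 0);
    mat Cs = Xs.t() * Xs;
    C.zeros(X.n_cols, X.n_cols);
    for (uword a = 0; a < cols.n_elem; ++a)
      for (uword b = 0; b < cols.n_elem; ++b)
        C(cols(a), cols(b)) = Cs(a, b);
  }
  int warn = 0;
  double s = node_score(X, C, kinds, n, v, P, form, warn);
  return Rcpp::List::create(Rcpp::Named("score") = s,
                            Rcpp::Named("warn") = warn);
}

// ---- transitive closure (Warshall) ---------------------------------------

static umat closure(const umat& A) {
  const uword p = A.n_rows;
  umat R = A;
  for (uword k = 0; k < p; ++k)
    for (uword i = 0; i < p; ++i)
      if (R(i, k))
        for (uword j = 0; j < p; ++j)
          if (R(k, j)) R(i, j) = 1;
  return R;
}

// ---- hill climbing --------------------------------------------------------

struct HCState {
  const mat& X;
  mat C;
  const ivec& kinds;
  int n, p, form, max_parents;
  umat A, reach;
  imat white, black;
  vec nodeScore;
  mat dAdd;   // dAdd(u,v): delta of adding u to pa(v); NA when u in pa(v)
  mat dDel;   // dDel(u,v): delta of removing u from pa(v); valid when A(u,v)
  int warn = 0;

  HCState(const mat& X_, const ivec& kinds_, const umat& A0,
          const imat& white_, const imat& black_, int form_, int maxpa_)
      : X(X_), kinds(kinds_), n(X_.n_rows), p(X_.n_cols), form(form_),
        max_parents(maxpa_), A(A0), white(white_), black(black_) {
    if (any(kinds == 0)) {
      mat Xc = X;
      Xc.each_row() -= mean(Xc, 0);
      C = Xc.t() * Xc;
    } else {
      C.zeros(p, p);
    }
    reach = closure(A);
    nodeScore.set_size(p);
    dAdd.set_size(p, p);
    dDel.set_size(p, p);
    dAdd.fill(datum::nan);
    dDel.fill(datum::nan);
    for (int v = 0; v < p; ++v) refresh_child(v);
  }

  double score_of(uword v, const uvec& P) {
    return node_score(X, C, kinds, n, v, P, form, warn);
  }

  // recompute the cached score and delta column of child v
  void refresh_child(uword v) {
    uvec P = find(A.col(v));
    nodeScore(v) = score_of(v, P);
    bool room = (int)P.n_elem < max_parents;  // parent-set size cap
    for (uword u = 0; u < (uword)p; ++u) {
      dAdd(u, v) = datum::nan;
      dDel(u, v) = datum::nan;
      if (u == v) continue;
      if (A(u, v)) {
        uvec Pm = P(find(P != u));
        dDel(u, v) = score_of(v, Pm) - nodeScore(v);
      } else if (room) {
        uvec Pp = join_cols(P, uvec{u});
        dAdd(u, v) = score_of(v, Pp) - nodeScore(v);
      }
    }
  }

  // reversal of u->v is acyclic-safe iff no second directed path u ~> v
  bool reverse_safe(uword u, uword v) const {
    for (uword w = 0; w < (uword)p; ++w)
      if (w != v && A(u, w) && reach(w, v)) return false;
    return true;
  }

  void add_edge_update_reach(uword u, uword v) {
    A(u, v) = 1;
    uvec anc = find(reach.col(u));
    uvec desc = find(reach.row(v).t());
    anc = join_cols(uvec{u}, anc);
    desc = join_cols(uvec{v}, desc);
    for (uword a : anc)
      for (uword b : desc) reach(a, b) = 1;
  }
};

// kind codes in the trace: 0 = add, 1 = delete, 2 = reverse
// [[Rcpp::export]]
Rcpp::List cpp_hc(const arma::mat& X, const arma::ivec& kinds,
                  const arma::umat& A0, const arma::imat& white,
                  const arma::imat& black, int max_steps, double tol,
                  int form, int max_parents) {
  HCState st(X, kinds, A0, white, black, form, max_parents);
  const int p = st.p;
  std::vector<int> tr_kind, tr_from, tr_to;
  std::vector<double> tr_delta, tr_total;
  double total = accu(st.nodeScore);
  bool local_min = false;

  for (int step = 0; step < max_steps; ++step) {
    double best = datum::inf;
    int bkind = -1, bu = -1, bv = -1;
    // candidate scan in deterministic tie-break order:
    // add < delete < reverse, then source index, then target index;
    // strictly-smaller comparison keeps the earliest minimum
    for (int u = 0; u < p; ++u)
      for (int v = 0; v < p; ++v) {
        if (u == v || st.A(u, v) || st.A(v, u)) continue;
        if (st.black(u, v) || st.reach(v, u)) continue;
        double d = st.dAdd(u, v);
        if (d < best) { best = d; bkind = 0; bu = u; bv = v; }
      }
    for (int u = 0; u < p; ++u)
      for (int v = 0; v < p; ++v) {
        if (!st.A(u, v) || st.white(u, v)) continue;
        double d = st.dDel(u, v);
        if (d < best) { best = d; bkind = 1; bu = u; bv = v; }
      }
    for (int u = 0; u < p; ++u)
      for (int v = 0; v < p; ++v) {
        if (!st.A(u, v) || st.white(u, v) || st.black(v, u)) continue;
        double d = st.dAdd(v, u) + st.dDel(u, v);
        if (d < best && st.reverse_safe(u, v)) {
          best = d; bkind = 2; bu = u; bv = v;
        }
      }
    if (bkind < 0 || !(best < -tol)) { local_min = true; break; }

    if (bkind == 0) {
      st.add_edge_update_reach(bu, bv);
      st.refresh_child(bv);
    } else if (bkind == 1) {
      st.A(bu, bv) = 0;
      st.reach = closure(st.A);
      st.refresh_child(bv);
    } else {
      st.A(bu, bv) = 0;
      st.A(bv, bu) = 1;
      st.reach = closure(st.A);
      st.refresh_child(bu);
      st.refresh_child(bv);
    }
    total += best;
    tr_kind.push_back(bkind);
    tr_from.push_back(bu + 1);
    tr_to.push_back(bv + 1);
    tr_delta.push_back(best);
    tr_total.push_back(total);
  }

  return Rcpp::List::create(
      Rcpp::Named("A") = Rcpp::wrap(conv_to<imat>::from(st.A)),
      Rcpp::Named("node_scores") = st.nodeScore,
      Rcpp::Named("total") = accu(st.nodeScore),
      Rcpp::Named("kind") = tr_kind, Rcpp::Named("from") = tr_from,
      Rcpp::Named("to") = tr_to, Rcpp::Named("delta") = tr_delta,
      Rcpp::Named("running_total") = tr_total,
      Rcpp::Named("local_min") = local_min, Rcpp::Named("warn") = st.warn);
}
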