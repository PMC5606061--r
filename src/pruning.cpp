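// Felsenstein-pruning likelihood engine for the finite-sites single-cell model.
// Genotype states: binary {0,1} (k = 2) or ternary {0,1,2} (k = 3).
// Trees use ape's node numbering: tips 1..ntip, root ntip+1.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Qt for a branch of length t: point mutation 0->1 at rate 1, LOH and
// deletion effects through lambda_d, lambda_l.
static arma::mat rate_matrix_t(double t, double lambda_d, double lambda_l, int k) {
  arma::mat Q(k, k, arma::fill::zeros);
  if (k == 3) {
    double s = (lambda_d + lambda_l) * t;
    Q(0, 0) = -t;      Q(0, 1) = t;   Q(0, 2) = 0.0;
    Q(1, 0) = s / 2.0; Q(1, 1) = -s;  Q(1, 2) = s / 2.0;
    Q(2, 0) = 0.0;     Q(2, 1) = lambda_d * t; Q(2, 2) = -lambda_d * t;
  } else {
    double s = (lambda_d + lambda_l) * t / 2.0;
    Q(0, 0) = -t; Q(0, 1) = t;
    Q(1, 0) = s;  Q(1, 1) = -s;
  }
  return Q;
}

// [[Rcpp::export]]
arma::mat cpp_rate_matrix(double t, double lambda_d, double lambda_l, int k) {
  return rate_matrix_t(t, lambda_d, lambda_l, k);
}

// Pade scaling-and-squaring matrix exponential (no eigendecomposition).
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q) {
  return arma::expmat(Q);
}

// Observation probabilities Pr(D = d | G = g) as a k-vector over g.
static arma::vec leaf_partial(int d, double alpha, double beta, int k) {
  arma::vec v(k);
  if (d == NA_INTEGER) { v.ones(); return v; }
  if (k == 2) {
    if (d == 0)      { v(0) = 1.0 - alpha; v(1) = beta; }
    else             { v(0) = alpha;       v(1) = 1.0 - beta; }
  } else {
    if (d == 0)      { v(0) = 1.0 - alpha - alpha * beta / 2.0; v(1) = beta / 2.0; v(2) = 0.0; }
    else if (d == 1) { v(0) = alpha;                            v(1) = 1.0 - beta; v(2) = 0.0; }
    else             { v(0) = alpha * beta / 2.0;               v(1) = beta / 2.0; v(2) = 1.0; }
  }
  return v;
}

// [[Rcpp::export]]
arma::vec cpp_leaf_partial(int d, double alpha, double beta, int k) {
  return leaf_partial(d, alpha, beta, k);
}

// Per-site log-likelihoods log L_i^r(0) over all n sites.
// edge: (2*ntip - 2) x 2 integer matrix, parent/child (ape numbering);
// D: n x ntip observed genotypes with NA for missing, column j = tip j.
// [[Rcpp::export]]
arma::rowvec cpp_site_logliks(const IntegerMatrix& edge,
                              const NumericVector& edge_length,
                              const IntegerMatrix& D,
                              int ntip,
                              double alpha, double beta,
                              double lambda_d, double lambda_l,
                              int k) {
  const int E = edge.nrow();
  const int n = D.nrow();
  const int N = ntip + (E / 2);  // total nodes (rooted binary)
  const int root = ntip + 1;

  // children and incoming edge index per node
  std::vector<std::vector<int>> child_edges(N + 1);
  for (int e = 0; e < E; ++e) child_edges[edge(e, 0)].push_back(e);

  // transition matrix per edge
  std::vector<arma::mat> P(E);
  for (int e = 0; e < E; ++e)
    P[e] = arma::expmat(rate_matrix_t(edge_length[e], lambda_d, lambda_l, k));

  // postorder over internal nodes via explicit stack
  std::vector<int> order;
  order.reserve(N);
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (int e : child_edges[v]) {
      int c = edge(e, 1);
      if (c > ntip) stack.push_back(c);
    }
  }
  std::reverse(order.begin(), order.end());

  std::vector<arma::mat> L(N + 1);
  arma::rowvec logscale(n, arma::fill::zeros);

  // leaf partials: one column per possible observation (0..k-1, missing)
  arma::mat lp(k, k + 1);
  for (int d = 0; d < k; ++d) lp.col(d) = leaf_partial(d, alpha, beta, k);
  lp.col(k).ones();
  for (int j = 1; j <= ntip; ++j) {
    arma::mat Lj(k, n);
    for (int i = 0; i < n; ++i) {
      int d = D(i, j - 1);
      Lj.col(i) = lp.col(d == NA_INTEGER ? k : d);
    }
    L[j] = std::move(Lj);
  }

  for (int v : order) {
    arma::mat Lv(k, n, arma::fill::ones);
    for (int e : child_edges[v]) {
      int c = edge(e, 1);
      Lv %= P[e] * L[c];
      L[c].reset();  // free
    }
    // rescale per site only when close to underflow (matters at large m)
    arma::rowvec cmax = arma::max(Lv, 0);
    if (cmax.min() < 1e-120) {
      for (int i = 0; i < n; ++i) {
        if (cmax(i) > 0.0) {
          Lv.col(i) /= cmax(i);
          logscale(i) += std::log(cmax(i));
        }
      }
    }
    L[v] = std::move(Lv);
  }

  // root conditioned on genotype 0 with probability 1
  arma::rowvec out(n);
  for (int i = 0; i < n; ++i) {
    double l0 = L[root](0, i);
    out(i) = (l0 > 0.0) ? std::log(l0) + logscale(i) : -arma::datum::inf;
  }
  return out;
}
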