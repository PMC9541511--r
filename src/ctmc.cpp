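// Core numerics of the three-state CTMC: transition probabilities by
// matrix exponential, Felsenstein pruning with per-node rescaling, exact
// joint node-state sampling, and endpoint-conditioned path sampling by
// uniformization. Node numbers follow ape's convention (1-based; tips
// first, then internal nodes); state indices are 1-based (NON, FT, SYM).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// exp(Q * t); scaling-and-squaring, safe for defective Q
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) {
  if (t == 0.0) return arma::eye(Q.n_rows, Q.n_cols);
  return arma::expmat(Q * t);
}

// P(t_e) for every edge length; zero-length edges get the identity exactly
// [[Rcpp::export]]
arma::cube cpp_edge_probs(const arma::mat& Q, const arma::vec& len) {
  const arma::uword k = Q.n_rows, E = len.n_elem;
  arma::cube P(k, k, E);
  for (arma::uword e = 0; e < E; ++e) {
    if (len[e] == 0.0) P.slice(e) = arma::eye(k, k);
    else P.slice(e) = arma::expmat(Q * len[e]);
  }
  return P;
}

// Pruning log-likelihood plus per-node conditional likelihoods.
// edgePost: postorder edge matrix (E x 2, columns parent/child, 1-based);
// P: cube of per-edge transition matrices in the same edge order;
// tipLik: nNode x k matrix, tip rows = observation vectors, internal
// rows = 1. Per-node rescaling by the maximum partial likelihood keeps
// deep trees from underflowing; the returned partials are rescaled (only
// within-node ratios are meaningful, which is all joint sampling needs).
// [[Rcpp::export]]
List cpp_prune(const arma::imat& edgePost, const arma::cube& P,
               const arma::mat& tipLik, int root,
               const arma::vec& rootPrior) {
  const arma::uword k = tipLik.n_cols, E = edgePost.n_rows;
  arma::mat L = tipLik;
  double logscale = 0.0;
  bool impossible = false;
  for (arma::uword e = 0; e < E; ++e) {
    const arma::uword p = edgePost(e, 0) - 1, c = edgePost(e, 1) - 1;
    arma::vec v = P.slice(e) * L.row(c).t();
    const double m = v.max();
    if (m <= 0.0) { impossible = true; break; }
    v /= m;
    logscale += std::log(m);
    for (arma::uword s = 0; s < k; ++s) L(p, s) *= v[s];
    // rescale the parent too: with many children products still shrink
    const double mp = L.row(p).max();
    if (mp > 0.0 && mp < 1e-100) {
      L.row(p) /= mp;
      logscale += std::log(mp);
    }
  }
  double ll = R_NegInf;
  if (!impossible) {
    const double rootSum =
      arma::dot(rootPrior, L.row(root - 1).t());
    if (rootSum > 0.0) ll = std::log(rootSum) + logscale;
  }
  // normalize rows for output
  for (arma::uword i = 0; i < L.n_rows; ++i) {
    const double m = L.row(i).max();
    if (m > 0.0) L.row(i) /= m;
  }
  return List::create(_["loglik"] = ll, _["partials"] = L,
                      _["impossible"] = impossible || !R_finite(ll));
}

static int sampleState(const arma::vec& w) {
  const double tot = arma::accu(w);
  if (tot <= 0.0) return -1;
  double u = R::unif_rand() * tot;
  for (arma::uword j = 0; j < w.n_elem; ++j) {
    u -= w[j];
    if (u <= 0.0) return (int)j;
  }
  return (int)(w.n_elem - 1);
}

// Joint draws of node states from their exact conditional distribution
// given all tip data: root ~ rootPrior * L_root, then preorder,
// child ~ P[parentState, .] * L_child. Returns nHist x nNode (1-based
// states). Uses R's RNG so draws respect set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_sample_node_states(const arma::imat& edgePre,
                                     const arma::cube& P,
                                     const arma::mat& partials, int root,
                                     const arma::vec& rootPrior,
                                     int nHist) {
  const arma::uword E = edgePre.n_rows, nNode = partials.n_rows;
  IntegerMatrix out(nHist, (int)nNode);
  arma::vec w(partials.n_cols);
  for (int h = 0; h < nHist; ++h) {
    std::vector<int> st(nNode, -1);
    w = rootPrior % partials.row(root - 1).t();
    int s = sampleState(w);
    if (s < 0) stop("zero normalizer at the root: data impossible under the model");
    st[root - 1] = s;
    for (arma::uword e = 0; e < E; ++e) {
      const arma::uword p = edgePre(e, 0) - 1, c = edgePre(e, 1) - 1;
      const int sp = st[p];
      w = P.slice(e).row(sp).t() % partials.row(c).t();
      s = sampleState(w);
      if (s < 0) stop("zero normalizer at a node: data impossible under the model");
      st[c] = s;
    }
    for (arma::uword i = 0; i < nNode; ++i) out(h, (int)i) = st[i] + 1;
  }
  return out;
}

// One endpoint-conditioned path on [0, t] from state a to state b (0-based
// here), by uniformization: the number of candidate jumps is drawn from
// Poisson(mu t) reweighted by n-step probabilities of the uniformized
// chain R = I + Q/mu, the jump states by backward conditioning on the
// endpoint, jump times as uniform order statistics, and virtual
// (self) jumps discarded. Appends rows (time, from+1, to+1) to ev.
static void samplePathInto(int a, int b, double t, double pab,
                           const arma::cube& Rpow, double mu, double hist,
                           double edge, std::vector<double>& ev) {
  if (mu * t <= 0.0) return;           // no jumps possible
  const int nmax = (int)Rpow.n_slices - 1;
  // draw n | endpoints
  double u = R::unif_rand() * pab;
  double term = std::exp(-mu * t);     // Poisson(0) term
  int n = 0;
  double cum = term * Rpow.slice(0)((arma::uword)a, (arma::uword)b);
  while (cum < u && n < nmax) {
    ++n;
    term *= (mu * t) / n;
    cum += term * Rpow.slice(n)((arma::uword)a, (arma::uword)b);
  }
  if (n == 0) return;
  // jump-chain states by forward sampling conditioned on the endpoint
  arma::vec times(n);
  for (int i = 0; i < n; ++i) times[i] = R::unif_rand() * t;
  times = arma::sort(times);
  int cur = a;
  const arma::mat& R1 = Rpow.slice(1);
  const arma::uword k = R1.n_rows;
  arma::vec w(k);
  for (int i = 1; i <= n; ++i) {
    int nxt;
    if (i == n) nxt = b;
    else {
      const arma::mat& Rrem = Rpow.slice(n - i);
      for (arma::uword j = 0; j < k; ++j)
        w[j] = R1((arma::uword)cur, j) * Rrem(j, (arma::uword)b);
      nxt = sampleState(w);
      if (nxt < 0) stop("endpoint-conditioned sampler hit a zero weight");
    }
    if (nxt != cur) {
      ev.push_back(hist); ev.push_back(edge); ev.push_back(times[i - 1]);
      ev.push_back(cur + 1); ev.push_back(nxt + 1);
      cur = nxt;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_path(int a, int b, double t, const arma::mat& P,
                              const arma::cube& Rpow, double mu) {
  const double pab = P((arma::uword)(a - 1), (arma::uword)(b - 1));
  if (pab <= 0.0) stop("endpoint unreachable: P[a,b](t) = 0");
  std::vector<double> ev;
  samplePathInto(a - 1, b - 1, t, pab, Rpow, mu, 1, 1, ev);
  const int n = (int)ev.size() / 5;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = ev[5 * i + 2];
    out(i, 1) = ev[5 * i + 3];
    out(i, 2) = ev[5 * i + 4];
  }
  return out;
}

// Conditioned paths for every (history, edge) pair given sampled node
// states. Returns a matrix with rows (history, edge, time, from, to).
// [[Rcpp::export]]
NumericMatrix cpp_map_histories(const arma::imat& edgePre,
                                const arma::vec& len, const arma::cube& P,
                                const arma::cube& Rpow, double mu,
                                const IntegerMatrix& nodeStates) {
  const arma::uword E = edgePre.n_rows;
  const int nHist = nodeStates.nrow();
  std::vector<double> ev;
  for (int h = 0; h < nHist; ++h) {
    for (arma::uword e = 0; e < E; ++e) {
      const int a = nodeStates(h, edgePre(e, 0) - 1) - 1;
      const int b = nodeStates(h, edgePre(e, 1) - 1) - 1;
      const double pab =
        P.slice(e)((arma::uword)a, (arma::uword)b);
      if (pab <= 0.0) stop("sampled endpoints unreachable on an edge");
      samplePathInto(a, b, len[e], pab, Rpow, mu, h + 1, e + 1, ev);
    }
  }
  const int n = (int)ev.size() / 5;
  NumericMatrix out(n, 5);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = ev[5 * i + j];
  colnames(out) = CharacterVector::create("history", "edge", "time",
                                          "from", "to");
  return out;
}

// Unconditioned forward simulation of the trait process down the tree:
// exponential waiting times under the current state's exit rate.
// Returns rows (edge, time, from, to); node states are filled in place.
// [[Rcpp::export]]
List cpp_simulate_forward(const arma::imat& edgePre, const arma::vec& len,
                          const arma::mat& Q, int root, int rootState,
                          int nNode) {
  const arma::uword E = edgePre.n_rows, k = Q.n_rows;
  IntegerVector st(nNode, NA_INTEGER);
  st[root - 1] = rootState;
  std::vector<double> ev;
  arma::vec w(k);
  for (arma::uword e = 0; e < E; ++e) {
    const arma::uword p = edgePre(e, 0) - 1, c = edgePre(e, 1) - 1;
    int cur = st[p] - 1;
    double tpos = 0.0;
    for (;;) {
      const double exit = -Q((arma::uword)cur, (arma::uword)cur);
      if (exit <= 0.0) break;                    // absorbing state
      tpos += R::exp_rand() / exit;
      if (tpos >= len[e]) break;
      for (arma::uword j = 0; j < k; ++j)
        w[j] = (j == (arma::uword)cur) ? 0.0 : Q((arma::uword)cur, j);
      const int nxt = sampleState(w);
      ev.push_back((double)(e + 1)); ev.push_back(tpos);
      ev.push_back(cur + 1); ev.push_back(nxt + 1);
      cur = nxt;
    }
    st[c] = cur + 1;
  }
  const int n = (int)ev.size() / 4;
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = ev[4 * i + j];
  colnames(out) = CharacterVector::create("edge", "time", "from", "to");
  return List::create(_["nodeStates"] = st, _["events"] = out);
}
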