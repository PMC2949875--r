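// Mk (multistate) pruning likelihood and Metropolis-Hastings sampler.
// The MCMC inner loop lives here because node-support Bayes factors need
// many fossilized replicate runs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat mk_build_q(const arma::vec& rates, int ns) {
  arma::mat Q(ns, ns, arma::fill::zeros);
  int k = 0;
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) {
      if (i == j) continue;
      Q(i, j) = rates(k++);
    }
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// Felsenstein pruning with per-node rescaling. edge rows are in postorder,
// node ids 0-based, root = ntip. fossil_node/fossil_state are 0-based or -1.
// If Pout/partial_out are non-null the per-edge transition matrices (indexed
// by child node) and unscaled-shape partials are stored for state sampling.
static double mk_prune(const arma::imat& edge, const arma::vec& elen,
                       int ntip, int nnode, const arma::ivec& tipstate,
                       const arma::mat& Q, int fossil_node, int fossil_state,
                       std::vector<arma::mat>* Pout, arma::mat* partial_out) {
  const int ns = Q.n_rows, nn = ntip + nnode, ne = edge.n_rows;
  arma::mat partial(nn, ns, arma::fill::zeros);
  for (int i = 0; i < ntip; ++i) partial(i, tipstate(i)) = 1.0;
  for (int i = ntip; i < nn; ++i) partial.row(i).ones();
  arma::vec logsc(nn, arma::fill::zeros);
  if (Pout) Pout->assign(nn, arma::mat());
  for (int r = 0; r < ne; ++r) {
    int p = edge(r, 0), c = edge(r, 1);
    arma::rowvec pc = partial.row(c);
    if (c == fossil_node) {
      for (int s = 0; s < ns; ++s) if (s != fossil_state) pc(s) = 0.0;
    }
    arma::mat P = arma::expmat(Q * elen(r));
    P.clamp(0.0, arma::datum::inf);
    if (Pout) (*Pout)[c] = P;
    arma::rowvec v = pc * P.t();  // v(i) = sum_j P(i,j) partial(c,j)
    double mx = v.max();
    if (mx <= 0.0) return -arma::datum::inf;
    v /= mx;
    logsc(p) += std::log(mx) + logsc(c);
    partial.row(p) %= v;
  }
  int root = ntip;
  arma::rowvec pr = partial.row(root);
  if (root == fossil_node) {
    for (int s = 0; s < ns; ++s) if (s != fossil_state) pr(s) = 0.0;
  }
  double L = arma::accu(pr) / ns;  // uniform root state frequencies
  if (partial_out) *partial_out = partial;
  if (L <= 0.0) return -arma::datum::inf;
  return std::log(L) + logsc(root);
}

// [[Rcpp::export]]
double cpp_mk_loglik(const arma::imat& edge, const arma::vec& elen,
                     int ntip, int nnode, const arma::ivec& tipstate,
                     const arma::vec& rates, int n_states,
                     int fossil_node, int fossil_state) {
  arma::mat Q = mk_build_q(rates, n_states);
  return mk_prune(edge, elen, ntip, nnode, tipstate, Q,
                  fossil_node, fossil_state, nullptr, nullptr);
}

static double rate_log_prior(const arma::vec& rates, double m) {
  return -((double)rates.n_elem) * std::log(m) - arma::accu(rates) / m;
}

// Draw internal-node states from their joint conditional given the rates.
static arma::ivec sample_node_states(const arma::imat& edge, int ntip, int nnode,
                                     const std::vector<arma::mat>& P,
                                     const arma::mat& partial,
                                     int fossil_node, int fossil_state) {
  const int ns = partial.n_cols, nn = ntip + nnode, ne = edge.n_rows;
  arma::ivec state(nn, arma::fill::value(-1));
  int root = ntip;
  arma::rowvec w = partial.row(root);
  if (root == fossil_node)
    for (int s = 0; s < ns; ++s) if (s != fossil_state) w(s) = 0.0;
  auto draw = [&](arma::rowvec probs) {
    double tot = arma::accu(probs);
    double u = unif_rand() * tot, acc = 0.0;
    for (int s = 0; s < ns; ++s) { acc += probs(s); if (u <= acc) return s; }
    return ns - 1;
  };
  state(root) = draw(w);
  for (int r = ne - 1; r >= 0; --r) {  // reverse postorder = parents first
    int p = edge(r, 0), c = edge(r, 1);
    if (c < ntip) continue;
    arma::rowvec probs(ns);
    for (int s = 0; s < ns; ++s) probs(s) = P[c](state(p), s) * partial(c, s);
    if (c == fossil_node)
      for (int s = 0; s < ns; ++s) if (s != fossil_state) probs(s) = 0.0;
    state(c) = draw(probs);
  }
  return state.subvec(ntip, nn - 1);
}

// [[Rcpp::export]]
List cpp_mk_mcmc(const arma::imat& edge, const arma::vec& elen,
                 int ntip, int nnode, const arma::ivec& tipstate,
                 int n_states, int ngen, int sample_every,
                 double rate_dev, double m_window, double m_max,
                 arma::vec rates, double m,
                 bool update_rates, bool update_m,
                 int fossil_node, int fossil_state) {
  const int nr = rates.n_elem;
  arma::mat Q = mk_build_q(rates, n_states);
  double lnl = mk_prune(edge, elen, ntip, nnode, tipstate, Q,
                        fossil_node, fossil_state, nullptr, nullptr);
  double lpr = rate_log_prior(rates, m);
  int nsamp = ngen / sample_every;
  arma::mat trace(nsamp, 3 + nr);          // gen, lnL, rates..., m
  arma::imat nodes(nsamp, nnode);
  long accepted = 0, proposed = 0;
  int nsaved = 0;
  int npar = (update_rates ? nr : 0) + (update_m ? 1 : 0);
  std::vector<arma::mat> P;
  arma::mat partial;
  for (int gen = 1; gen <= ngen; ++gen) {
    if (npar > 0) {
      int pick = (int)std::floor(unif_rand() * npar);
      if (pick >= npar) pick = npar - 1;
      ++proposed;
      if (update_rates && pick < nr) {
        double old = rates(pick);
        double prop = std::fabs(old + (unif_rand() - 0.5) * rate_dev);
        rates(pick) = prop;
        arma::mat Qn = mk_build_q(rates, n_states);
        double lnl_n = mk_prune(edge, elen, ntip, nnode, tipstate, Qn,
                                fossil_node, fossil_state, nullptr, nullptr);
        double lpr_n = rate_log_prior(rates, m);
        double logr = (lnl_n + lpr_n) - (lnl + lpr);
        if (std::isfinite(lnl_n) && std::log(unif_rand()) < logr) {
          lnl = lnl_n; lpr = lpr_n; Q = Qn; ++accepted;
        } else {
          rates(pick) = old;
        }
      } else {  // hyperprior mean
        double prop = m + (unif_rand() - 0.5) * m_window;
        while (prop < 0.0 || prop > m_max) {
          if (prop < 0.0) prop = -prop;
          if (prop > m_max) prop = 2.0 * m_max - prop;
        }
        if (prop > 1e-12) {
          double lpr_n = rate_log_prior(rates, prop);
          if (std::log(unif_rand()) < lpr_n - lpr) { m = prop; lpr = lpr_n; ++accepted; }
        }
      }
    }
    if (gen % sample_every == 0 && nsaved < nsamp) {
      double check = mk_prune(edge, elen, ntip, nnode, tipstate, Q,
                              fossil_node, fossil_state, &P, &partial);
      trace(nsaved, 0) = gen;
      trace(nsaved, 1) = check;
      for (int i = 0; i < nr; ++i) trace(nsaved, 2 + i) = rates(i);
      trace(nsaved, 2 + nr) = m;
      nodes.row(nsaved) = sample_node_states(edge, ntip, nnode, P, partial,
                                             fossil_node, fossil_state).t();
      ++nsaved;
    }
  }
  return List::create(_["trace"] = trace, _["node_states"] = nodes,
                      _["accepted"] = (double)accepted,
                      _["proposed"] = (double)proposed);
}
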