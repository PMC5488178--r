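// Felsenstein pruning over an arbitrary rooted tree with a finite mixture of
// site classes.  Each (class, edge) pair indexes a precomputed transition
// kernel: kernels are supplied as eigen-systems of reversible generators, and
// each class carries a rate multiplier so gamma-rate and invariant classes
// reuse a single generator.  Per-pattern scaling guards against underflow.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static arma::mat make_pmat(const arma::mat& U, const arma::mat& Uinv,
                           const arma::vec& lambda, double t) {
  arma::vec e = arma::exp(lambda * t);
  arma::mat P = U * arma::diagmat(e) * Uinv;
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return P;
}

// tip_states: ntip x npat (1-based states, 0 = missing)
// edges: nedge x 2 (parent, child), 1-based, in postorder (child rows first)
// eig: list of eigen-systems list(U, Uinv, lambda)
// kernel_mat / kernel_rate: for kernel k, generator index (1-based into eig)
//   and rate multiplier; trans_index: nclass x nedge, 1-based kernel id
// class_props: mixture weights; root_freq: equilibrium frequencies
// [[Rcpp::export]]
List prune_loglik_cpp(const arma::imat& tip_states,
                      const arma::vec& weights,
                      const arma::imat& edges,
                      int n_nodes,
                      int root,
                      const arma::vec& edge_len,
                      const List& eig,
                      const arma::ivec& kernel_mat,
                      const arma::vec& kernel_rate,
                      const arma::imat& trans_index,
                      const arma::vec& class_props,
                      const arma::vec& root_freq,
                      bool site_values) {
  const int ntip  = tip_states.n_rows;
  const int npat  = tip_states.n_cols;
  const int nedge = edges.n_rows;
  const int nclass = class_props.n_elem;
  const int ns = root_freq.n_elem;
  const int nkern = kernel_mat.n_elem;

  // precompute transition matrices per (kernel, edge)
  std::vector<arma::mat> U(eig.size()), Uinv(eig.size());
  std::vector<arma::vec> lam(eig.size());
  for (int m = 0; m < (int)eig.size(); ++m) {
    List em = eig[m];
    U[m]    = as<arma::mat>(em["U"]);
    Uinv[m] = as<arma::mat>(em["Uinv"]);
    lam[m]  = as<arma::vec>(em["lambda"]);
  }
  // which kernels are actually used on which edges
  std::vector<arma::mat> P(nkern * nedge);
  std::vector<bool> need(nkern * nedge, false);
  for (int c = 0; c < nclass; ++c)
    for (int e = 0; e < nedge; ++e)
      need[(trans_index(c, e) - 1) * nedge + e] = true;
  for (int k = 0; k < nkern; ++k) {
    int m = kernel_mat(k) - 1;
    for (int e = 0; e < nedge; ++e) {
      if (!need[k * nedge + e]) continue;
      double t = edge_len(e) * kernel_rate(k);
      P[k * nedge + e] = make_pmat(U[m], Uinv[m], lam[m], t);
    }
  }

  arma::mat class_loglik(npat, nclass);
  std::vector<arma::mat> node_partial(n_nodes);
  arma::vec logscale(npat);
  arma::vec ones_col(ns, arma::fill::ones);

  for (int c = 0; c < nclass; ++c) {
    logscale.zeros();
    for (int n = ntip; n < n_nodes; ++n) node_partial[n].reset();
    for (int e = 0; e < nedge; ++e) {
      int pa = edges(e, 0) - 1, ch = edges(e, 1) - 1;
      int k = trans_index(c, e) - 1;
      const arma::mat& Pe = P[k * nedge + e];
      arma::mat contrib(ns, npat);
      if (ch < ntip) {
        // tip partials are unit vectors: gather columns of P
        for (int p = 0; p < npat; ++p) {
          int s = tip_states(ch, p);
          if (s == 0) contrib.col(p) = ones_col;
          else contrib.col(p) = Pe.col(s - 1);
        }
      } else {
        contrib = Pe * node_partial[ch];
        // rescale per pattern when magnitudes shrink
        arma::rowvec mx = arma::max(contrib, 0);
        if (mx.min() < 1e-6) {
          for (int p = 0; p < npat; ++p) {
            double m = mx(p);
            if (m <= 0) m = 1e-300;
            contrib.col(p) /= m;
            logscale(p) += std::log(m);
          }
        }
      }
      if (node_partial[pa].is_empty())
        node_partial[pa] = std::move(contrib);
      else
        node_partial[pa] %= contrib;
    }
    arma::rowvec rl = root_freq.t() * node_partial[root - 1];
    for (int p = 0; p < npat; ++p)
      class_loglik(p, c) = std::log(std::max(rl(p), 1e-300)) + logscale(p);
  }

  // mixture via log-sum-exp
  arma::vec lp = arma::log(class_props);
  arma::vec site_ll(npat);
  arma::mat post;
  if (site_values) post.set_size(npat, nclass);
  double total = 0.0;
  for (int p = 0; p < npat; ++p) {
    double mx = -arma::datum::inf;
    for (int c = 0; c < nclass; ++c)
      mx = std::max(mx, class_loglik(p, c) + lp(c));
    double s = 0.0;
    for (int c = 0; c < nclass; ++c)
      s += std::exp(class_loglik(p, c) + lp(c) - mx);
    site_ll(p) = mx + std::log(s);
    total += weights(p) * site_ll(p);
    if (site_values)
      for (int c = 0; c < nclass; ++c)
        post(p, c) = std::exp(class_loglik(p, c) + lp(c) - site_ll(p));
  }

  if (site_values)
    return List::create(_["loglik"] = total, _["site_loglik"] = site_ll,
                        _["class_posterior"] = post);
  return List::create(_["loglik"] = total);
}
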