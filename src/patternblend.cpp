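#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Brute-force k-nearest-neighbour search for moderate point clouds
// (n up to ~60k). Returns 1-based neighbour indices and distances.
// [[Rcpp::export(name = ".knn_brute")]]
List knn_brute(const arma::mat& pts, const int k) {
  const int n = pts.n_rows;
  if (k >= n) stop("k must be smaller than the number of points");
  arma::imat idx(n, k);
  arma::mat dist(n, k);
  for (int i = 0; i < n; ++i) {
    arma::vec d2 = arma::sum(arma::square(pts.each_row() - pts.row(i)), 1);
    d2(i) = arma::datum::inf;
    arma::uvec ord = arma::sort_index(d2);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = static_cast<int>(ord(j)) + 1;
      dist(i, j) = std::sqrt(d2(ord(j)));
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Felsenstein pruning log-likelihood for a discrete-state CTMC on a rooted
// tree. Edges must be supplied in postorder (children before parents).
// tip_states: 1-based state index per tip, 0 = ambiguous (all states).
// Transition matrices come from a one-off eigendecomposition of Q
// (P(t) = V exp(D t) V^-1), falling back to a Pade expmat per branch when
// the eigenvector matrix is ill-conditioned.
// [[Rcpp::export(name = ".ctmc_loglik_cpp")]]
double ctmc_loglik_cpp(const arma::imat& edge, const arma::vec& edge_length,
                       const int n_tips, const arma::ivec& tip_states,
                       const arma::mat& Q, const arma::vec& root_prior) {
  const int ns = Q.n_rows;

  arma::cx_vec eval;
  arma::cx_mat evec, evec_inv;
  bool use_eig = arma::eig_gen(eval, evec, Q);
  if (use_eig) {
    use_eig = arma::rcond(evec) > 1e-10 && arma::inv(evec_inv, evec);
  }
  auto trans_mat = [&](double t) -> arma::mat {
    if (use_eig) {
      arma::cx_mat P = evec * arma::diagmat(arma::exp(eval * t)) * evec_inv;
      arma::mat Pr = arma::real(P);
      Pr.elem(arma::find(Pr < 0)).zeros();
      return Pr;
    }
    return arma::expmat(Q * t);
  };
  const int n_nodes = edge.max();
  arma::mat partial(ns, n_nodes, arma::fill::ones);
  std::vector<bool> seen(n_nodes, false);
  double logscale = 0.0;

  for (int t = 0; t < n_tips; ++t) {
    if (tip_states(t) > 0) {
      partial.col(t).zeros();
      partial(tip_states(t) - 1, t) = 1.0;
    }
    seen[t] = true;
  }
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    if (!seen[child]) stop("edges are not in postorder");
    arma::mat P = trans_mat(edge_length(e));
    arma::vec contrib = P * partial.col(child);
    if (!seen[parent]) { partial.col(parent).ones(); seen[parent] = true; }
    partial.col(parent) %= contrib;
    double mx = partial.col(parent).max();
    if (mx > 0 && mx < 1e-280) {
      partial.col(parent) /= mx;
      logscale += std::log(mx);
    }
  }
  const int root = edge(edge.n_rows - 1, 0) - 1;
  double lik = arma::dot(root_prior, partial.col(root));
  if (lik <= 0.0 || !std::isfinite(lik)) return -arma::datum::inf;
  return std::log(lik) + logscale;
}
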