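#include <Rcpp.h>
#include <vector>
#include <deque>
using namespace Rcpp;

// Brandes betweenness for an undirected, unweighted simple graph given as a
// 0/1 adjacency matrix. Scores are pair fractions over unordered pairs:
// score(v) = sum_{s != v != t} sigma_st(v) / sigma_st.
// [[Rcpp::export(name = ".betweenness_scores")]]
NumericVector betweenness_scores(IntegerMatrix adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) nbr[i].push_back(j);

  NumericVector bc(n);
  std::vector<int> stack_order;
  stack_order.reserve(n);
  std::vector<std::vector<int>> pred(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> dist(n);

  for (int s = 0; s < n; ++s) {
    stack_order.clear();
    for (int i = 0; i < n; ++i) {
      pred[i].clear();
      sigma[i] = 0.0;
      dist[i] = -1;
    }
    sigma[s] = 1.0;
    dist[s] = 0;
    std::deque<int> queue{s};
    while (!queue.empty()) {
      int v = queue.front();
      queue.pop_front();
      stack_order.push_back(v);
      for (int w : nbr[v]) {
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          queue.push_back(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = (int)stack_order.size() - 1; i >= 0; --i) {
      int w = stack_order[i];
      for (int v : pred[w])
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  // each unordered pair was accumulated from both endpoints
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}

// Dominant-eigenvector centrality by power iteration on A + I, run per
// connected component. The identity shift leaves eigenvectors untouched but
// makes A + I primitive on each connected component, so the iteration
// converges there even for bipartite structure; iterating per component
// avoids the arbitrarily slow mixing that near-tied spectral radii of
// *different* components would cause on the whole graph. The component with
// the largest spectral radius carries the dominant eigenvector (exact ties
// broken by lowest node index); every other node scores 0. Scores are
// non-negative, normalised to unit Euclidean length; an edgeless graph
// scores all zeros.
// Convergence is declared when the max entrywise change drops below `tol`.
// A component whose spectral gap is tiny mixes too slowly for that; after
// `max_iter` iterations the iterate is accepted anyway if its eigen-residual
// ||(A+I)x - lambda x||_inf < 1e-6 * lambda, i.e. it is numerically an
// eigenvector to the precision the signals can resolve. Anything worse is a
// convergence error.
// [[Rcpp::export(name = ".eigenvector_scores")]]
NumericVector eigenvector_scores(IntegerMatrix adj, double tol = 1e-8,
                                 int max_iter = 200000) {
  const int n = adj.nrow();
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) nbr[i].push_back(j);

  std::vector<int> comp(n, -1);
  int n_comp = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0 || nbr[s].empty()) continue;  // isolated nodes score 0
    comp[s] = n_comp;
    std::deque<int> queue{s};
    while (!queue.empty()) {
      int v = queue.front();
      queue.pop_front();
      for (int w : nbr[v])
        if (comp[w] < 0) { comp[w] = n_comp; queue.push_back(w); }
    }
    ++n_comp;
  }
  if (n_comp == 0) return NumericVector(n);  // no edges at all

  double best_lambda = -1.0;
  std::vector<double> best_vec;
  std::vector<int> best_nodes;
  for (int c = 0; c < n_comp; ++c) {
    std::vector<int> nodes;
    for (int i = 0; i < n; ++i)
      if (comp[i] == c) nodes.push_back(i);
    const int m = (int)nodes.size();
    std::vector<int> local(n, -1);
    for (int i = 0; i < m; ++i) local[nodes[i]] = i;

    std::vector<double> x(m, 1.0 / std::sqrt((double)m)), y(m);
    double lambda = 0.0;
    bool converged = false;
    for (int iter = 0; iter < max_iter && !converged; ++iter) {
      for (int i = 0; i < m; ++i) {
        double acc = x[i];  // the +I shift
        for (int j : nbr[nodes[i]]) acc += x[local[j]];
        y[i] = acc;
      }
      double norm = 0.0;
      for (int i = 0; i < m; ++i) norm += y[i] * y[i];
      norm = std::sqrt(norm);
      double diff = 0.0;
      for (int i = 0; i < m; ++i) {
        y[i] /= norm;
        double d = std::fabs(y[i] - x[i]);
        if (d > diff) diff = d;
        x[i] = y[i];
      }
      lambda = norm - 1.0;  // spectral radius of A restricted to the component
      converged = diff < tol;
    }
    if (!converged) {
      // near-degenerate gap: accept if the iterate is an eigenvector to
      // within the precision that matters downstream
      double resid = 0.0;
      for (int i = 0; i < m; ++i) {
        double acc = x[i];
        for (int j : nbr[nodes[i]]) acc += x[local[j]];
        double d = std::fabs(acc - (lambda + 1.0) * x[i]);
        if (d > resid) resid = d;
      }
      if (resid >= 1e-6 * (lambda + 1.0))
        stop("eigenvector centrality: power iteration did not converge within %d iterations",
             max_iter);
    }
    if (lambda > best_lambda + 1e-12) {
      best_lambda = lambda;
      best_vec = x;
      best_nodes = nodes;
    }
  }

  NumericVector out(n);
  for (size_t i = 0; i < best_nodes.size(); ++i)
    out[best_nodes[i]] = best_vec[i] < 0 ? 0.0 : best_vec[i];
  return out;
}
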