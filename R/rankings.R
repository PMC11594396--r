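#' Degree centrality table
#'
#' Raw neighbour counts per node together with their network average.
#' Because public signals only compare each node with the average, any fixed
#' positive rescaling would be behaviour-preserving; raw degree is used so
#' logged tables are immediately interpretable.
#'
#' @param state A [population_state()].
#' @return An object of class `ranking_table`: list with numeric `score`
#'   (one per node) and `average` (their arithmetic mean).
#' @export
degree_centrality <- function(state) {
  new_ranking_table(as.numeric(rowSums(state$adj)))
}

#' Betweenness centrality table
#'
#' Shortest-path pair counting (Brandes' algorithm): node `v` scores the sum
#' over unordered pairs `s != v != t` of the fraction of shortest `s`-`t`
#' paths passing through `v`. Measures the traversability a node offers.
#'
#' @param state A [population_state()].
#' @return A `ranking_table`.
#' @export
betweenness_centrality <- function(state) {
  new_ranking_table(.betweenness_scores(state$adj))
}

#' Eigenvector centrality table
#'
#' Entrywise non-negative dominant eigenvector of the adjacency matrix,
#' normalised to unit Euclidean length — a node's social capital counts not
#' just its own connections but those of its neighbours. Computed by power
#' iteration run per connected component on the identity-shifted adjacency,
#' which is primitive there, so bipartite structure and near-tied spectral
#' radii of other components cannot stall it; on a disconnected graph the
#' component with the largest spectral radius carries the scores and every
#' other node scores zero.
#'
#' @param state A [population_state()].
#' @param tol Convergence tolerance on the max absolute entry change.
#' @param max_iter Iteration cap; a component that has not met `tol` by then
#'   is accepted only if its iterate is an eigenvector to within `1e-6`
#'   (near-degenerate spectral gap), otherwise a convergence error is raised.
#' @return A `ranking_table`.
#' @export
eigenvector_centrality <- function(state, tol = 1e-8, max_iter = 200000L) {
  new_ranking_table(.eigenvector_scores(state$adj, tol, max_iter))
}

new_ranking_table <- function(score) {
  structure(list(score = score, average = mean(score)),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("Ranking table over %d nodes; network average %.6g\n",
              length(x$score), x$average))
  invisible(x)
}

#' Compute the ranking table a given public-information method consults
#'
#' Dispatches to the centrality the method is based on. The RANDOM method
#' consults no centrality; it receives an all-zero placeholder table so the
#' step driver can treat every method uniformly.
#'
#' @param state A [population_state()].
#' @param method One of [RANKING_METHODS].
#' @return A `ranking_table`.
#' @export
ranking_table <- function(state, method) {
  method <- match_ranking_method(method)
  switch(substr(method, 1L, 3L),
         DEG = degree_centrality(state),
         BET = betweenness_centrality(state),
         EIG = eigenvector_centrality(state),
         RAN = new_ranking_table(numeric(population_size(state))))
}

#' Public-information indication for a candidate
#'
#' HI variants endorse a candidate whose score strictly exceeds the network
#' average; LO variants one whose score falls strictly below it. A score
#' exactly equal to the average is endorsed by neither (relevant on regular
#' graphs, where every HI and LO signal is negative). The RANDOM method
#' endorses independently with probability `rc`, consuming one uniform
#' deviate per evaluation.
#'
#' @param method One of [RANKING_METHODS].
#' @param candidate Node index of the candidate (ignored for RANDOM).
#' @param table The current `ranking_table` for `method`.
#' @param rc Endorsement probability of the RANDOM method (default 0.8).
#' @return Logical indication.
#' @examples
#' st <- population_state(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
#'                        rep(TRUE, 3))
#' tb <- degree_centrality(st)
#' public_signal("DEG_HI", 2, tb)  # centre of the path: degree 2 > 4/3
#' @export
public_signal <- function(method, candidate, table, rc = 0.8) {
  method <- match_ranking_method(method)
  if (method == "RANDOM") return(stats::runif(1) < rc)
  if (!is.numeric(candidate) || length(candidate) != 1L || is.na(candidate) ||
      candidate < 1L || candidate > length(table$score)) {
    stop("candidate ", candidate, " not present in the ranking table")
  }
  s <- table$score[candidate]
  if (endsWith(method, "HI")) s > table$average else s < table$average
}
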