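# Independent oracles and small-fixture builders used across the suite.

# random simple undirected graph as a population state
random_state <- function(n, p_edge = 0.4, coop_prob = 0.5) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p_edge)
  a <- a + t(a)
  population_state(a, runif(n) < coop_prob)
}

state_from_edges <- function(n, edges, coop = rep(TRUE, n)) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  population_state(a, coop)
}

# payoff oracle: re-sum the prisoner's-dilemma payoff matrix edge by edge
# (C,C) -> (b-c, b-c); (C,D) -> (-c, b); (D,D) -> (0, 0)
brute_payoffs <- function(state, params) {
  n <- population_size(state)
  pay <- numeric(n)
  el <- edge_list(state)
  for (r in seq_len(nrow(el))) {
    u <- el[r, 1]; v <- el[r, 2]
    cu <- state$coop[u]; cv <- state$coop[v]
    if (cu && cv) {
      pay[u] <- pay[u] + params$b - params$c
      pay[v] <- pay[v] + params$b - params$c
    } else if (cu && !cv) {
      pay[u] <- pay[u] - params$c
      pay[v] <- pay[v] + params$b
    } else if (!cu && cv) {
      pay[u] <- pay[u] + params$b
      pay[v] <- pay[v] - params$c
    }
  }
  pay
}

# betweenness oracle: exhaustive enumeration of all simple paths per pair,
# keep the shortest ones, credit intermediate nodes their pair fraction
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- list()
      walk <- function(v, visited) {
        if (v == t) {
          paths[[length(paths) + 1]] <<- visited
          return(invisible(NULL))
        }
        for (w in which(adj[v, ] == 1L)) {
          if (!(w %in% visited)) walk(w, c(visited, w))
        }
      }
      walk(s, s)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      inner <- setdiff(seq_len(n), c(s, t))
      for (v in inner) {
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        if (through > 0) bc[v] <- bc[v] + through / sigma
      }
    }
  }
  bc
}

# eigenvector oracle: dense symmetric eigendecomposition; also reports the
# spectral gap so degenerate (tied) dominant eigenspaces can be excluded
dense_eigenvector <- function(adj) {
  ev <- eigen(adj, symmetric = TRUE)
  list(score = abs(ev$vectors[, 1]),
       gap = ev$values[1] - ev$values[2])
}

expect_within_binomial_se <- function(phat, p0, n_draws, k_se = 3) {
  se <- sqrt(p0 * (1 - p0) / n_draws)
  expect_lt(abs(phat - p0), max(k_se * se, 1e-12))
}
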