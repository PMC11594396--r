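#' Payoff of a single node
#'
#' A cooperator with `K` cooperating and `J` defecting neighbours earns
#' `K*(b - c) - J*c`: it pays the cost `c` for every neighbour but receives
#' the benefit `b` only from cooperating ones. A defector earns `K*b`: it
#' harvests the benefit from each cooperating neighbour and pays nothing.
#' Isolated nodes earn 0. Payoffs are stateless: they are a pure function of
#' the current graph and strategies, recomputed whenever needed.
#'
#' @param state A [population_state()].
#' @param node Node index in `1..N`.
#' @param params A [game_params()].
#' @return The node's payoff (a single number).
#' @examples
#' st <- population_state(rbind(c(0, 1), c(1, 0)), c(TRUE, FALSE))
#' node_payoff(st, 1, game_params())  # exploited cooperator: -8
#' node_payoff(st, 2, game_params())  # defector harvesting: 9
#' @export
node_payoff <- function(state, node, params) {
  n <- population_size(state)
  if (!is.numeric(node) || length(node) != 1L || is.na(node) ||
      node != as.integer(node) || node < 1L || node > n) {
    stop("unknown node id '", node, "' (population has ", n, " nodes)")
  }
  nbr <- state$adj[, node] == 1L
  k <- sum(state$coop[nbr])
  j <- sum(nbr) - k
  if (state$coop[node]) k * (params$b - params$c) - j * params$c else k * params$b
}

#' Payoffs of every node
#'
#' Vectorised equivalent of [node_payoff()] applied to each node of the
#' current graph.
#'
#' @inheritParams node_payoff
#' @return Numeric vector of payoffs, one per node.
#' @export
all_payoffs <- function(state, params) {
  k <- as.vector(state$adj %*% state$coop)      # cooperating neighbours
  deg <- rowSums(state$adj)
  j <- deg - k                                  # defecting neighbours
  ifelse(state$coop, k * (params$b - params$c) - j * params$c, k * params$b)
}

#' Fitness from payoff
#'
#' Maps payoff `P` to fitness `(1 + delta)^P`. The exponential form keeps
#' fitness strictly positive for the negative payoffs an exploited cooperator
#' accrues, which fitness-proportional role-model selection requires, and is
#' strictly increasing in `P` whenever `delta > 0` (constant 1 at
#' `delta = 0`, i.e. neutral drift).
#'
#' @param payoff Numeric payoff(s).
#' @param params A [game_params()] supplying `delta`.
#' @return Fitness value(s), strictly positive.
#' @examples
#' fitness(0, game_params())       # 1
#' fitness(10, game_params())      # 1.01^10
#' @export
fitness <- function(payoff, params) {
  (1 + params$delta)^payoff
}

#' Normalised payoff ratio
#'
#' Payoff divided by the maximum a cooperator could earn: being connected to
#' all `N - 1` others with everyone cooperating, i.e. `(N - 1) * (b - c)`.
#'
#' @param payoff Numeric payoff(s).
#' @param n Population size, at least 2.
#' @param params A [game_params()].
#' @return Payoff ratio(s); 1 for a maximally connected all-cooperator node.
#' @export
payoff_ratio <- function(payoff, n, params) {
  stopifnot(n >= 2)
  payoff / ((n - 1) * (params$b - params$c))
}
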