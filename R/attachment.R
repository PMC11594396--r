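#' Fitness-proportional role-model selection
#'
#' Roulette-wheel draw: node `i` is selected with probability
#' `f_i / sum_j f_j`. With the exponential payoff-to-fitness map every
#' weight is strictly positive, so the draw is always well defined; under
#' weak selection (`delta` small) high-payoff nodes are only mildly favoured.
#'
#' @param fitness Numeric vector of strictly positive fitness values, one
#'   per node.
#' @return The selected node index, consuming one deviate from the RNG
#'   stream.
#' @export
select_role_model <- function(fitness) {
  if (any(!is.finite(fitness)) || any(fitness <= 0)) {
    stop("role-model selection requires strictly positive finite fitness values")
  }
  sample.int(length(fitness), 1L, prob = fitness)
}

#' Fuse public and private indications into a connection decision
#'
#' The four-case rule: agreement is decisive (both positive connects, both
#' negative rejects); a public-only indication connects with probability
#' `p`, a private-only indication with probability `q`. Each mixed case
#' consumes one uniform deviate; the decisive cases consume none.
#'
#' @param public_sig Logical public-information indication.
#' @param private_sig Logical private-information indication.
#' @param weights An [info_weights()].
#' @return Logical: form the connection?
#' @export
decide_connection <- function(public_sig, private_sig, weights) {
  if (public_sig && private_sig) return(TRUE)
  if (!public_sig && !private_sig) return(FALSE)
  thr <- if (public_sig) weights$p else weights$q
  stats::runif(1) < thr
}

#' Integrate one newcomer (a single simulation step)
#'
#' Executes, in a fixed order that makes trials reproducible under a seeded
#' RNG stream:
#' \enumerate{
#'   \item a role model is drawn fitness-proportionally from the current
#'     payoffs;
#'   \item the newcomer adopts the role model's strategy;
#'   \item each candidate — the role model and its neighbours, visited in
#'     increasing node order — gets one private perception draw, then one
#'     connection decision fusing it with the candidate's public signal
#'     (rankings were computed at the end of the previous step; the
#'     newcomer itself has no score and is never a candidate);
#'   \item the newcomer joins with the accepted edges;
#'   \item one incumbent, chosen uniformly (the role model included, the
#'     newcomer excluded), is removed with all its edges — the Moran
#'     replacement that keeps the population size at `N`. If the removed
#'     incumbent was one the newcomer just attached to, that edge is lost.
#' }
#' The newcomer takes over the removed incumbent's node slot.
#'
#' @param state A [population_state()] with `N` nodes.
#' @param table The `ranking_table` for `method` computed on `state`.
#' @param game A [game_params()].
#' @param perc A [perception_params()].
#' @param weights An [info_weights()].
#' @param method One of [RANKING_METHODS].
#' @param rc Endorsement probability for the RANDOM method.
#' @return A list with the updated `state` and a `record` (list: `role_model`,
#'   `adopted_cooperator`, `candidates`, `connections_formed`,
#'   `replaced_node`).
#' @export
integrate_newcomer <- function(state, table, game, perc, weights, method,
                               rc = 0.8) {
  method <- match_ranking_method(method)
  n <- population_size(state)
  if (length(table$score) != n) {
    stop("ranking table covers ", length(table$score),
         " nodes but the population has ", n)
  }

  f <- fitness(all_payoffs(state, game), game)
  role <- select_role_model(f)
  adopts <- state$coop[role]

  candidates <- sort(unique(c(role, which(state$adj[, role] == 1L))))

  samples <- sample_perception(state$coop[candidates], perc)
  priv <- private_signal(samples, perc)

  accept <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    pub <- public_signal(method, candidates[i], table, rc)
    accept[i] <- decide_connection(pub, priv[i], weights)
  }
  formed <- candidates[accept]

  victim <- sample.int(n, 1L)

  # newcomer takes the victim's slot; an accepted edge to the victim is lost
  adj <- state$adj
  adj[victim, ] <- 0L
  adj[, victim] <- 0L
  keep <- formed[formed != victim]
  adj[victim, keep] <- 1L
  adj[keep, victim] <- 1L
  coop <- state$coop
  coop[victim] <- adopts

  list(
    state = structure(list(adj = adj, coop = coop), class = "netcoop_state"),
    record = list(role_model = role,
                  adopted_cooperator = adopts,
                  candidates = candidates,
                  connections_formed = formed,
                  replaced_node = victim)
  )
}
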