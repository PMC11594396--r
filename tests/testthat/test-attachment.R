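test_that("role-model selection is fitness-proportional", {
  set.seed(401)
  # equal fitness: uniform over nodes
  n_draw <- 4e4
  draws <- vapply(seq_len(n_draw), function(i) select_role_model(rep(1, 5)),
                  integer(1))
  freq <- tabulate(draws, 5) / n_draw
  for (k in 1:5) expect_within_binomial_se(freq[k], 0.2, n_draw)

  # two nodes, payoffs 0 and 10 at delta = 0.01
  gp <- game_params()
  f <- fitness(c(0, 10), gp)
  p2 <- f[2] / sum(f)
  expect_equal(p2, 1.01^10 / (1 + 1.01^10))
  draws <- vapply(seq_len(n_draw), function(i) select_role_model(f), integer(1))
  expect_within_binomial_se(mean(draws == 2L), p2, n_draw)

  expect_error(select_role_model(c(1, 0)), "strictly positive")
})

test_that("the four-case decision rule has frequencies (1, 0, p, q)", {
  set.seed(402)
  n <- 2e4
  for (pv in c(0.25, 0.75)) {
    for (qv in c(0.25, 0.75)) {
      w <- info_weights(pv, qv)
      expect_true(all(vapply(1:50, function(i)
        decide_connection(TRUE, TRUE, w), logical(1))))
      expect_false(any(vapply(1:50, function(i)
        decide_connection(FALSE, FALSE, w), logical(1))))
      pub_only <- mean(vapply(seq_len(n), function(i)
        decide_connection(TRUE, FALSE, w), logical(1)))
      prv_only <- mean(vapply(seq_len(n), function(i)
        decide_connection(FALSE, TRUE, w), logical(1)))
      expect_within_binomial_se(pub_only, pv, n)
      expect_within_binomial_se(prv_only, qv, n)
    }
  }
})

test_that("an isolated role-model is the only candidate", {
  set.seed(403)
  st <- state_from_edges(4, list(c(2, 3), c(2, 4), c(3, 4)))
  # node 1 isolated; force its selection by neutral drift retries
  repeat {
    res <- integrate_newcomer(st, degree_centrality(st), game_params(),
                              perception_params(), info_weights(), "DEG_HI")
    if (res$record$role_model == 1L) break
  }
  expect_identical(res$record$candidates, 1L)
})

test_that("all-negative decisions leave the newcomer isolated but still replace", {
  set.seed(404)
  st <- random_state(10, p_edge = 0.5, coop_prob = 1)
  res <- integrate_newcomer(st, degree_centrality(st), game_params(),
                            perception_params(tau = -10),  # private never fires
                            info_weights(p = 0, q = 0), "DEG_HI")
  expect_length(res$record$connections_formed, 0)
  slot <- res$record$replaced_node
  expect_equal(sum(res$state$adj[slot, ]), 0)
  expect_equal(population_size(res$state), 10)
})

test_that("forced-positive signals connect the newcomer to the whole closed neighbourhood", {
  set.seed(405)
  st <- random_state(10, p_edge = 0.5, coop_prob = 1)
  res <- integrate_newcomer(st, degree_centrality(st), game_params(),
                            perception_params(tau = 10),  # private always fires
                            info_weights(p = 1, q = 1), "DEG_HI")
  role <- res$record$role_model
  closed_nbhd <- sort(unique(c(role, which(st$adj[, role] == 1L))))
  expect_identical(res$record$candidates, closed_nbhd)
  expect_identical(res$record$connections_formed, closed_nbhd)
  # newcomer degree: every accepted edge except a lost one to the victim
  slot <- res$record$replaced_node
  expected_deg <- length(setdiff(closed_nbhd, slot))
  expect_equal(sum(res$state$adj[slot, ]), expected_deg)
})

test_that("steps conserve population size and graph simplicity", {
  set.seed(406)
  st <- random_state(20, p_edge = 0.3, coop_prob = 0.7)
  tb <- degree_centrality(st)
  for (i in 1:200) {
    res <- integrate_newcomer(st, tb, game_params(), perception_params(tau = 0.5),
                              info_weights(0.5, 0.5), "DEG_HI")
    st <- res$state
    tb <- degree_centrality(st)
    expect_true(all(res$record$connections_formed %in% res$record$candidates))
  }
  expect_equal(population_size(st), 20)
  expect_identical(st$adj, t(st$adj))
  expect_true(all(diag(st$adj) == 0L))
  expect_false(anyNA(st$coop))
})

test_that("absorbed states are permanent under copying-only dynamics", {
  set.seed(407)
  for (all_coop in c(TRUE, FALSE)) {
    st <- random_state(12, p_edge = 0.4, coop_prob = if (all_coop) 1 else 0)
    expect_equal(count_cooperators(st), if (all_coop) 12 else 0)
    tb <- degree_centrality(st)
    for (i in 1:100) {
      res <- integrate_newcomer(st, tb, game_params(), perception_params(),
                                info_weights(), "RANDOM")
      st <- res$state
    }
    expect_equal(count_cooperators(st), if (all_coop) 12 else 0)
  }
})

test_that("count_cooperators tallies strategies", {
  st <- random_state(10, coop_prob = 1)
  expect_equal(count_cooperators(st), 10)
  st$coop[4] <- FALSE
  expect_equal(count_cooperators(st), 9)
  st$coop[] <- FALSE
  expect_equal(count_cooperators(st), 0)
})
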