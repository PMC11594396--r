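test_that("Erdos-Renyi initialisation hits the configured density", {
  set.seed(501)
  cfg <- trial_config(n = 100, init_density = 0.30)
  m <- sum(init_network(cfg)$adj) / 2
  # one G(n, p) draw: binomial around 0.3 * 4950 = 1485
  expect_lt(abs(m - 1485), 5 * sqrt(4950 * 0.3 * 0.7))

  empty <- init_network(trial_config(n = 30, init_density = 0))
  expect_equal(sum(empty$adj), 0)
  full <- init_network(trial_config(n = 30, init_density = 1))
  expect_equal(sum(full$adj) / 2, choose(30, 2))

  exact <- init_network(trial_config(n = 40, init_density = 0.30,
                                     er_exact = TRUE))
  expect_equal(sum(exact$adj) / 2, round(0.30 * choose(40, 2)))

  expect_true(all(init_network(cfg)$coop))
})

test_that("a smoke trial resolves and reports coherent pre-invasion metrics", {
  cfg <- trial_config(n = 20, burn_in = 200, max_steps = 50000,
                      perc = perception_params(tau = -2),
                      weights = info_weights(0.25, 0.25),
                      method = "DEG_HI", seed = 7)
  tr <- run_invasion_trial(cfg, keep_state = TRUE)
  expect_true(tr$outcome %in% c("RECOVERY", "INVASION"))
  expect_true(tr$resolution_steps >= 0)

  # pre-invasion state is all-cooperator, so mean payoff = (b-c) * mean degree
  expect_true(all(tr$pre_invasion_state$coop))
  expect_identical(tr$pre_invasion_mean_payoff,
                   (cfg$game$b - cfg$game$c) * tr$pre_invasion_mean_degree)
  expect_gte(tr$pre_invasion_mean_payoff, 0)
  expect_equal(tr$pre_invasion_payoff_ratio,
               tr$pre_invasion_mean_payoff / (19 * 1))
  # final state is absorbed and matches the reported outcome
  nc <- count_cooperators(tr$final_state)
  expect_equal(nc, if (tr$outcome == "RECOVERY") 20 else 0)
})

test_that("trials are bit-reproducible from their seed", {
  cfg <- trial_config(n = 15, burn_in = 100, max_steps = 5000,
                      method = "BET_LO", seed = 99)
  a <- run_invasion_trial(cfg, keep_state = TRUE)
  b <- run_invasion_trial(cfg, keep_state = TRUE)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$resolution_steps, b$resolution_steps)
  expect_identical(a$final_state$adj, b$final_state$adj)
})

test_that("batch aggregation reproduces hand-computed means", {
  cfg <- trial_config(n = 15, burn_in = 100, max_steps = 20000,
                      method = "DEG_LO", seed = 30)
  b <- run_batch(cfg, 5)
  tr <- b$trials
  expect_equal(nrow(tr), 5)
  expect_equal(b$n_recovery + b$n_invasion + b$n_censored, 5)
  resolved <- tr$outcome %in% c("RECOVERY", "INVASION")
  if (any(resolved)) {
    expect_equal(b$recovery_ratio,
                 sum(tr$outcome == "RECOVERY") / sum(resolved))
  }
  if (any(tr$outcome == "RECOVERY")) {
    expect_equal(b$mean_recovery_time,
                 mean(tr$resolution_steps[tr$outcome == "RECOVERY"]))
  }
  expect_equal(b$mean_pre_invasion_degree, mean(tr$pre_invasion_mean_degree))
  expect_equal(b$mean_payoff_ratio, mean(tr$pre_invasion_payoff_ratio))
  # per-trial seeds are consecutive from the base seed
  expect_equal(tr$seed, 30:34)
  # trial 3 rerun in isolation matches its batch row
  cfg3 <- cfg; cfg3$seed <- 32L; class(cfg3) <- "trial_config"
  t3 <- run_invasion_trial(cfg3)
  expect_identical(t3$outcome, tr$outcome[3])
  expect_equal(t3$pre_invasion_mean_degree, tr$pre_invasion_mean_degree[3])
})

test_that("degenerate batches report boundary recovery ratios", {
  # tau very low and p=q=0: graph empties, resolution is pure drift
  cfg <- trial_config(n = 8, burn_in = 30, max_steps = 5000,
                      perc = perception_params(tau = -10),
                      weights = info_weights(0, 0), method = "RANDOM",
                      seed = 60)
  b <- run_batch(cfg, 4)
  expect_true(b$recovery_ratio >= 0 && b$recovery_ratio <= 1)
  expect_true(is.na(b$mean_recovery_time) || b$n_recovery > 0)
  expect_true(is.na(b$mean_invasion_time) || b$n_invasion > 0)
})

test_that("tradeoff score is the stated convex combination", {
  expect_equal(tradeoff_score(0.4, 0.9, 0), 0.4)
  expect_equal(tradeoff_score(0.4, 0.9, 1), 0.9)
  expect_equal(tradeoff_score(0.4, 0.9, 0.5), 0.65)
  expect_error(tradeoff_score(0.4, 0.9, 1.2), "\\[0, 1\\]")
})

test_that("sweep cells equal standalone batches and are order-independent", {
  base <- trial_config(n = 12, burn_in = 50, max_steps = 5000, seed = 200)
  one <- sweep_rankings(base, tau_grid = 0.5, methods = "DEG_HI",
                        pq_regimes = list(c(0.25, 0.25)), n_trials = 3)
  expect_equal(nrow(one), 1)
  cfg <- base
  cfg$perc$tau <- 0.5
  cfg$weights <- info_weights(0.25, 0.25)
  class(cfg) <- "trial_config"
  direct <- summary(run_batch(cfg, 3))
  expect_equal(one$recovery_ratio, direct$recovery_ratio)
  expect_equal(one$mean_pre_invasion_degree, direct$mean_pre_invasion_degree)

  # permuting the method order leaves each cell unchanged given its seed
  fwd <- sweep_rankings(base, tau_grid = 0.5,
                        methods = c("DEG_HI", "DEG_LO"),
                        pq_regimes = list(c(0.25, 0.25)), n_trials = 2,
                        cell_seeds = c(1000, 2000))
  rev <- sweep_rankings(base, tau_grid = 0.5,
                        methods = c("DEG_LO", "DEG_HI"),
                        pq_regimes = list(c(0.25, 0.25)), n_trials = 2,
                        cell_seeds = c(2000, 1000))
  for (m in c("DEG_HI", "DEG_LO")) {
    expect_equal(fwd[fwd$method == m, -1], rev[rev$method == m, -1],
                 ignore_attr = TRUE)
  }
})
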