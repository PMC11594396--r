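#' Configuration of one invasion trial
#'
#' Bundles every parameter one trial consumes. Defaults are the study
#' conditions: `n = 100` nodes, Erdos-Renyi initialisation with 30% of the
#' `choose(n, 2)` possible edges, a 10,000-step burn-in before the forced
#' mutation, and the default game, perception and information-weight
#' parameters.
#'
#' @param n Population size (>= 2).
#' @param init_density Fraction of possible edges at initialisation, in
#'   `[0, 1]`.
#' @param burn_in Newcomer steps before the forced mutation (>= 0).
#' @param max_steps Cap on post-mutation steps; a trial still unresolved at
#'   the cap is reported as CENSORED, never dropped.
#' @param game A [game_params()].
#' @param perc A [perception_params()].
#' @param weights An [info_weights()].
#' @param method One of [RANKING_METHODS].
#' @param rc Endorsement probability of the RANDOM method.
#' @param seed Integer seed making the trial reproducible in isolation, or
#'   `NULL` to continue the current RNG stream.
#' @param er_exact If `TRUE`, initialise with exactly
#'   `round(init_density * choose(n, 2))` edges (the G(n, M) variant) instead
#'   of including each edge independently with probability `init_density`
#'   (the default G(n, p) variant).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n = 100, init_density = 0.30, burn_in = 10000,
                         max_steps = 1e6, game = game_params(),
                         perc = perception_params(), weights = info_weights(),
                         method = "DEG_HI", rc = 0.8, seed = NULL,
                         er_exact = FALSE) {
  stopifnot(inherits(game, "game_params"), inherits(perc, "perception_params"),
            inherits(weights, "info_weights"))
  if (!is.numeric(n) || n < 2) stop("population size 'n' must be >= 2")
  if (init_density < 0 || init_density > 1) {
    stop("'init_density' must lie in [0, 1]")
  }
  if (burn_in < 0) stop("'burn_in' must be >= 0")
  if (max_steps < 1) stop("'max_steps' must be > 0")
  if (is.na(rc) || rc < 0 || rc > 1) stop("'rc' must be a probability in [0, 1]")
  structure(list(n = as.integer(n), init_density = init_density,
                 burn_in = as.integer(burn_in),
                 max_steps = as.integer(max_steps), game = game, perc = perc,
                 weights = weights, method = match_ranking_method(method),
                 rc = rc, seed = if (is.null(seed)) NULL else as.integer(seed),
                 er_exact = isTRUE(er_exact)),
            class = "trial_config")
}

#' Initialise a population on an Erdos-Renyi random graph
#'
#' Each of the `choose(n, 2)` possible edges is included independently with
#' probability `init_density` (or, with `er_exact`, a uniform subset of
#' exactly `round(init_density * choose(n, 2))` edges is drawn). Every node
#' starts as a cooperator: the perturbation protocol introduces the single
#' defector only after the burn-in, and copying-only dynamics are coherent
#' only from a cooperator-monomorphic start.
#'
#' @param cfg A [trial_config()].
#' @return A [population_state()] of `cfg$n` cooperators.
#' @export
init_network <- function(cfg) {
  n <- cfg$n
  adj <- matrix(0L, n, n)
  ut <- which(upper.tri(adj))
  if (cfg$er_exact) {
    m <- round(cfg$init_density * length(ut))
    on <- sample(ut, m)
  } else {
    on <- ut[stats::runif(length(ut)) < cfg$init_density]
  }
  adj[on] <- 1L
  adj <- adj + t(adj)
  population_state(adj, rep(TRUE, n))
}

# one newcomer step plus the end-of-step ranking recomputation
step_and_rerank <- function(state, table, cfg) {
  res <- integrate_newcomer(state, table, cfg$game, cfg$perc, cfg$weights,
                            cfg$method, cfg$rc)
  res$table <- if (cfg$method == "RANDOM") table else
    ranking_table(res$state, cfg$method)
  res
}

#' Run one cheater-invasion trial
#'
#' The perturbation protocol: initialise the network, run `burn_in` newcomer
#' steps so the structure settles, record the pre-invasion prosperity
#' metrics (mean payoff, mean degree, mean normalised payoff ratio) at the
#' step just before the mutation, flip one uniformly chosen node to
#' defection, then keep stepping until one strategy is extinct or
#' `max_steps` post-mutation steps have elapsed. Absorption into the
#' all-cooperator state is a RECOVERY, into the all-defector state an
#' INVASION; hitting the cap yields CENSORED.
#'
#' @param cfg A [trial_config()].
#' @param keep_state If `TRUE`, attach the pre-invasion and final
#'   [population_state()]s to the result.
#' @return An object of class `netcoop_trial`: list with `outcome`
#'   ("RECOVERY", "INVASION" or "CENSORED"), `resolution_steps` (post-mutation
#'   steps to absorption; `NA` when censored), `pre_invasion_mean_payoff`,
#'   `pre_invasion_mean_degree`, `pre_invasion_payoff_ratio`, `mutant`, and
#'   the `config`.
#' @export
run_invasion_trial <- function(cfg, keep_state = FALSE) {
  stopifnot(inherits(cfg, "trial_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  state <- init_network(cfg)
  table <- ranking_table(state, cfg$method)
  for (i in seq_len(cfg$burn_in)) {
    res <- step_and_rerank(state, table, cfg)
    state <- res$state
    table <- res$table
  }

  pay <- all_payoffs(state, cfg$game)
  deg <- node_degrees(state)
  pre_payoff <- mean(pay)
  pre_degree <- mean(deg)
  pre_ratio <- mean(payoff_ratio(pay, cfg$n, cfg$game))
  pre_state <- if (keep_state) state else NULL

  mutant <- sample.int(cfg$n, 1L)
  state$coop[mutant] <- FALSE

  outcome <- "CENSORED"
  steps <- NA_integer_
  for (t in seq_len(cfg$max_steps)) {
    nc <- count_cooperators(state)
    if (nc == 0L || nc == cfg$n) {
      outcome <- if (nc == cfg$n) "RECOVERY" else "INVASION"
      steps <- t - 1L
      break
    }
    res <- step_and_rerank(state, table, cfg)
    state <- res$state
    table <- res$table
  }
  if (outcome == "CENSORED") {
    nc <- count_cooperators(state)
    if (nc == 0L || nc == cfg$n) {
      outcome <- if (nc == cfg$n) "RECOVERY" else "INVASION"
      steps <- cfg$max_steps
    }
  }

  structure(list(outcome = outcome, resolution_steps = steps,
                 pre_invasion_mean_payoff = pre_payoff,
                 pre_invasion_mean_degree = pre_degree,
                 pre_invasion_payoff_ratio = pre_ratio,
                 mutant = mutant, config = cfg,
                 pre_invasion_state = pre_state,
                 final_state = if (keep_state) state else NULL),
            class = "netcoop_trial")
}

#' @export
print.netcoop_trial <- function(x, ...) {
  cat(sprintf("Invasion trial (%s, tau = %g, p = %g, q = %g): %s",
              x$config$method, x$config$perc$tau, x$config$weights$p,
              x$config$weights$q, x$outcome))
  if (!is.na(x$resolution_steps)) {
    cat(sprintf(" after %d post-mutation steps", x$resolution_steps))
  }
  cat(sprintf("\n  pre-invasion: mean payoff %.3f, mean degree %.3f, payoff ratio %.4f\n",
              x$pre_invasion_mean_payoff, x$pre_invasion_mean_degree,
              x$pre_invasion_payoff_ratio))
  invisible(x)
}

#' Run a batch of independently seeded invasion trials
#'
#' Trial `i` uses seed `cfg$seed + i - 1`, so any single trial can be
#' reproduced in isolation. The recovery ratio is the fraction of resolved
#' trials (censored trials are counted and reported but excluded from the
#' denominator), and per-outcome mean resolution times are taken only over
#' trials with the matching outcome.
#'
#' @param cfg A [trial_config()] whose `seed` must be set.
#' @param n_trials Number of trials (>= 1).
#' @return An object of class `netcoop_batch`: list with `trials` (one row
#'   per trial) and the aggregate fields `n_trials`, `n_recovery`,
#'   `n_invasion`, `n_censored`, `recovery_ratio`, `mean_recovery_time`,
#'   `mean_invasion_time`, `mean_pre_invasion_payoff`,
#'   `mean_pre_invasion_degree`, `mean_payoff_ratio`.
#' @export
run_batch <- function(cfg, n_trials) {
  stopifnot(inherits(cfg, "trial_config"), n_trials >= 1)
  if (is.null(cfg$seed)) stop("run_batch() needs a seeded trial_config")
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tcfg <- cfg
    tcfg$seed <- cfg$seed + i - 1L
    tr <- run_invasion_trial(tcfg)
    rows[[i]] <- data.frame(
      trial = i, seed = tcfg$seed, outcome = tr$outcome,
      resolution_steps = tr$resolution_steps,
      pre_invasion_mean_payoff = tr$pre_invasion_mean_payoff,
      pre_invasion_mean_degree = tr$pre_invasion_mean_degree,
      pre_invasion_payoff_ratio = tr$pre_invasion_payoff_ratio,
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  summarise_trials(trials, cfg)
}

# aggregation shared by run_batch and sweep
summarise_trials <- function(trials, cfg) {
  rec <- trials$outcome == "RECOVERY"
  inv <- trials$outcome == "INVASION"
  cen <- trials$outcome == "CENSORED"
  resolved <- sum(rec) + sum(inv)
  structure(list(
    trials = trials,
    config = cfg,
    n_trials = nrow(trials),
    n_recovery = sum(rec),
    n_invasion = sum(inv),
    n_censored = sum(cen),
    recovery_ratio = if (resolved > 0) sum(rec) / resolved else NA_real_,
    mean_recovery_time = if (any(rec)) mean(trials$resolution_steps[rec]) else NA_real_,
    mean_invasion_time = if (any(inv)) mean(trials$resolution_steps[inv]) else NA_real_,
    mean_pre_invasion_payoff = mean(trials$pre_invasion_mean_payoff),
    mean_pre_invasion_degree = mean(trials$pre_invasion_mean_degree),
    mean_payoff_ratio = mean(trials$pre_invasion_payoff_ratio)
  ), class = "netcoop_batch")
}

#' @export
print.netcoop_batch <- function(x, ...) {
  cat(sprintf("Batch of %d invasion trials (%s, tau = %g, p = %g, q = %g)\n",
              x$n_trials, x$config$method, x$config$perc$tau,
              x$config$weights$p, x$config$weights$q))
  cat(sprintf("  outcomes: %d recoveries, %d invasions, %d censored\n",
              x$n_recovery, x$n_invasion, x$n_censored))
  cat(sprintf("  recovery ratio: %s\n",
              ifelse(is.na(x$recovery_ratio), "undefined (no resolved trials)",
                     sprintf("%.3f", x$recovery_ratio))))
  cat(sprintf("  mean recovery time: %s | mean invasion time: %s\n",
              ifelse(is.na(x$mean_recovery_time), "-",
                     sprintf("%.1f", x$mean_recovery_time)),
              ifelse(is.na(x$mean_invasion_time), "-",
                     sprintf("%.1f", x$mean_invasion_time))))
  cat(sprintf("  pre-invasion: mean payoff %.3f, mean degree %.3f, payoff ratio %.4f\n",
              x$mean_pre_invasion_payoff, x$mean_pre_invasion_degree,
              x$mean_payoff_ratio))
  invisible(x)
}

#' @export
summary.netcoop_batch <- function(object, ...) {
  data.frame(method = object$config$method, tau = object$config$perc$tau,
             p = object$config$weights$p, q = object$config$weights$q,
             n_trials = object$n_trials, n_recovery = object$n_recovery,
             n_invasion = object$n_invasion, n_censored = object$n_censored,
             recovery_ratio = object$recovery_ratio,
             mean_recovery_time = object$mean_recovery_time,
             mean_invasion_time = object$mean_invasion_time,
             mean_pre_invasion_payoff = object$mean_pre_invasion_payoff,
             mean_pre_invasion_degree = object$mean_pre_invasion_degree,
             mean_payoff_ratio = object$mean_payoff_ratio,
             stringsAsFactors = FALSE)
}

#' Prosperity-stability trade-off score
#'
#' `(1 - w) * payoff_ratio + w * recovery_rate`: at `w = 0` pure prosperity
#' (the normalised pre-invasion payoff), at `w = 1` pure stability (the
#' recovery rate).
#'
#' @param payoff_ratio Normalised payoff ratio in `[0, 1]`.
#' @param recovery_rate Recovery ratio in `[0, 1]`.
#' @param w Stability weight in `[0, 1]`.
#' @return The weighted score.
#' @export
tradeoff_score <- function(payoff_ratio, recovery_rate, w) {
  if (any(is.na(w)) || any(w < 0) || any(w > 1)) {
    stop("trade-off weight 'w' must lie in [0, 1]")
  }
  (1 - w) * payoff_ratio + w * recovery_rate
}

#' Sweep ranking methods, thresholds and information regimes
#'
#' Runs one batch per cell of the grid
#' `methods x tau_grid x pq_regimes`. Cells are seeded independently
#' (`cell_seeds`, defaulting to consecutive blocks of `n_trials` seeds from
#' the base seed), so every cell is reproducible in isolation and the cell
#' order is immaterial given the same per-cell seeds.
#'
#' @param base A [trial_config()] supplying every non-swept parameter and
#'   the base seed.
#' @param tau_grid Numeric vector of decision thresholds (default the
#'   21-point grid `seq(-2, 2, by = 0.2)`).
#' @param methods Character vector of ranking methods (default all seven).
#' @param pq_regimes List of `c(p, q)` pairs (default the four corners of
#'   `{0.25, 0.75}^2`).
#' @param n_trials Trials per cell.
#' @param cell_seeds Optional integer vector, one seed per cell.
#' @return A data frame with one row per cell: the cell parameters followed
#'   by the [run_batch()] aggregate columns. Class `netcoop_sweep`.
#' @export
sweep_rankings <- function(base, tau_grid = seq(-2, 2, by = 0.2),
                           methods = RANKING_METHODS,
                           pq_regimes = list(c(0.25, 0.25), c(0.25, 0.75),
                                             c(0.75, 0.25), c(0.75, 0.75)),
                           n_trials = 1000, cell_seeds = NULL) {
  stopifnot(inherits(base, "trial_config"), length(tau_grid) > 0,
            length(methods) > 0, length(pq_regimes) > 0)
  grid <- expand.grid(regime = seq_along(pq_regimes), tau = tau_grid,
                      method = methods, stringsAsFactors = FALSE)
  if (is.null(cell_seeds)) {
    cell_seeds <- base$seed + (seq_len(nrow(grid)) - 1L) * as.integer(n_trials)
  }
  if (length(cell_seeds) != nrow(grid)) {
    stop("need one cell seed per grid cell (", nrow(grid), " cells)")
  }
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pq <- pq_regimes[[grid$regime[i]]]
    cfg <- base
    cfg$method <- match_ranking_method(grid$method[i])
    cfg$perc$tau <- grid$tau[i]
    cfg$weights <- info_weights(p = pq[1], q = pq[2])
    cfg$seed <- as.integer(cell_seeds[i])
    out[[i]] <- summary(run_batch(cfg, n_trials))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("netcoop_sweep", class(res))
  res
}
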