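#' Game parameters of the networked prisoner's dilemma
#'
#' Bundles the benefit `b` produced by a cooperator for each neighbour, the
#' cost `c` the cooperator pays per neighbour, and the selection strength
#' `delta` that maps payoff to fitness. The defaults are the values used
#' throughout the simulations: `b = 9`, `c = 8` (so a mutual-cooperation
#' edge is worth `b - c = 1` to each endpoint while exploitation transfers
#' 9 to the defector at a cost of 8 to the cooperator) and `delta = 0.01`
#' (weak selection).
#'
#' @param b Benefit conferred on each neighbour by a cooperator. Must satisfy
#'   `b > c`.
#' @param c Cost paid by a cooperator per neighbour. Must satisfy `c > 0`.
#' @param delta Selection strength, `delta >= 0`. `delta = 0` makes role-model
#'   selection uniform regardless of payoff.
#' @return An object of class `game_params`.
#' @examples
#' game_params()
#' game_params(b = 3, c = 1, delta = 0.05)
#' @export
game_params <- function(b = 9, c = 8, delta = 0.01) {
  stopifnot(is.numeric(b), is.numeric(c), is.numeric(delta),
            length(b) == 1L, length(c) == 1L, length(delta) == 1L)
  if (!(b > c && c > 0)) {
    stop("game parameters must satisfy b > c > 0 (got b = ", b, ", c = ", c, ")")
  }
  if (delta < 0) stop("selection strength 'delta' must be >= 0")
  structure(list(b = b, c = c, delta = delta), class = "game_params")
}

#' Private-information (perception) parameters
#'
#' A newcomer perceives the intent of each candidate partner by drawing from
#' one of two Gaussians: mean `mu_c` if the candidate cooperates, `mu_d` if it
#' defects, common variance `sigma2`. The draw is compared with the decision
#' threshold `tau`: values below `tau` indicate a connection should be made.
#' Defaults place the two peaks one apart (`mu_c = -0.5`, `mu_d = 0.5`) with
#' `sigma2 = 0.5`, so perception is informative but noisy: at `tau = 0` a
#' cooperator is endorsed with probability `pnorm(0.5/sqrt(0.5))`, about 0.76,
#' a defector with about 0.24.
#'
#' @param mu_c Mean of the cooperator-perception distribution.
#' @param mu_d Mean of the defector-perception distribution; must exceed
#'   `mu_c`.
#' @param sigma2 Common variance of both distributions, strictly positive.
#' @param tau Decision threshold; higher values endorse more candidates of
#'   either strategy.
#' @return An object of class `perception_params`.
#' @examples
#' perception_params(tau = 1.6)
#' @export
perception_params <- function(mu_c = -0.5, mu_d = 0.5, sigma2 = 0.5, tau = 0) {
  stopifnot(is.numeric(mu_c), is.numeric(mu_d), is.numeric(sigma2),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (sigma2 <= 0) stop("perception variance 'sigma2' must be > 0")
  if (mu_d <= mu_c) stop("'mu_d' must exceed 'mu_c' (defectors read higher)")
  structure(list(mu_c = mu_c, mu_d = mu_d, sigma2 = sigma2, tau = tau),
            class = "perception_params")
}

#' Information-priority weights
#'
#' When public and private information disagree about a candidate, the
#' connection is formed with probability `p` if only public information
#' endorses it and with probability `q` if only private information does.
#' Agreement is decisive: both positive always connects, both negative never
#' does.
#'
#' @param p Probability of connecting on a public-only indication, in `[0, 1]`.
#' @param q Probability of connecting on a private-only indication, in `[0, 1]`.
#' @return An object of class `info_weights`.
#' @examples
#' info_weights(p = 0.25, q = 0.75)
#' @export
info_weights <- function(p = 0.25, q = 0.25) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 1L, length(q) == 1L)
  if (is.na(p) || p < 0 || p > 1) stop("'p' must be a probability in [0, 1]")
  if (is.na(q) || q < 0 || q > 1) stop("'q' must be a probability in [0, 1]")
  structure(list(p = p, q = q), class = "info_weights")
}

#' The seven public-information ranking methods
#'
#' Candidates are endorsed by public information when their centrality score
#' exceeds (HI variants) or falls below (LO variants) the network average,
#' computed over degree, betweenness or eigenvector centrality; the RANDOM
#' method endorses independently with probability `rc` (default 0.8).
#'
#' @format A character vector of the seven method names.
#' @export
RANKING_METHODS <- c("DEG_HI", "DEG_LO", "BET_HI", "BET_LO",
                     "EIG_HI", "EIG_LO", "RANDOM")

match_ranking_method <- function(method) {
  if (!is.character(method) || length(method) != 1L ||
      !(method %in% RANKING_METHODS)) {
    stop("unknown ranking method '", paste(method, collapse = ","),
         "'; must be one of ", paste(RANKING_METHODS, collapse = ", "))
  }
  method
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("Prisoner's dilemma parameters: b = %g, c = %g, delta = %g\n",
              x$b, x$c, x$delta))
  invisible(x)
}

#' @export
print.perception_params <- function(x, ...) {
  cat(sprintf(
    "Perception: N(%g, %g) cooperators | N(%g, %g) defectors | tau = %g\n",
    x$mu_c, x$sigma2, x$mu_d, x$sigma2, x$tau))
  invisible(x)
}

#' @export
print.info_weights <- function(x, ...) {
  cat(sprintf("Information weights: p = %g (public-only), q = %g (private-only)\n",
              x$p, x$q))
  invisible(x)
}
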