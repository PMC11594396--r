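#' Draw a private perception value for a candidate
#'
#' The newcomer's noisy read of a candidate's intent: a fresh draw from
#' `N(mu_c, sigma2)` if the candidate cooperates or `N(mu_d, sigma2)` if it
#' defects. Draws are independent across candidates and steps — perception
#' has no memory.
#'
#' @param cooperator Logical (vectorised): is each candidate a cooperator?
#' @param params A [perception_params()].
#' @return Numeric perception value(s), consuming one normal deviate per
#'   candidate from the current RNG stream.
#' @export
sample_perception <- function(cooperator, params) {
  mu <- ifelse(cooperator, params$mu_c, params$mu_d)
  stats::rnorm(length(mu), mean = mu, sd = sqrt(params$sigma2))
}

#' Private-information indication from a perception value
#'
#' Indicates a connection should be made exactly when the threshold `tau`
#' strictly exceeds the sampled value, so lower (more cooperator-like)
#' perception values are endorsed. Ties have probability zero; the strict
#' inequality is fixed for determinism. Raising `tau` endorses more
#' candidates of either strategy, with cooperators always endorsed more
#' often than defectors: the acceptance probability for strategy `s` is
#' `pnorm((tau - mu_s) / sqrt(sigma2))` and `mu_c < mu_d`.
#'
#' @param sample Numeric perception value(s) from [sample_perception()].
#' @param params A [perception_params()] supplying `tau`.
#' @return Logical indication(s).
#' @examples
#' pp <- perception_params(tau = 0)
#' private_signal(-0.3, pp)  # TRUE
#' private_signal(0.3, pp)   # FALSE
#' @export
private_signal <- function(sample, params) {
  params$tau > sample
}
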