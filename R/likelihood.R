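#' Marginalized log-likelihood of one survey period
#'
#' The latent occurrence state z of a period is marginalized analytically:
#' \deqn{\log[ \psi \prod_j p_j^{y_j}(1-p_j)^{1-y_j} + I(\sum_j y_j = 0)(1-\psi) ]}
#' A period with any detection forces z = 1; an all-zero history is either
#' an occupied period with J missed nights or an unoccupied one.
#'
#' @param y Binary detection vector for the period's nights.
#' @param psi Occurrence probability, in (0, 1).
#' @param p Detection probabilities per night, each in (0, 1); scalar `p`
#'   is recycled.
#' @return Scalar log-probability.
#' @export
#' @examples
#' period_loglik(c(0, 0), 0.5, c(0.5, 0.5))  # log(0.625)
period_loglik <- function(y, psi, p) {
  p <- rep_len(p, length(y))
  if (!all(y %in% c(0, 1)))
    fireocc_error("fireocc_domain", "y must be binary")
  if (length(psi) != 1 || psi <= 0 || psi >= 1)
    fireocc_error("fireocc_domain", "psi must be a scalar in (0, 1)")
  if (any(p <= 0) || any(p >= 1))
    fireocc_error("fireocc_domain", "all p must be in (0, 1)")
  ll_det <- sum(y * log(p) + (1 - y) * log1p(-p))
  if (any(y == 1)) {
    log(psi) + ll_det
  } else {
    log_sum_exp(log(psi) + ll_det, log1p(-psi))
  }
}

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Prior settings for the occupancy model
#'
#' Weakly regularizing Normal(0, `sd_fixed`) priors on all fixed effects
#' (logit scale) and hierarchical Normal(0, sigma) priors on the site and
#' fire-area random intercepts with HalfNormal(`sigma_scale`) hyperpriors on
#' each sigma.
#'
#' @param sd_fixed Prior SD for fixed effects.
#' @param sigma_scale HalfNormal scale for the random-intercept SDs.
#' @return List of class `occu_priors`.
#' @export
occu_priors <- function(sd_fixed = 1.5, sigma_scale = 1) {
  stopifnot(sd_fixed > 0, sigma_scale > 0)
  structure(list(sd_fixed = sd_fixed, sigma_scale = sigma_scale),
            class = "occu_priors")
}

#' Pointwise marginal log-likelihood for all periods (pure R)
#'
#' Reference implementation used for testing, exact-LOO oracles and
#' cross-checking the compiled sampler; the MCMC engine computes the same
#' quantity in C++.
#'
#' @param params List with `alpha`, `beta`, `u_site`, `u_area` (numeric
#'   vectors; random effects may be omitted and default to 0).
#' @param data An `occu_data`.
#' @param y Binary night-level detection vector (rows of `data$X_det`).
#' @return Numeric vector of per-period log-likelihoods.
#' @export
occu_pointwise_loglik <- function(params, data, y) {
  stopifnot(inherits(data, "occu_data"))
  if (length(y) != data$n_nights)
    fireocc_error("fireocc_shape", "y must have one entry per survey night")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    fireocc_error("fireocc_validation", "y must be binary with no NA")
  u_site <- params$u_site %||% rep(0, data$n_site)
  u_area <- params$u_area %||% rep(0, data$n_area)
  eta_p <- drop(data$X_det %*% params$alpha)
  eta_psi <- drop(data$X_occ %*% params$beta) +
    u_site[data$site] + u_area[data$area]
  # log Bernoulli terms accumulated per period
  lb <- y * plogis(eta_p, log.p = TRUE) + (1 - y) * plogis(-eta_p, log.p = TRUE)
  A <- rep(0, data$n_periods)
  det <- rep(FALSE, data$n_periods)
  for (k in seq_along(y)) {
    i <- data$night_period[k]
    A[i] <- A[i] + lb[k]
    if (y[k] == 1) det[i] <- TRUE
  }
  lpsi <- plogis(eta_psi, log.p = TRUE)
  l1mpsi <- plogis(-eta_psi, log.p = TRUE)
  ifelse(det, lpsi + A, log_sum_exp(lpsi + A, l1mpsi))
}

#' Log posterior density of the occupancy model
#'
#' Sum of the marginalized pointwise log-likelihood and the log priors
#' declared in `priors`. Random-effect SDs enter on the natural scale.
#'
#' @inheritParams occu_pointwise_loglik
#' @param priors An [occu_priors()].
#' @return Scalar log posterior (unnormalized).
#' @export
occu_log_posterior <- function(params, data, y, priors = occu_priors()) {
  ll <- sum(occu_pointwise_loglik(params, data, y))
  u_site <- params$u_site %||% rep(0, data$n_site)
  u_area <- params$u_area %||% rep(0, data$n_area)
  sig_s <- params$sigma_site %||% 1
  sig_a <- params$sigma_area %||% 1
  if (sig_s <= 0 || sig_a <= 0)
    fireocc_error("fireocc_domain", "sigmas must be positive")
  lp <- sum(dnorm(params$alpha, 0, priors$sd_fixed, log = TRUE)) +
    sum(dnorm(params$beta, 0, priors$sd_fixed, log = TRUE)) +
    sum(dnorm(u_site, 0, sig_s, log = TRUE)) +
    sum(dnorm(u_area, 0, sig_a, log = TRUE)) +
    half_normal_lpdf(sig_s, priors$sigma_scale) +
    half_normal_lpdf(sig_a, priors$sigma_scale)
  ll + lp
}

half_normal_lpdf <- function(x, scale) {
  log(2) + dnorm(x, 0, scale, log = TRUE)
}

#' Conditional probability of occurrence given the detection history
#'
#' Bayes rule for the latent state: 1 if the species was detected during
#' the period, otherwise
#' \eqn{\psi \prod_j (1-p_j) / [\psi \prod_j (1-p_j) + 1 - \psi]}.
#'
#' @param y Binary detection vector for the period.
#' @param psi Occurrence probability in (0, 1).
#' @param p Nightly detection probabilities (recycled).
#' @return Probability in (0, 1\].
#' @export
conditional_occurrence_prob <- function(y, psi, p) {
  p <- rep_len(p, length(y))
  if (any(y == 1)) return(1)
  q <- psi * prod(1 - p)
  q / (q + 1 - psi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
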