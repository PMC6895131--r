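#' Species-level generating parameters
#'
#' Container for the true detection and occurrence coefficients of one
#' species under the occupancy model, used by the simulator and recovered
#' by the fitter. Coefficient order follows the design matrices built by
#' [occu_model_data()]: detection (intercept, day, day^2, canopy, noise,
#' temperature, microphone) and occurrence (intercept, elevation, water
#' distance, severity, severity^2, pyrodiversity), all on the logit scale.
#'
#' @param alpha Detection coefficients.
#' @param beta Occurrence coefficients.
#' @param sigma_site,sigma_area SDs of the site and fire-area random
#'   intercepts (>= 0).
#' @param u_site,u_area Optional fixed realizations of the random
#'   intercepts; drawn from Normal(0, sigma) at simulation time if `NULL`.
#' @return List of class `true_params`.
#' @export
true_params <- function(alpha, beta, sigma_site = 0.5, sigma_area = 0.5,
                        u_site = NULL, u_area = NULL) {
  if (!all(is.finite(alpha)) || !all(is.finite(beta)))
    fireocc_error("fireocc_invalid_argument", "coefficients must be finite")
  if (sigma_site < 0 || sigma_area < 0)
    fireocc_error("fireocc_invalid_argument", "sigmas must be >= 0")
  structure(list(alpha = alpha, beta = beta,
                 sigma_site = sigma_site, sigma_area = sigma_area,
                 u_site = u_site, u_area = u_area),
            class = "true_params")
}

#' Draw a community of species parameters
#'
#' Generates `S` species whose intercepts and effects span the magnitudes
#' typical of a forest bat community: detection intercepts centred below 0
#' (most species detected on a minority of occupied nights), occupancy
#' intercepts spanning rare to near-ubiquitous species, and moderate
#' covariate effects including severity and pyrodiversity responses of
#' either sign.
#'
#' @param S Number of species.
#' @param n_det,n_occ Numbers of detection/occurrence coefficients.
#' @param seed Optional integer seed.
#' @return Named list of [true_params()], one per species.
#' @export
community_params <- function(S = 17, n_det = 7, n_occ = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(S), function(s) {
    alpha <- c(rnorm(1, -1, 1), rnorm(n_det - 1, 0, 0.4))
    beta <- c(rnorm(1, 0, 1.2), rnorm(n_occ - 1, 0, 0.5))
    true_params(alpha, beta, sigma_site = 0.5, sigma_area = 0.5)
  })
  names(out) <- sprintf("sp%02d", seq_len(S))
  out
}

#' Simulate a detection history under the occupancy model
#'
#' Draws the latent occurrence state once per survey period,
#' z_i ~ Bernoulli(psi_i), then nightly observations
#' y_ij ~ Bernoulli(p_ij * z_i); an unoccupied period can never yield a
#' detection.
#'
#' @param data An `occu_data` with standardized covariates.
#' @param params A [true_params()].
#' @param seed Optional integer seed.
#' @return List of class `occu_sim`: `y` (binary vector over nights),
#'   `z` (binary vector over periods), `psi`, `p`, and the realized
#'   `u_site` / `u_area`.
#' @export
simulate_detections <- function(data, params, seed = NULL) {
  stopifnot(inherits(data, "occu_data"))
  if (length(params$alpha) != ncol(data$X_det) ||
      length(params$beta) != ncol(data$X_occ))
    fireocc_error("fireocc_shape",
                  "parameter lengths do not match design matrix columns")
  if (!is.null(seed)) set.seed(seed)
  u_site <- params$u_site %||% rnorm(data$n_site, 0, params$sigma_site)
  u_area <- params$u_area %||% rnorm(data$n_area, 0, params$sigma_area)
  psi <- plogis(drop(data$X_occ %*% params$beta) +
                  u_site[data$site] + u_area[data$area])
  p <- plogis(drop(data$X_det %*% params$alpha))
  z <- rbinom(data$n_periods, 1, psi)
  y <- rbinom(data$n_nights, 1, p * z[data$night_period])
  structure(list(y = y, z = z, psi = psi, p = p,
                 u_site = u_site, u_area = u_area, params = params),
            class = "occu_sim")
}

#' Simulate detection histories for a whole community
#'
#' @param data An `occu_data`.
#' @param params_list Named list of [true_params()] (one per species).
#' @param seed Optional integer seed; species s uses substream `seed + s`.
#' @return Named list of `occu_sim` objects.
#' @export
simulate_community <- function(data, params_list, seed = NULL) {
  sims <- lapply(seq_along(params_list), function(s) {
    sp_seed <- if (is.null(seed)) NULL else seed + s
    simulate_detections(data, params_list[[s]], seed = sp_seed)
  })
  names(sims) <- names(params_list)
  sims
}

#' Naive occupancy: fraction of periods with at least one detection
#'
#' @param y Binary night-level detections.
#' @param night_period Period index per night.
#' @return Proportion in \[0, 1\].
#' @export
naive_occupancy <- function(y, night_period) {
  det <- tapply(y, night_period, function(v) any(v == 1))
  mean(det)
}
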