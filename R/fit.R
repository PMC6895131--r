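#' Fit the single-season occupancy model by MCMC
#'
#' Samples the posterior of the marginalized-likelihood occupancy model for
#' one species at one covariate scale, using a component-wise adaptive
#' random-walk Metropolis sampler (compiled). The latent occurrence state
#' is marginalized analytically in the likelihood; per-draw conditional
#' occurrence probabilities P(z = 1 | y) are stored for downstream
#' diversity calculations, along with per-draw psi and pointwise
#' log-likelihoods for model comparison.
#'
#' @param data An `occu_data`.
#' @param y Binary night-level detection vector.
#' @param chains Number of chains (>= 2 for R-hat).
#' @param iter Iterations per chain, including warmup.
#' @param warmup Warmup (adaptation) iterations discarded from the output.
#' @param seed Optional integer seed; chain c uses `seed + c`.
#' @param priors An [occu_priors()].
#' @return Object of class `occu_fit`: `draws` (total kept draws x
#'   parameters, named columns), `chain` (chain id per draw), `psi`, `pz`,
#'   `loglik` (kept draws x periods), `rhat` (per parameter), `converged`
#'   flag, acceptance rates, and the `data` standardization metadata.
#' @export
fit_occupancy <- function(data, y, chains = 3, iter = 2000, warmup = 1000,
                          seed = NULL, priors = occu_priors()) {
  stopifnot(inherits(data, "occu_data"))
  if (chains < 2)
    fireocc_error("fireocc_invalid_argument", "need >= 2 chains for R-hat")
  if (warmup >= iter)
    fireocc_error("fireocc_invalid_argument", "warmup must be < iter")
  if (length(y) != data$n_nights)
    fireocc_error("fireocc_shape", "y must have one entry per survey night")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    fireocc_error("fireocc_validation", "y must be binary with no NA")

  nd <- ncol(data$X_det)
  no <- ncol(data$X_occ)
  npar <- nd + no + data$n_site + data$n_area + 2L
  pnames <- c(paste0("alpha", seq_len(nd) - 1L),
              paste0("beta", seq_len(no) - 1L),
              paste0("u_site[", seq_len(data$n_site), "]"),
              paste0("u_area[", seq_len(data$n_area), "]"),
              "log_sigma_site", "log_sigma_area")

  # fixed effects start at 0; occupancy intercept at the logit of naive
  # occupancy (clipped); random intercepts at 0; sigmas at 0.5
  base_init <- numeric(npar)
  naive <- naive_occupancy(y, data$night_period)
  base_init[nd + 1L] <- min(3, max(-3, qlogis(min(0.99, max(0.01, naive)))))
  base_init[npar - 1L] <- log(0.5)
  base_init[npar] <- log(0.5)

  keep <- iter - warmup
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    if (!is.null(seed)) set.seed(seed + ch)
    init <- base_init + rnorm(npar, 0, 0.1)
    res[[ch]] <- occu_mcmc_chain(
      as.integer(y), as.integer(data$night_period) - 1L,
      data$X_det, data$X_occ,
      as.integer(data$site) - 1L, as.integer(data$area) - 1L,
      data$n_site, data$n_area, as.integer(iter), as.integer(warmup),
      priors$sd_fixed, priors$sigma_scale, init)
  }

  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(draws) <- pnames
  chain <- rep(seq_len(chains), each = keep)

  rh <- vapply(seq_len(npar), function(j)
    rhat(matrix(draws[, j], nrow = keep, ncol = chains)), numeric(1))
  names(rh) <- pnames
  main <- c(seq_len(nd + no), npar - 1L, npar)
  converged <- all(is.finite(rh[main])) && max(rh[main]) < 1.1
  if (!converged)
    warning("possible non-convergence: max R-hat on fixed effects/sigmas = ",
            round(max(rh[main], na.rm = TRUE), 3), call. = FALSE)

  structure(list(
    draws = draws, chain = chain,
    psi = do.call(rbind, lapply(res, `[[`, "psi")),
    pz = do.call(rbind, lapply(res, `[[`, "pz")),
    loglik = do.call(rbind, lapply(res, `[[`, "loglik")),
    rhat = rh, converged = converged,
    accept = rowMeans(sapply(res, `[[`, "accept")),
    n_det = nd, n_occ = no,
    centers = data$centers, scales = data$scales, radius = data$radius,
    chains = chains, iter = iter, warmup = warmup
  ), class = "occu_fit")
}

#' Posterior summary of an occupancy fit
#'
#' @param object An `occu_fit`.
#' @param pars Optional character vector of parameter names.
#' @param ... Unused.
#' @return data.frame with mean, sd, 90% credible interval and R-hat.
#' @export
summary.occu_fit <- function(object, pars = NULL, ...) {
  d <- object$draws
  if (is.null(pars))
    pars <- c(grep("^alpha|^beta", colnames(d), value = TRUE),
              "log_sigma_site", "log_sigma_area")
  d <- d[, pars, drop = FALSE]
  data.frame(
    param = pars,
    mean = colMeans(d),
    sd = apply(d, 2, sd),
    q5 = apply(d, 2, quantile, 0.05),
    q50 = apply(d, 2, quantile, 0.50),
    q95 = apply(d, 2, quantile, 0.95),
    rhat = object$rhat[pars],
    row.names = NULL
  )
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("<occu_fit> ", x$chains, " chains x ", x$iter - x$warmup,
      " kept draws; ", ncol(x$psi), " periods; ",
      if (x$converged) "converged (max R-hat < 1.1)" else "NOT converged",
      "\n", sep = "")
  print(summary(x), digits = 3)
  invisible(x)
}
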