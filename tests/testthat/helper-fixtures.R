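# Fixture builders shared across tests. All fixtures are generated in code
# under fixed seeds; nothing is stored on disk.

# A model-ready dataset with standardized random covariates, J nights per
# period, and a balanced site/area layout. Bypasses the landscape pipeline
# so likelihood/sampler tests control their own design matrices.
make_toy_data <- function(n_periods = 100, J = 6, n_site = NULL, n_area = 3,
                          n_det = 7, n_occ = 6, seed = 1) {
  set.seed(seed)
  if (is.null(n_site)) n_site <- max(2L, n_periods %/% 4L)
  site <- rep_len(seq_len(n_site), n_periods)
  area <- ((site - 1L) %% n_area) + 1L
  night_period <- rep(seq_len(n_periods), each = J)
  std_cols <- function(n, k) {
    if (k == 0) return(NULL)
    if (n < 2) return(matrix(0, n, k))
    vapply(seq_len(k), function(j) standardize(rnorm(n))$values, numeric(n))
  }
  X_det <- cbind(rep(1, n_periods * J), std_cols(n_periods * J, n_det - 1))
  X_occ <- cbind(rep(1, n_periods), std_cols(n_periods, n_occ - 1))
  occu_data(X_det, X_occ, night_period, site, area)
}

# Paper-magnitude generating parameters used in the recovery and
# scale-selection experiments (fixed once; see the methods vignette).
recovery_alpha <- c(0, 0.25, -0.25, -0.25, -0.5, 0.25, 0.25)
recovery_beta <- c(0, 0.5, -0.25, 1.0, -0.5, 0.75)

# Remove one survey period from an occu_data + detection vector, reindexing
# periods, for exact leave-one-out refits.
drop_period <- function(data, y, i) {
  keep_n <- data$night_period != i
  np <- data$night_period[keep_n]
  np[np > i] <- np[np > i] - 1L
  keep_p <- setdiff(seq_len(data$n_periods), i)
  occu_data(data$X_det[keep_n, , drop = FALSE],
            data$X_occ[keep_p, , drop = FALSE],
            np, data$site[keep_p], data$area[keep_p])
}

# Brute-force marginal log-likelihood by enumerating z in {0, 1}.
enum_loglik <- function(y, psi, p) {
  p <- rep_len(p, length(y))
  pz1 <- psi * prod(p^y * (1 - p)^(1 - y))
  pz0 <- (1 - psi) * as.numeric(sum(y) == 0)
  log(pz1 + pz0)
}
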