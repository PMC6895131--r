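# Small-but-real MCMC fits; sizes chosen to finish in seconds while leaving
# enough information for the posterior checks. The heavier replicate-based
# calibration experiments live in test-acceptance.R.

test_that("intercept-only truth is recovered within posterior uncertainty", {
  md <- make_toy_data(n_periods = 500, J = 4, n_site = 100, seed = 71)
  tp <- true_params(alpha = rep(0, 7), beta = rep(0, 6),
                    sigma_site = 0, sigma_area = 0)
  sim <- simulate_detections(md, tp, seed = 72)
  fit <- fit_occupancy(md, sim$y, seed = 73)
  s <- summary(fit)
  expect_lt(abs(s$mean[s$param == "alpha0"]), 0.25)
  expect_lt(abs(s$mean[s$param == "beta0"]), 0.25)
  expect_true(all(s$rhat[grepl("^alpha|^beta", s$param)] < 1.1))
})

test_that("duplicating every period shrinks posterior uncertainty", {
  md <- make_toy_data(n_periods = 150, J = 4, n_site = 50, seed = 74)
  tp <- true_params(alpha = c(0.3, rep(0, 6)), beta = c(0.2, rep(0, 5)),
                    sigma_site = 0, sigma_area = 0)
  sim <- simulate_detections(md, tp, seed = 75)
  fit1 <- fit_occupancy(md, sim$y, seed = 76)
  md2 <- occu_data(rbind(md$X_det, md$X_det), rbind(md$X_occ, md$X_occ),
                   c(md$night_period, md$night_period + md$n_periods),
                   c(md$site, md$site), c(md$area, md$area))
  fit2 <- fit_occupancy(md2, c(sim$y, sim$y), seed = 76)
  s1 <- summary(fit1)
  s2 <- summary(fit2)
  for (pp in c("alpha0", "beta0")) {
    expect_lt(s2$sd[s2$param == pp], s1$sd[s1$param == pp])
  }
})

test_that("stored pointwise log-likelihood matches the R reference at draws", {
  md <- make_toy_data(n_periods = 60, J = 3, n_site = 20, seed = 77)
  tp <- true_params(alpha = recovery_alpha, beta = recovery_beta)
  sim <- simulate_detections(md, tp, seed = 78)
  fit <- suppressWarnings(
    fit_occupancy(md, sim$y, chains = 2, iter = 400, warmup = 200, seed = 79))
  for (dr in c(1, 57, 311)) {
    th <- fit$draws[dr, ]
    params <- list(
      alpha = unname(th[1:7]), beta = unname(th[8:13]),
      u_site = unname(th[13 + seq_len(md$n_site)]),
      u_area = unname(th[13 + md$n_site + seq_len(md$n_area)]))
    expect_equal(unname(fit$loglik[dr, ]),
                 occu_pointwise_loglik(params, md, sim$y),
                 tolerance = 1e-10)
  }
})

test_that("stored conditional occurrence draws obey Bayes rule", {
  md <- make_toy_data(n_periods = 40, J = 3, n_site = 10, seed = 80)
  tp <- true_params(alpha = recovery_alpha, beta = recovery_beta)
  sim <- simulate_detections(md, tp, seed = 81)
  fit <- suppressWarnings(
    fit_occupancy(md, sim$y, chains = 2, iter = 300, warmup = 150, seed = 82))
  detected <- tapply(sim$y, md$night_period, max) == 1
  expect_true(all(fit$pz[, detected] == 1))
  dr <- 42
  th <- fit$draws[dr, ]
  params <- list(
    alpha = unname(th[1:7]), beta = unname(th[8:13]),
    u_site = unname(th[13 + seq_len(md$n_site)]),
    u_area = unname(th[13 + md$n_site + seq_len(md$n_area)]))
  p <- plogis(drop(md$X_det %*% params$alpha))
  psi <- plogis(drop(md$X_occ %*% params$beta) +
                  params$u_site[md$site] + params$u_area[md$area])
  i <- which(!detected)[1]
  expect_equal(fit$pz[dr, i],
               conditional_occurrence_prob(sim$y[md$night_period == i],
                                           psi[i], p[md$night_period == i]),
               tolerance = 1e-10)
})

test_that("all-positive histories drive the occupancy posterior upward", {
  md <- make_toy_data(n_periods = 80, J = 8, n_site = 20, seed = 83)
  md$X_det[, -1] <- 0
  md$X_occ[, -1] <- 0
  fit <- suppressWarnings(
    fit_occupancy(md, rep(1, md$n_nights), chains = 2, iter = 600,
                  warmup = 300, seed = 84))
  # every period detected every night: psi posterior concentrates near 1
  expect_gt(mean(plogis(fit$draws[, "beta0"])), 0.9)
})

test_that("fit validates inputs", {
  md <- make_toy_data(n_periods = 10, J = 2, seed = 85)
  y <- rep(0, md$n_nights)
  expect_error(fit_occupancy(md, y, chains = 1), class = "fireocc_invalid_argument")
  expect_error(fit_occupancy(md, y[-1]), class = "fireocc_shape")
  expect_error(fit_occupancy(md, replace(y, 3, 2)), class = "fireocc_validation")
})
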