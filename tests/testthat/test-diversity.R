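# Minimal stand-in for an occu_fit carrying just what diversity needs:
# occurrence-coefficient draws, conditional-z draws and scale metadata.
fake_fit <- function(beta = matrix(0, 50, 6), pz = NULL,
                     sev_center = 50, sev_scale = 25) {
  colnames(beta) <- paste0("beta", 0:5)
  structure(list(draws = beta, pz = pz,
                 centers = list(sev = sev_center),
                 scales = list(sev = sev_scale),
                 radius = 250),
            class = "occu_fit")
}

test_that("S identical psi = 0.5 species give richness S/2 with zero width", {
  fits <- replicate(6, fake_fit(), simplify = FALSE)
  rs <- richness_curve(fits, severity = c(0, 50, 100))
  expect_true(all(rs$mean == 3))
  expect_true(all(rs$lo90 == 3 & rs$hi90 == 3))
})

test_that("richness matches the closed form sum of inverse-logit curves", {
  set.seed(101)
  betas <- lapply(1:3, function(s) rnorm(6, 0, 0.8))
  fits <- lapply(betas, function(b)
    fake_fit(matrix(b, nrow = 40, ncol = 6, byrow = TRUE)))
  sev <- seq(0, 100, by = 10)
  rs <- richness_curve(fits, severity = sev, pyro_levels = c(-2, 0, 2))
  sev_z <- (sev - 50) / 25
  for (pl in c(-2, 0, 2)) {
    direct <- Reduce(`+`, lapply(betas, function(b)
      plogis(b[1] + b[4] * sev_z + b[5] * sev_z^2 + b[6] * pl)))
    expect_equal(rs$mean[rs$pyro_level == pl], direct, tolerance = 1e-12)
  }
})

test_that("richness draws are bounded by the species count", {
  set.seed(102)
  fits <- replicate(5, fake_fit(matrix(rnorm(40 * 6, 0, 2), 40, 6)),
                    simplify = FALSE)
  rs <- richness_curve(fits, severity = seq(0, 100, 20))
  draws <- attr(rs, "draws")
  expect_true(all(draws >= 0 & draws <= 5))
  expect_true(all(rs$lo90 <= rs$hi90))
})

test_that("collapsing draws to their mean never widens richness intervals", {
  set.seed(103)
  fits <- replicate(4, fake_fit(matrix(rnorm(60 * 6, 0, 1), 60, 6)),
                    simplify = FALSE)
  rs <- richness_curve(fits, severity = seq(0, 100, 25))
  fits_pt <- lapply(fits, function(f)
    fake_fit(matrix(colMeans(f$draws), 60, 6, byrow = TRUE)))
  rs_pt <- richness_curve(fits_pt, severity = seq(0, 100, 25))
  expect_true(all((rs_pt$hi90 - rs_pt$lo90) <= (rs$hi90 - rs$lo90) + 1e-12))
})

test_that("severity grid outside [0,100] is a domain error", {
  expect_error(richness_curve(list(fake_fit()), severity = c(-5, 50)),
               class = "fireocc_domain")
})

test_that("jaccard dissimilarity handles the standard set fixtures", {
  expect_equal(jaccard_dissimilarity(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(jaccard_dissimilarity(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(jaccard_dissimilarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(jaccard_dissimilarity(c(0, 0), c(0, 0)), 0)
  expect_error(jaccard_dissimilarity(c(0.5, 1), c(1, 0)),
               class = "fireocc_validation")
  expect_error(jaccard_dissimilarity(c(0, 1), c(1, 0, 1)),
               class = "fireocc_shape")
})

test_that("pairwise jaccard matrix matches vegan and the scalar function", {
  set.seed(104)
  Z <- matrix(rbinom(12 * 8, 1, 0.5), 12, 8)
  Z[3, ] <- 0  # one empty community
  D <- jaccard_matrix(Z)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  for (a in 1:11) for (b in (a + 1):12) {
    expect_equal(D[a, b], jaccard_dissimilarity(Z[a, ], Z[b, ]))
  }
  # cross-check against vegan on the non-empty rows (vegan's binary jaccard)
  nz <- rowSums(Z) > 0
  Dv <- as.matrix(vegan::vegdist(Z[nz, ], method = "jaccard", binary = TRUE))
  expect_equal(unname(D[nz, nz]), unname(Dv), tolerance = 1e-12)
})

test_that("jaccard obeys symmetry and the triangle inequality", {
  set.seed(105)
  Z <- matrix(rbinom(10 * 6, 1, 0.4), 10, 6)
  D <- jaccard_matrix(Z)
  for (a in 1:10) for (b in 1:10) for (c in 1:10) {
    expect_lte(D[a, b], D[a, c] + D[c, b] + 1e-12)
  }
})

test_that("occurrence draws are deterministic where the species was detected", {
  pz <- matrix(c(1, 1, 0.2, 0.7), nrow = 2, ncol = 2, byrow = FALSE)
  fits <- list(a = fake_fit(pz = pz), b = fake_fit(pz = matrix(1, 2, 2)))
  set.seed(106)
  Z <- draw_occurrence_matrix(fits, 1)
  expect_equal(dim(Z), c(2, 2))
  expect_equal(unname(Z[1, "a"]), 1)
  expect_true(all(Z[, "b"] == 1))
  expect_error(draw_occurrence_matrix(fits, 99), class = "fireocc_shape")
})

test_that("never-detected conditional z frequency matches Bayes arithmetic", {
  # psi = 0.5, p = 0.5, J = 2: P(z=1 | y=0) = 0.125 / 0.625 = 0.2
  pzval <- conditional_occurrence_prob(c(0, 0), 0.5, 0.5)
  expect_equal(pzval, 0.2)
  fits <- list(a = fake_fit(pz = matrix(pzval, 4000, 1)))
  set.seed(107)
  zs <- vapply(1:4000, function(d) draw_occurrence_matrix(fits, d)[1, 1],
               numeric(1))
  expect_lt(abs(mean(zs) - 0.2), 3 * sqrt(0.2 * 0.8 / 4000))
})

test_that("identical communities give sentinel correlation and zero means", {
  Z <- matrix(1, 6, 4)
  st <- beta_stats(jaccard_matrix(Z), severity = c(0, 10, 30, 60, 80, 95))
  expect_true(is.na(st$correlation))
  expect_true(all(st$group_means == 0, na.rm = TRUE))
})

test_that("perfect two-cluster structure yields correlation 1", {
  Z <- rbind(matrix(rep(c(1, 1, 0, 0), 3), 3, 4, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 1), 3), 3, 4, byrow = TRUE))
  sev <- c(0, 0, 0, 100, 100, 100)
  expect_warning(st <- beta_stats(jaccard_matrix(Z), sev), "empty severity")
  expect_equal(st$correlation, 1)
  expect_equal(st$group_means["unchanged", "unchanged"], 0)
  expect_equal(st$group_means["high", "high"], 0)
  expect_equal(st$group_means["unchanged", "high"], 1)
})

test_that("beta statistics match a brute-force O(n^2) oracle", {
  set.seed(108)
  n <- 12
  Z <- matrix(rbinom(n * 7, 1, 0.5), n, 7)
  sev <- runif(n, 0, 100)
  st <- suppressWarnings(beta_stats(jaccard_matrix(Z), sev))
  dv <- c()
  sv <- c()
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    dv <- c(dv, jaccard_dissimilarity(Z[a, ], Z[b, ]))
    sv <- c(sv, abs(sev[a] - sev[b]))
  }
  expect_equal(st$correlation, cor(dv, sv), tolerance = 1e-12)
  cls <- as.integer(severity_class(sev))
  for (g1 in 1:4) for (g2 in 1:4) {
    sel <- c()
    k <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      k <- k + 1
      if ((cls[a] == g1 && cls[b] == g2) || (cls[a] == g2 && cls[b] == g1))
        sel <- c(sel, k)
    }
    if (length(sel))
      expect_equal(unname(st$group_means[g1, g2]), mean(dv[sel]),
                   tolerance = 1e-12)
  }
})

test_that("severity classes use the documented half-open boundaries", {
  cls <- severity_class(c(0, 1, 25, 25.1, 75, 75.1, 100))
  expect_equal(as.character(cls),
               c("unchanged", "low", "low", "moderate", "moderate",
                 "high", "high"))
})

test_that("perfect detection makes posterior beta diversity equal raw data", {
  # p = 1 and every species detected where present: pz draws equal the
  # raw detection-derived occurrence, so the summaries coincide
  set.seed(109)
  n <- 10
  Zobs <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  fits <- lapply(1:5, function(s)
    fake_fit(pz = matrix(Zobs[, s], 200, n, byrow = TRUE)))
  names(fits) <- paste0("sp", 1:5)
  sev <- seq(0, 90, by = 10)
  bs <- beta_summary(fits, sev, n_draws = 20, seed = 110)
  st <- beta_stats(jaccard_matrix(Zobs), sev)
  expect_equal(bs$correlation, st$correlation, tolerance = 1e-12)
  expect_equal(bs$correlation_point, st$correlation, tolerance = 1e-12)
})
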