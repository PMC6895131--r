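# hand-built landscape for exactly controlled buffer contents
manual_landscape <- function(mat, cell_m = 10) {
  structure(list(severity = mat, perimeter = matrix(TRUE, nrow(mat), ncol(mat)),
                 cell_m = cell_m,
                 fire_centers = matrix(c(1, 1), 1, 2),
                 extent_m = nrow(mat) * cell_m),
            class = "fire_landscape")
}

test_that("buffer over a uniform landscape returns (value, 0)", {
  l <- manual_landscape(matrix(40, 9, 9))
  bs <- buffer_stats(l, c(45, 45), 30)
  expect_equal(unname(bs), c(40, 0))
})

test_that("two-point symmetric buffer matches the population-SD convention", {
  # two cells at 0 and 100: population SD 50, sample SD 100/sqrt(2)
  l <- manual_landscape(matrix(c(0, 100), 1, 2), cell_m = 10)
  l$severity <- matrix(c(0, 100), 2, 1)  # column layout: centres 5 and 15
  expect_equal(unname(buffer_stats(l, c(10, 5), 8, sd_type = "population")),
               c(50, 50))
  expect_equal(unname(buffer_stats(l, c(10, 5), 8, sd_type = "sample")),
               c(50, 100 / sqrt(2)))
})

test_that("full-coverage buffer reproduces direct mean/SD of all cells", {
  set.seed(21)
  vals <- matrix(runif(25, 0, 100), 5, 5)
  l <- manual_landscape(vals, cell_m = 10)
  bs <- buffer_stats(l, c(25, 25), 1000)
  expect_equal(bs[["mean"]], mean(vals))
  expect_equal(bs[["sd"]], sd(as.vector(vals)))
})

test_that("empty buffers and bad radii are rejected", {
  l <- manual_landscape(matrix(1, 5, 5), cell_m = 10)
  expect_error(buffer_stats(l, c(-500, -500), 20), class = "fireocc_empty_buffer")
  expect_error(buffer_stats(l, c(25, 25), 0), class = "fireocc_invalid_argument")
})

test_that("buffer stats scale linearly with the landscape", {
  set.seed(22)
  vals <- matrix(runif(64, 0, 50), 8, 8)
  l1 <- manual_landscape(vals, cell_m = 10)
  l2 <- manual_landscape(2 * vals, cell_m = 10)
  for (r in c(15, 25, 40)) {
    b1 <- buffer_stats(l1, c(40, 40), r)
    b2 <- buffer_stats(l2, c(40, 40), r)
    expect_equal(unname(b2), 2 * unname(b1))
  }
})

test_that("pyrodiversity residuals vanish for exact quadratic relationships", {
  sev <- seq(0, 100, length.out = 20)
  sev_sd <- 3 + 0.8 * sev - 0.007 * sev^2
  expect_equal(pyrodiversity_residuals(sev, sev_sd), rep(0, 20))
  # three points saturate the quadratic: residuals are identically zero
  expect_equal(pyrodiversity_residuals(c(0, 50, 100), c(0, 50, 0)), rep(0, 3))
})

test_that("pyrodiversity residuals match a hand-rolled normal-equations solve", {
  set.seed(23)
  sev <- runif(50, 0, 100)
  sev_sd <- 5 + 0.6 * sev - 0.005 * sev^2 + rnorm(50, 0, 4)
  X <- cbind(1, sev, sev^2)
  beta <- solve(t(X) %*% X, t(X) %*% sev_sd)
  oracle <- as.vector(sev_sd - X %*% beta)
  expect_equal(pyrodiversity_residuals(sev, sev_sd), oracle, tolerance = 1e-8)
})

test_that("pyrodiversity residuals are orthogonal to {1, sev, sev^2}", {
  set.seed(24)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    sev <- runif(n, 0, 100)
    r <- pyrodiversity_residuals(sev, runif(n, 0, 60))
    expect_lt(abs(sum(r)), 1e-8 * n)
    expect_lt(abs(sum(r * sev)), 1e-8 * n * 100)
    expect_lt(abs(sum(r * sev^2)), 1e-8 * n * 1e4)
  }
})

test_that("degenerate severity designs raise a collinearity error", {
  expect_error(pyrodiversity_residuals(rep(10, 5), runif(5)),
               class = "fireocc_collinear")
  expect_error(pyrodiversity_residuals(1:2, 1:2), class = "fireocc_invalid_argument")
})

test_that("standardize centres and scales with the sample-SD convention", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z$values, c(-1, 0, 1))
  expect_equal(standardize(c(1, 2, 3), sd_type = "population")$values,
               c(-1, 0, 1) * sqrt(3 / 2))
  set.seed(25)
  z2 <- standardize(rnorm(100, 50, 9))
  expect_equal(mean(z2$values), 0, tolerance = 1e-10)
  expect_equal(sd(z2$values), 1, tolerance = 1e-10)
  # idempotence
  z3 <- standardize(z2$values)
  expect_equal(z3$values, z2$values, tolerance = 1e-10)
  expect_error(standardize(rep(2, 10)), class = "fireocc_degenerate_covariate")
})

test_that("model data carries standardized columns and consistent indexing", {
  l <- generate_landscape(grid_size = 100, cell_m = 50, seed = 26)
  d <- sample_design(l, n_sites = 40, n_years = 2, seed = 27)
  covs <- build_covariates(l, d, radii = c(100, 250))
  md <- occu_model_data(d, covs, radius = 100)
  for (cn in c("elevation", "water_distance", "sev", "pyrodiversity")) {
    expect_equal(mean(md$X_occ[, cn]), 0, tolerance = 1e-10)
    expect_equal(sd(md$X_occ[, cn]), 1, tolerance = 1e-10)
  }
  for (cn in c("day", "canopy", "noise", "temperature")) {
    expect_equal(mean(md$X_det[, cn]), 0, tolerance = 1e-10)
    expect_equal(sd(md$X_det[, cn]), 1, tolerance = 1e-10)
  }
  expect_equal(md$X_occ[, "sev2"], unname(md$X_occ[, "sev"]^2))
  expect_true(all(md$X_det[, "smm"] %in% 0:1))
  expect_equal(md$n_nights, nrow(d$nights))
  expect_equal(md$n_periods, nrow(d$periods))
})
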