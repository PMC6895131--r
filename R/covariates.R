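#' Buffer statistics of burn severity around a point
#'
#' Mean and SD of percent basal-area mortality over all raster cells whose
#' centres fall within `radius_m` of the point. Cell membership is by
#' centre-in-circle. The SD convention is sample (n-1) by default, matching
#' the standardization convention used elsewhere in the package; population
#' SD is available for reproducing alternative conventions. A single-cell
#' buffer has SD 0.
#'
#' @param landscape A `fire_landscape`.
#' @param site_xy Numeric length-2 vector (x, y) in metres, or an n x 2
#'   matrix of points.
#' @param radius_m Buffer radius in metres.
#' @param sd_type `"sample"` (n-1 denominator) or `"population"` (n).
#'
#' @return For one point, named vector `c(mean, sd)`; for a matrix of
#'   points, a data.frame with columns `mean` and `sd`.
#' @export
buffer_stats <- function(landscape, site_xy, radius_m,
                         sd_type = c("sample", "population")) {
  stopifnot(inherits(landscape, "fire_landscape"))
  sd_type <- match.arg(sd_type)
  if (radius_m <= 0)
    fireocc_error("fireocc_invalid_argument", "radius_m must be positive")
  if (is.matrix(site_xy)) {
    out <- t(apply(site_xy, 1, function(p)
      buffer_stats(landscape, p, radius_m, sd_type)))
    return(data.frame(mean = out[, 1], sd = out[, 2]))
  }
  g <- nrow(landscape$severity)
  xy <- cell_centers(g, landscape$cell_m)
  inside <- (xy[, 1] - site_xy[1])^2 + (xy[, 2] - site_xy[2])^2 <= radius_m^2
  if (!any(inside))
    fireocc_error("fireocc_empty_buffer",
                  "buffer intersects no raster cell centres")
  vals <- as.vector(landscape$severity)[inside]
  s <- if (length(vals) < 2) 0
       else if (sd_type == "sample") sd(vals)
       else sqrt(mean((vals - mean(vals))^2))
  c(mean = mean(vals), sd = s)
}

#' Pyrodiversity as residual variation in burn severity
#'
#' Pyrodiversity is the heterogeneity of burn severity around a point after
#' removing its strong dependence on mean severity: the residuals of an OLS
#' regression of the buffer SD of severity on mean severity and its square
#' (with intercept). Residuals sum to zero and are orthogonal to both
#' regressors.
#'
#' @param sev_vec Mean severity per unit (e.g. survey period).
#' @param sev_sd_vec Buffer SD of severity for the same units.
#' @return Numeric vector of residuals (the pyrodiversity index, unitless).
#' @export
#' @examples
#' sev <- c(0, 20, 40, 60, 80, 100)
#' pyrodiversity_residuals(sev, 2 + 0.5 * sev - 0.004 * sev^2)
pyrodiversity_residuals <- function(sev_vec, sev_sd_vec) {
  if (length(sev_vec) != length(sev_sd_vec))
    fireocc_error("fireocc_shape", "sev and sev_sd must have equal length")
  if (length(sev_vec) < 3)
    fireocc_error("fireocc_invalid_argument", "need at least 3 observations")
  if (!all(is.finite(sev_vec)) || !all(is.finite(sev_sd_vec)))
    fireocc_error("fireocc_invalid_argument", "inputs must be finite")
  X <- cbind(1, sev_vec, sev_vec^2)
  if (qr(X)$rank < 3L)
    fireocc_error("fireocc_collinear",
                  "severity values give a rank-deficient quadratic design (are all sev equal?)")
  unname(lm.fit(X, sev_sd_vec)$residuals)
}

#' Standardize a covariate to mean 0, SD 1
#'
#' Sample-SD (n-1) scaling by default. The centre and scale are returned so
#' model predictions can be mapped back to natural units.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @param sd_type `"sample"` or `"population"`.
#' @return List with `values` (standardized), `center`, `scale`.
#' @export
standardize <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(values) < 2)
    fireocc_error("fireocc_invalid_argument", "need at least 2 values")
  if (!all(is.finite(values)))
    fireocc_error("fireocc_invalid_argument", "values must be finite")
  center <- mean(values)
  scale <- if (sd_type == "sample") sd(values)
           else sqrt(mean((values - center)^2))
  if (scale == 0)
    fireocc_error("fireocc_degenerate_covariate",
                  "constant covariate cannot be standardized")
  list(values = (values - center) / scale, center = center, scale = scale)
}

#' Multi-scale severity covariates for all sites
#'
#' Computes `sev_<r>` and `sev_sd_<r>` (buffer mean and SD of percent
#' basal-area mortality) for each site at each radius.
#'
#' @param landscape A `fire_landscape`.
#' @param design A `survey_design`.
#' @param radii Buffer radii in metres.
#' @param sd_type SD convention, see [buffer_stats()].
#' @return `design$sites` with the severity columns appended.
#' @export
build_covariates <- function(landscape, design, radii = c(50, 100, 250, 500),
                             sd_type = "sample") {
  sites <- design$sites
  xy <- cbind(sites$x_m, sites$y_m)
  for (r in radii) {
    bs <- buffer_stats(landscape, xy, r, sd_type)
    sites[[paste0("sev_", r)]] <- bs$mean
    sites[[paste0("sev_sd_", r)]] <- bs$sd
  }
  sites
}

#' Construct model-ready data for the occupancy likelihood
#'
#' Low-level constructor used both by [occu_model_data()] and directly in
#' tests or with user-supplied matrices. Rows of `X_det` are survey nights;
#' rows of `X_occ` are survey periods. First columns of each are expected to
#' be an intercept.
#'
#' @param X_det Night-level detection design matrix.
#' @param X_occ Period-level occurrence design matrix.
#' @param night_period Integer vector mapping each night (row of `X_det`)
#'   to its period (row of `X_occ`).
#' @param site,area Integer vectors mapping each period to its site and
#'   fire-area random-intercept group.
#' @param centers,scales Optional named lists of standardization constants.
#' @param radius Optional buffer radius (m) the covariates were built at.
#' @return An object of class `occu_data`.
#' @export
occu_data <- function(X_det, X_occ, night_period, site, area,
                      centers = list(), scales = list(), radius = NA_real_) {
  X_det <- as.matrix(X_det)
  X_occ <- as.matrix(X_occ)
  night_period <- as.integer(night_period)
  site <- as.integer(site)
  area <- as.integer(area)
  n_periods <- nrow(X_occ)
  if (length(night_period) != nrow(X_det))
    fireocc_error("fireocc_shape", "night_period must have one entry per row of X_det")
  if (any(night_period < 1L) || any(night_period > n_periods))
    fireocc_error("fireocc_shape", "night_period indexes outside X_occ rows")
  if (length(site) != n_periods || length(area) != n_periods)
    fireocc_error("fireocc_shape", "site/area must have one entry per period")
  if (anyNA(X_det) || anyNA(X_occ))
    fireocc_error("fireocc_validation", "NaN/NA in covariates")
  structure(list(
    X_det = X_det, X_occ = X_occ, night_period = night_period,
    site = site, area = area,
    n_site = max(site), n_area = max(area),
    n_periods = n_periods, n_nights = nrow(X_det),
    centers = centers, scales = scales, radius = radius
  ), class = "occu_data")
}

#' Build standardized design matrices at one spatial scale
#'
#' Assembles the detection design matrix (intercept, day, day^2, canopy,
#' noise, temperature, microphone indicator) and the occurrence design
#' matrix (intercept, elevation, water distance, severity, severity^2,
#' pyrodiversity) from a survey design and its site covariate table.
#' All continuous predictors are standardized to mean 0 / SD 1 across the
#' rows of the matrix they enter; the binary microphone flag is left as
#' 0/1. Quadratic terms are squares of the standardized linear terms. The
#' pyrodiversity residual regression is fitted across all survey periods
#' entering the model (unburned periods included at sev = sev_sd = 0).
#'
#' @param design A `survey_design`.
#' @param site_covs Site table with `sev_<radius>` / `sev_sd_<radius>`
#'   columns, from [build_covariates()] (or read from file).
#' @param radius Buffer radius (m) selecting which severity columns to use.
#' @param sd_type SD convention for standardization.
#' @return An `occu_data` object with named columns and stored
#'   centers/scales for back-transformation.
#' @export
occu_model_data <- function(design, site_covs, radius = 250,
                            sd_type = "sample") {
  stopifnot(inherits(design, "survey_design"))
  sev_col <- paste0("sev_", radius)
  sd_col <- paste0("sev_sd_", radius)
  if (!all(c(sev_col, sd_col) %in% names(site_covs)))
    fireocc_error("fireocc_invalid_argument",
                  sprintf("site_covs lacks %s/%s columns", sev_col, sd_col))
  periods <- design$periods
  nights <- design$nights
  srow <- match(periods$site_id, site_covs$site_id)

  # occurrence covariates at the period level
  sev <- site_covs[[sev_col]][srow]
  sev_sd <- site_covs[[sd_col]][srow]
  pyro <- pyrodiversity_residuals(sev, sev_sd)
  centers <- list()
  scales <- list()
  zf <- function(x, name) {
    z <- standardize(x, sd_type)
    centers[[name]] <<- z$center
    scales[[name]] <<- z$scale
    z$values
  }
  elev_z <- zf(site_covs$elevation[srow], "elevation")
  water_z <- zf(site_covs$water_distance[srow], "water_distance")
  sev_z <- zf(sev, "sev")
  pyro_z <- zf(pyro, "pyrodiversity")
  X_occ <- cbind(intercept = 1, elevation = elev_z, water_distance = water_z,
                 sev = sev_z, sev2 = sev_z^2, pyrodiversity = pyro_z)

  # detection covariates at the night level
  prow <- match(nights$period_id, periods$period_id)
  day_z <- zf(nights$day, "day")
  canopy_z <- zf(periods$canopy[prow], "canopy")
  noise_z <- zf(nights$noise, "noise")
  temp_z <- zf(nights$temperature, "temperature")
  X_det <- cbind(intercept = 1, day = day_z, day2 = day_z^2,
                 canopy = canopy_z, noise = noise_z, temperature = temp_z,
                 smm = periods$smm[prow])

  occu_data(X_det, X_occ, night_period = prow,
            site = periods$site_id, area = design$sites$fire_area[periods$site_id],
            centers = centers, scales = scales, radius = radius)
}

#' @export
print.occu_data <- function(x, ...) {
  cat("<occu_data> ", x$n_periods, " periods, ", x$n_nights, " nights, ",
      x$n_site, " sites, ", x$n_area, " fire areas",
      if (!is.na(x$radius)) paste0("; covariate radius ", x$radius, " m"),
      "\n", sep = "")
  invisible(x)
}
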