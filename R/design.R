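#' Distributional settings for the survey-design simulator
#'
#' All distributions that the field campaign does not pin down are declared
#' here so a simulation is fully reproducible from its config. Defaults
#' emulate a multi-year acoustic monitoring campaign: most sites surveyed in
#' one year, a May--September season, low ambient-noise rates, and a mix of
#' two microphone models.
#'
#' @param year_weights Probabilities that a site is surveyed in 1, 2, ...
#'   years (recycled/truncated to `n_years`).
#' @param nights_lambda Poisson rate for nights per survey period, truncated
#'   to `nights_range`; the default gives median 6.
#' @param nights_range Support of the nights-per-period distribution.
#' @param season_length_days Length of the survey season in days.
#' @param night_spacing_days Days between consecutive survey nights
#'   (detectors record on alternate nights).
#' @param canopy_shape Beta shape parameters for canopy cover (scaled to
#'   percent).
#' @param noise_shape Beta shape parameters for the nightly noise rate
#'   (ratio of noise recordings to total, in \[0,1\]).
#' @param temp_mean_c,temp_sd_c Nightly mean temperature distribution (deg C).
#' @param smm_prob Probability a period uses the newer microphone model.
#' @param elev_mean_m,elev_sd_m Site elevation distribution (m).
#' @param water_mean_m Mean distance to perennial water (m, exponential).
#'
#' @return A named list of class `design_config`.
#' @export
design_config <- function(year_weights = c(0.52, 0.31, 0.15, 0.02),
                          nights_lambda = 6, nights_range = c(1L, 17L),
                          season_length_days = 130, night_spacing_days = 2,
                          canopy_shape = c(2, 2), noise_shape = c(1.5, 8),
                          temp_mean_c = 15, temp_sd_c = 5, smm_prob = 0.5,
                          elev_mean_m = 1600, elev_sd_m = 250,
                          water_mean_m = 300) {
  structure(as.list(environment()), class = "design_config")
}

#' Draw nights-per-period counts
#'
#' Truncated Poisson on `range`; the default rate of 6 yields a median of
#' 6 nights per survey period on support 1--17.
#'
#' @param n Number of draws.
#' @param lambda Poisson rate.
#' @param range Integer support bounds (inclusive).
#' @return Integer vector.
#' @export
rnights_truncpois <- function(n, lambda = 6, range = c(1L, 17L)) {
  support <- seq.int(range[1], range[2])
  sample(support, n, replace = TRUE, prob = dpois(support, lambda))
}

#' Simulate a multi-year acoustic survey design on a landscape
#'
#' Places survey sites at least `min_separation_m` apart, assigns each to
#' its nearest fire area, decides which years each site is surveyed, and
#' simulates period-level (canopy, microphone model, nights) and
#' night-level (day-of-season, noise rate, temperature) covariates from the
#' distributions declared in `config`.
#'
#' @param landscape A `fire_landscape`.
#' @param n_sites Number of unique survey locations.
#' @param n_years Number of survey years.
#' @param nights_rule `NULL` for the default truncated-Poisson rule, a
#'   single integer for a fixed number of nights per period, or a
#'   `function(n)` returning integer counts.
#' @param min_separation_m Minimum pairwise distance between sites (m).
#' @param config A [design_config()].
#' @param seed Optional integer seed.
#'
#' @return An object of class `survey_design`: list with data frames
#'   `sites` (site_id, x_m, y_m, elevation, water_distance, fire_area),
#'   `periods` (period_id, site_id, year, canopy, smm, n_nights) and
#'   `nights` (period_id, night_index, day, noise, temperature).
#' @export
sample_design <- function(landscape, n_sites = 122, n_years = 4,
                          nights_rule = NULL, min_separation_m = 500,
                          config = design_config(), seed = NULL) {
  stopifnot(inherits(landscape, "fire_landscape"))
  if (n_sites < 1) fireocc_error("fireocc_invalid_argument", "n_sites must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  xy <- place_sites(landscape$extent_m, n_sites, min_separation_m)
  d2 <- function(c) (xy[, 1] - c[1])^2 + (xy[, 2] - c[2])^2
  dist_by_fire <- sapply(seq_len(nrow(landscape$fire_centers)),
                         function(k) d2(landscape$fire_centers[k, ]))
  fire_area <- max.col(-matrix(dist_by_fire, nrow = n_sites))

  sites <- data.frame(
    site_id = seq_len(n_sites),
    x_m = xy[, 1], y_m = xy[, 2],
    elevation = rnorm(n_sites, config$elev_mean_m, config$elev_sd_m),
    water_distance = rexp(n_sites, 1 / config$water_mean_m),
    fire_area = fire_area
  )

  # which years each site is surveyed
  w <- rep_len(config$year_weights, n_years)
  w <- w / sum(w)
  n_yr_site <- sample.int(n_years, n_sites, replace = TRUE, prob = w)
  period_rows <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
    yrs <- sort(sample.int(n_years, n_yr_site[s]))
    data.frame(site_id = s, year = yrs)
  }))
  n_periods <- nrow(period_rows)

  nights_fun <- resolve_nights_rule(nights_rule, config)
  periods <- data.frame(
    period_id = seq_len(n_periods),
    site_id = period_rows$site_id,
    year = period_rows$year,
    canopy = 100 * rbeta(n_periods, config$canopy_shape[1], config$canopy_shape[2]),
    smm = rbinom(n_periods, 1, config$smm_prob),
    n_nights = as.integer(nights_fun(n_periods))
  )
  if (any(periods$n_nights < 1))
    fireocc_error("fireocc_invalid_argument", "nights_rule produced counts < 1")

  start_max <- max(1, config$season_length_days -
                     config$night_spacing_days * max(periods$n_nights))
  start_day <- runif(n_periods, 1, start_max)
  nights <- do.call(rbind, lapply(seq_len(n_periods), function(i) {
    J <- periods$n_nights[i]
    data.frame(
      period_id = i, night_index = seq_len(J),
      day = start_day[i] + config$night_spacing_days * (seq_len(J) - 1)
    )
  }))
  nights$noise <- rbeta(nrow(nights), config$noise_shape[1], config$noise_shape[2])
  nights$temperature <- rnorm(nrow(nights), config$temp_mean_c, config$temp_sd_c)

  structure(list(sites = sites, periods = periods, nights = nights,
                 config = config, landscape_extent_m = landscape$extent_m),
            class = "survey_design")
}

resolve_nights_rule <- function(nights_rule, config) {
  if (is.null(nights_rule)) {
    function(n) rnights_truncpois(n, config$nights_lambda, config$nights_range)
  } else if (is.function(nights_rule)) {
    nights_rule
  } else if (is.numeric(nights_rule) && length(nights_rule) == 1) {
    function(n) rep.int(as.integer(nights_rule), n)
  } else {
    fireocc_error("fireocc_invalid_argument",
                  "nights_rule must be NULL, a single integer, or a function")
  }
}

place_sites <- function(extent_m, n_sites, min_sep_m, max_tries = 500L) {
  xy <- matrix(NA_real_, n_sites, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n_sites) {
    cand <- runif(2, 0, extent_m)
    ok <- placed == 0L ||
      min((xy[seq_len(placed), 1] - cand[1])^2 +
            (xy[seq_len(placed), 2] - cand[2])^2) >= min_sep_m^2
    if (ok) {
      placed <- placed + 1L
      xy[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries)
        fireocc_error("fireocc_infeasible_design",
                      sprintf("could not place %d sites %g m apart on a %g m extent",
                              n_sites, min_sep_m, extent_m))
    }
  }
  xy
}

#' @export
print.survey_design <- function(x, ...) {
  cat("<survey_design> ", nrow(x$sites), " sites, ", nrow(x$periods),
      " survey periods, ", nrow(x$nights), " survey nights\n", sep = "")
  invisible(x)
}
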