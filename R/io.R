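#' Write a simulated survey to plain-text files
#'
#' Writes `sites.csv`, `nights.csv`, `detections.csv` (long format:
#' species, period_id, site_id, year, night_index, y) and `truth.json`
#' (the generating parameters) to a directory, and the severity raster as
#' `landscape.csv` when a landscape is supplied.
#'
#' @param dir Output directory (created if needed).
#' @param design A `survey_design`.
#' @param sims Named list of `occu_sim` objects (one per species).
#' @param data The `occu_data` the simulations were generated from.
#' @param landscape Optional `fire_landscape`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, design, sims, data, landscape = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(design$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  nights <- design$nights
  write.csv(nights, file.path(dir, "nights.csv"), row.names = FALSE)
  det <- do.call(rbind, lapply(names(sims), function(sp) {
    data.frame(
      species = sp,
      period_id = nights$period_id,
      site_id = design$periods$site_id[nights$period_id],
      year = design$periods$year[nights$period_id],
      night_index = nights$night_index,
      y = sims[[sp]]$y
    )
  }))
  write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  truth <- lapply(sims, function(s) {
    list(alpha = s$params$alpha, beta = s$params$beta,
         sigma_site = s$params$sigma_site, sigma_area = s$params$sigma_area,
         u_site = s$u_site, u_area = s$u_area)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(landscape))
    utils::write.table(landscape$severity, file.path(dir, "landscape.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write standardized covariates for one spatial scale
#'
#' Writes `covariates_<radius>.csv` (design-matrix columns for occurrence
#' and detection) and a `centers_scales_<radius>.json` sidecar holding the
#' standardization constants needed to map predictions back to natural
#' units.
#'
#' @param dir Output directory.
#' @param data An `occu_data` built by [occu_model_data()].
#' @return `dir`, invisibly.
#' @export
write_covariates <- function(dir, data) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- data$radius
  occ <- as.data.frame(data$X_occ)
  occ$period_id <- seq_len(nrow(occ))
  det <- as.data.frame(data$X_det)
  det$period_id <- data$night_period
  write.csv(occ, file.path(dir, sprintf("covariates_occ_%s.csv", r)),
            row.names = FALSE)
  write.csv(det, file.path(dir, sprintf("covariates_det_%s.csv", r)),
            row.names = FALSE)
  jsonlite::write_json(list(centers = data$centers, scales = data$scales),
                       file.path(dir, sprintf("centers_scales_%s.json", r)),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write the species-by-scale LOOIC comparison table
#'
#' @param tab data.frame from [loo_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_loo_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
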