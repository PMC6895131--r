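#' Generate a synthetic burn-severity landscape
#'
#' Simulates a spatially autocorrelated field of burn severity (percent
#' basal-area mortality, 0--100) on a square raster, together with fire
#' perimeters. Severity is produced by smoothing Gaussian white noise with a
#' Gaussian kernel whose bandwidth equals the requested correlation length,
#' rescaling to the target mean and SD, clipping to \[0, 100\], and zeroing
#' all cells outside the fire perimeters (area outside a burn perimeter is
#' unchanged forest, 0% mortality).
#'
#' @param grid_size Cells per side of the square raster (>= 20).
#' @param cell_m Cell edge length in metres.
#' @param spatial_corr_length_m Gaussian smoothing bandwidth in metres;
#'   0 gives per-cell independent values.
#' @param mean_severity,sd_severity Target mean and SD of the severity field
#'   before clipping, in percent basal-area mortality.
#' @param n_fires Number of distinct fire perimeters (fire areas).
#' @param perimeter If `FALSE` the whole raster is treated as burned
#'   (useful for studying the field itself); fire-area membership is then by
#'   nearest fire centre.
#' @param seed Optional integer seed.
#'
#' @return An object of class `fire_landscape`: a list with `severity`
#'   (matrix, percent mortality), `perimeter` (logical matrix), `cell_m`,
#'   `fire_centers` (n_fires x 2, metres) and `extent_m`.
#' @export
#' @examples
#' l <- generate_landscape(grid_size = 40, seed = 1)
#' range(l$severity)
generate_landscape <- function(grid_size = 120, cell_m = 25,
                               spatial_corr_length_m = 100,
                               mean_severity = 40, sd_severity = 30,
                               n_fires = 3, perimeter = TRUE, seed = NULL) {
  if (!is.numeric(grid_size) || grid_size < 20)
    fireocc_error("fireocc_invalid_argument", "grid_size must be >= 20 cells per side")
  if (cell_m <= 0)
    fireocc_error("fireocc_invalid_argument", "cell_m must be positive")
  if (spatial_corr_length_m < 0)
    fireocc_error("fireocc_invalid_argument", "spatial_corr_length_m must be non-negative")
  if (sd_severity < 0)
    fireocc_error("fireocc_invalid_argument", "sd_severity must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  grid_size <- as.integer(grid_size)

  field <- matrix(rnorm(grid_size^2), grid_size, grid_size)
  sigma_cells <- spatial_corr_length_m / cell_m
  field <- smooth_field(field, sigma_cells)

  # rescale smoothed noise to the requested first two moments
  f_sd <- sd(as.vector(field))
  z <- if (f_sd > 0) (field - mean(field)) / f_sd else field * 0
  sev <- mean_severity + sd_severity * z
  sev <- pmin(pmax(sev, 0), 100)

  extent_m <- grid_size * cell_m
  centers <- fire_centers(n_fires, extent_m)
  if (perimeter) {
    mask <- perimeter_mask(grid_size, cell_m, centers, extent_m)
    sev[!mask] <- 0
  } else {
    mask <- matrix(TRUE, grid_size, grid_size)
  }

  structure(list(
    severity = sev, perimeter = mask, cell_m = cell_m,
    fire_centers = centers, extent_m = extent_m
  ), class = "fire_landscape")
}

# Deterministic-ish centres: fixed relative layout with small jitter so the
# three fire areas are well separated on any extent.
fire_centers <- function(n_fires, extent_m) {
  base <- matrix(c(0.28, 0.28,
                   0.72, 0.34,
                   0.46, 0.74,
                   0.75, 0.75,
                   0.25, 0.72), ncol = 2, byrow = TRUE)
  base <- base[rep_len(seq_len(nrow(base)), n_fires), , drop = FALSE]
  jitter <- matrix(runif(2 * n_fires, -0.03, 0.03), ncol = 2)
  (base + jitter) * extent_m
}

perimeter_mask <- function(grid_size, cell_m, centers, extent_m) {
  # disc perimeters, each covering ~15% of the extent
  r <- sqrt(0.15 / pi) * extent_m
  xy <- cell_centers(grid_size, cell_m)
  mask <- rep(FALSE, nrow(xy))
  for (k in seq_len(nrow(centers))) {
    d2 <- (xy[, 1] - centers[k, 1])^2 + (xy[, 2] - centers[k, 2])^2
    mask <- mask | d2 <= r^2
  }
  matrix(mask, grid_size, grid_size)
}

cell_centers <- function(grid_size, cell_m) {
  cc <- (seq_len(grid_size) - 0.5) * cell_m
  cbind(x = rep(cc, times = grid_size), y = rep(cc, each = grid_size))
}

# separable Gaussian smoothing with edge renormalisation
smooth_field <- function(mat, sigma_cells) {
  if (sigma_cells <= 0) return(mat)
  half <- max(1L, as.integer(ceiling(3 * sigma_cells)))
  k <- dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  mat <- apply(mat, 2, conv_norm, k = k)
  t(apply(mat, 1, conv_norm, k = k))
}

conv_norm <- function(x, k) {
  half <- (length(k) - 1L) / 2L
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, length(x)), rep(0, half))
  num <- convolve(xp, k, type = "filter")
  den <- convolve(wp, k, type = "filter")
  num / den
}

#' Lag-k spatial autocorrelation of a severity field
#'
#' Pearson correlation between the field and itself shifted by `lag` cells,
#' averaged over the horizontal and vertical directions. A cheap stand-in
#' for a Moran's I profile, used to verify the generator's autocorrelation
#' structure.
#'
#' @param mat Numeric matrix (e.g. `landscape$severity`).
#' @param lag Shift in cells (>= 1).
#' @return Correlation in \[-1, 1\].
#' @export
field_autocorr <- function(mat, lag = 1L) {
  stopifnot(is.matrix(mat), lag >= 1, ncol(mat) > lag, nrow(mat) > lag)
  n <- ncol(mat)
  h <- cor(as.vector(mat[, seq_len(n - lag)]), as.vector(mat[, -seq_len(lag)]))
  v <- cor(as.vector(mat[seq_len(n - lag), ]), as.vector(mat[-seq_len(lag), ]))
  mean(c(h, v))
}

#' @export
print.fire_landscape <- function(x, ...) {
  cat("<fire_landscape> ", nrow(x$severity), "x", ncol(x$severity),
      " cells (", x$cell_m, " m); ", nrow(x$fire_centers), " fire area(s); ",
      "severity range ", paste(round(range(x$severity), 1), collapse = "-"),
      "%\n", sep = "")
  invisible(x)
}
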