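#' Posterior richness surface over severity and pyrodiversity
#'
#' Expected species richness is the sum over species of the posterior
#' occupancy probability, evaluated on a grid of burn severity (percent
#' basal-area mortality, natural units) crossed with pyrodiversity held at
#' fixed standardized levels (default -2, 0, +2 SD), with all other
#' covariates at their means (standardized 0) and random intercepts at 0
#' (population-level prediction). Uncertainty is propagated by evaluating
#' every posterior draw of every species' occurrence coefficients.
#'
#' @param fits Named list of `occu_fit` objects, one per species, all at a
#'   common covariate radius.
#' @param severity Severity grid in percent (0--100).
#' @param pyro_levels Pyrodiversity levels in standardized SD units.
#' @return data.frame of class `richness_surface`: severity, pyro_level,
#'   mean, lo90, hi90; attribute `draws` holds the full draws array
#'   (draws x grid point).
#' @export
richness_curve <- function(fits, severity = seq(0, 100, by = 5),
                           pyro_levels = c(-2, 0, 2)) {
  if (any(severity < 0 | severity > 100))
    fireocc_error("fireocc_domain", "severity must be within [0, 100] percent")
  radii <- vapply(fits, `[[`, numeric(1), "radius")
  if (length(unique(radii[!is.na(radii)])) > 1)
    warning("species fits use different covariate radii", call. = FALSE)
  f1 <- fits[[1]]
  ctr <- f1$centers$sev %||% 0
  scl <- f1$scales$sev %||% 1
  sev_z <- (severity - ctr) / scl

  grid <- expand.grid(severity = severity, pyro_level = pyro_levels)
  n_draws <- min(vapply(fits, function(f) nrow(f$draws), numeric(1)))
  rich <- matrix(0, n_draws, nrow(grid))
  for (f in fits) {
    b <- f$draws[seq_len(n_draws),
                 c("beta0", "beta3", "beta4", "beta5"), drop = FALSE]
    eta <- b[, "beta0"] %*% t(rep(1, nrow(grid))) +
      b[, "beta3"] %*% t((grid$severity - ctr) / scl) +
      b[, "beta4"] %*% t(((grid$severity - ctr) / scl)^2) +
      b[, "beta5"] %*% t(grid$pyro_level)
    rich <- rich + plogis(eta)
  }
  out <- data.frame(
    severity = grid$severity, pyro_level = grid$pyro_level,
    mean = colMeans(rich),
    lo90 = apply(rich, 2, quantile, 0.05),
    hi90 = apply(rich, 2, quantile, 0.95)
  )
  attr(out, "draws") <- rich
  class(out) <- c("richness_surface", "data.frame")
  out
}

#' Draw a detection-corrected occurrence matrix from the posterior
#'
#' For each species and survey period, the latent occurrence state is drawn
#' from its conditional distribution given the data: z = 1 with probability
#' 1 where the species was detected, otherwise with probability
#' psi prod(1-p) / (psi prod(1-p) + 1 - psi), evaluated at the requested
#' posterior draw.
#'
#' @param fits Named list of `occu_fit` objects over the same periods.
#' @param draw_index Posterior draw to condition on (valid for all species).
#' @return Binary matrix, periods x species.
#' @export
draw_occurrence_matrix <- function(fits, draw_index) {
  n_per <- unique(vapply(fits, function(f) ncol(f$pz), numeric(1)))
  if (length(n_per) != 1)
    fireocc_error("fireocc_shape", "species fits cover different periods")
  if (draw_index < 1 || any(vapply(fits, function(f) nrow(f$pz), numeric(1)) < draw_index))
    fireocc_error("fireocc_shape", "draw_index out of range for some species")
  Z <- matrix(NA_real_, n_per, length(fits),
              dimnames = list(NULL, names(fits)))
  for (s in seq_along(fits)) {
    pz <- fits[[s]]$pz[draw_index, ]
    Z[, s] <- rbinom(length(pz), 1, pz)
  }
  Z
}

#' Jaccard dissimilarity between two communities
#'
#' 1 minus shared species over the union of species. Two empty communities
#' are defined as identical (dissimilarity 0); this convention differs
#' between software packages and is flagged here so users can account
#' for it.
#'
#' @param occ_row_a,occ_row_b Equal-length binary occurrence vectors.
#' @return Dissimilarity in \[0, 1\].
#' @export
#' @examples
#' jaccard_dissimilarity(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 0.5
jaccard_dissimilarity <- function(occ_row_a, occ_row_b) {
  if (length(occ_row_a) != length(occ_row_b))
    fireocc_error("fireocc_shape", "occurrence vectors must have equal length")
  if (!all(occ_row_a %in% c(0, 1)) || !all(occ_row_b %in% c(0, 1)))
    fireocc_error("fireocc_validation", "occurrence vectors must be binary")
  u <- sum(occ_row_a == 1 | occ_row_b == 1)
  if (u == 0) return(0)
  1 - sum(occ_row_a == 1 & occ_row_b == 1) / u
}

#' Pairwise Jaccard dissimilarity matrix
#'
#' @param Z Binary matrix, units (e.g. survey periods) x species.
#' @return Symmetric dissimilarity matrix with zero diagonal; pairs of
#'   empty communities get 0.
#' @export
jaccard_matrix <- function(Z) {
  Z <- as.matrix(Z)
  if (!all(Z %in% c(0, 1)))
    fireocc_error("fireocc_validation", "occurrence matrix must be binary")
  inter <- tcrossprod(Z)
  n <- rowSums(Z)
  uni <- outer(n, n, "+") - inter
  D <- 1 - inter / uni
  D[uni == 0] <- 0
  diag(D) <- 0
  unname(D)
}

#' Severity classes of survey periods
#'
#' Unchanged (0%), low (0, 25\]%, moderate (25, 75\]%, high (> 75%) percent
#' basal-area mortality.
#'
#' @param severity Percent basal-area mortality per unit.
#' @return Factor with levels unchanged/low/moderate/high.
#' @export
severity_class <- function(severity) {
  cls <- cut(severity, breaks = c(-Inf, 0, 25, 75, Inf),
             labels = c("unchanged", "low", "moderate", "high"))
  factor(cls, levels = c("unchanged", "low", "moderate", "high"))
}

#' Beta-diversity statistics of one occurrence matrix
#'
#' Computes, for a single (drawn or observed) occurrence matrix: the
#' Pearson correlation between pairwise Jaccard dissimilarity and pairwise
#' severity distance |sev_a - sev_b|, and mean dissimilarities within and
#' between severity classes.
#'
#' @param D Pairwise Jaccard dissimilarity matrix (from [jaccard_matrix()]),
#'   or a binary occurrence matrix (converted automatically).
#' @param severity Percent basal-area mortality per unit.
#' @return List with `correlation` (NA when dissimilarities are constant),
#'   and `group_means` (4 x 4 matrix over severity classes; NA for empty
#'   classes).
#' @export
beta_stats <- function(D, severity) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isSymmetric(unname(D)))
    D <- jaccard_matrix(D)
  n <- nrow(D)
  if (length(severity) != n)
    fireocc_error("fireocc_shape", "severity must have one value per unit")
  ut <- upper.tri(D)
  dvec <- D[ut]
  sdist <- abs(outer(severity, severity, "-"))[ut]
  correlation <- if (sd(dvec) == 0 || sd(sdist) == 0) NA_real_
                 else cor(dvec, sdist)
  cls <- severity_class(severity)
  lev <- levels(cls)
  gm <- matrix(NA_real_, 4, 4, dimnames = list(lev, lev))
  ci <- as.integer(cls)
  pair_a <- row(D)[ut]
  pair_b <- col(D)[ut]
  for (a in 1:4) for (b in a:4) {
    sel <- (ci[pair_a] == a & ci[pair_b] == b) |
           (ci[pair_a] == b & ci[pair_b] == a)
    if (any(sel)) gm[a, b] <- gm[b, a] <- mean(dvec[sel])
  }
  empty <- setdiff(lev, levels(droplevels(cls)))
  if (length(empty))
    warning("empty severity class(es): ", paste(empty, collapse = ", "),
            call. = FALSE)
  list(correlation = correlation, group_means = gm)
}

#' Posterior beta diversity of the community
#'
#' Draws detection-corrected occurrence matrices from the joint posterior,
#' computes pairwise Jaccard dissimilarities and their relationship with
#' severity distance for each draw, and averages over draws. The
#' correlation is also reported for a single point-estimate occurrence
#' matrix (conditional occurrence probabilities >= 0.5), since the two
#' summaries can differ.
#'
#' @param fits Named list of `occu_fit` objects over the same periods.
#' @param severity Percent basal-area mortality per survey period.
#' @param n_draws Number of posterior draws to propagate.
#' @param seed Optional integer seed for the occurrence draws.
#' @return List of class `beta_summary`: `correlation` (posterior mean),
#'   `correlation_point`, `group_means` (posterior mean 4 x 4 matrix),
#'   `correlation_draws`, `n_draws`.
#' @export
beta_summary <- function(fits, severity, n_draws = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- min(vapply(fits, function(f) nrow(f$pz), numeric(1)))
  idx <- if (n_draws >= total) seq_len(total)
         else sort(sample.int(total, n_draws))
  cors <- numeric(length(idx))
  gm_sum <- matrix(0, 4, 4)
  gm_n <- matrix(0, 4, 4)
  for (r in seq_along(idx)) {
    Z <- draw_occurrence_matrix(fits, idx[r])
    st <- suppressWarnings(beta_stats(jaccard_matrix(Z), severity))
    cors[r] <- st$correlation
    ok <- !is.na(st$group_means)
    gm_sum[ok] <- gm_sum[ok] + st$group_means[ok]
    gm_n[ok] <- gm_n[ok] + 1
  }
  gm <- gm_sum / gm_n
  gm[gm_n == 0] <- NA_real_
  lev <- levels(severity_class(severity))
  dimnames(gm) <- list(lev, lev)
  # point-estimate occurrence: threshold the posterior-mean conditional z
  Zp <- vapply(fits, function(f) as.numeric(colMeans(f$pz) >= 0.5),
               numeric(length(severity)))
  stp <- suppressWarnings(beta_stats(jaccard_matrix(Zp), severity))
  structure(list(
    correlation = mean(cors, na.rm = TRUE),
    correlation_point = stp$correlation,
    group_means = gm,
    correlation_draws = cors,
    n_draws = length(idx)
  ), class = "beta_summary")
}

#' @export
print.beta_summary <- function(x, ...) {
  cat("<beta_summary> Jaccard ~ severity-distance correlation: ",
      round(x$correlation, 3), " (posterior mean over ", x$n_draws,
      " draws; point estimate ", round(x$correlation_point, 3), ")\n",
      "Mean dissimilarity by severity class:\n", sep = "")
  print(round(x$group_means, 3))
  invisible(x)
}
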