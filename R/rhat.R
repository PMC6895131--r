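#' Split-R-hat convergence diagnostic
#'
#' Classic (Gelman--Rubin style) potential scale reduction factor computed
#' on split chains: each chain is halved, and the between/within variance
#' ratio is computed over the resulting 2m sequences. Values near 1
#' indicate the chains are mixing over the same distribution.
#'
#' @param draws_by_chain Matrix (iterations x chains) or list of equal
#'   length numeric vectors, one per chain.
#' @return Scalar R-hat; `NA_real_` (with a warning) when the within-chain
#'   variance is zero, which makes the diagnostic undefined.
#' @export
rhat <- function(draws_by_chain) {
  if (is.list(draws_by_chain)) {
    len <- lengths(draws_by_chain)
    if (length(unique(len)) != 1)
      fireocc_error("fireocc_invalid_argument", "chains must have equal length")
    draws_by_chain <- do.call(cbind, draws_by_chain)
  }
  x <- as.matrix(draws_by_chain)
  if (ncol(x) < 2)
    fireocc_error("fireocc_invalid_argument", "R-hat requires >= 2 chains")
  if (nrow(x) < 4)
    fireocc_error("fireocc_invalid_argument", "R-hat requires >= 4 draws per chain")
  n <- nrow(x) %/% 2L
  split <- cbind(x[seq_len(n), , drop = FALSE],
                 x[seq.int(nrow(x) - n + 1L, nrow(x)), , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  if (W == 0 || !is.finite(W)) {
    warning("zero within-chain variance; R-hat undefined", call. = FALSE)
    return(NA_real_)
  }
  B <- n * var(means)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}
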