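#' Log-posterior of a tumor fraction given per-read d-scores
#'
#' Treats each d-score as the probability the read is tumor-derived and
#' the reads as independent, so the posterior of a sample at tumor
#' fraction `r` is the product of per-read mixture terms
#' `r * d_i + (1 - r) * (1 - d_i)`. The computation is done in the log
#' domain (the product underflows for realistic read counts) with
#' d-scores clipped away from 0 and 1.
#'
#' @param dscores Numeric vector of d-scores in `[0, 1]`.
#' @param r Tumor fraction(s) in `[0, 1]`; may be a vector.
#' @param clip Clipping bound: d-scores are constrained to
#'   `[clip, 1 - clip]`. Default 1e-6.
#' @return Log-posterior value(s), one per element of `r`.
#' @export
log_posterior <- function(dscores, r, clip = 1e-6) {
  if (length(dscores) == 0L) stop("log_posterior needs at least one d-score")
  stopifnot(all(r >= 0), all(r <= 1))
  d <- pmin(pmax(dscores, clip), 1 - clip)
  # term = (1 - d) + r * (2d - 1)
  colSums(log(outer(2 * d - 1, r) + (1 - d)))
}

#' Estimate the tumor-derived read fraction
#'
#' Maximizes the log-posterior of [log_posterior] over a regular grid of
#' tumor fractions from 0 to 1 (step 0.001 by default). Ties are broken
#' toward the smallest maximizing grid point (the conservative,
#' lowest-risk call); the flat-posterior case `d = 0.5` therefore
#' returns 0.
#'
#' @param dscores Numeric vector of d-scores.
#' @param grid_step Grid resolution. Default 0.001.
#' @param clip Passed to [log_posterior].
#' @return A `tumor_fraction_estimate` list: `r_hat`, `log_posterior`
#'   (the full curve), `grid`, `grid_step`, `n_reads`.
#' @export
estimate_tumor_fraction <- function(dscores, grid_step = 0.001,
                                    clip = 1e-6) {
  stopifnot(grid_step > 0, grid_step <= 1)
  grid <- seq(0, 1, by = grid_step)
  lp <- log_posterior(dscores, grid, clip = clip)
  best <- which.max(lp)  # first index on ties -> smallest r
  structure(list(r_hat = grid[best], log_posterior = lp, grid = grid,
                 grid_step = grid_step, n_reads = length(dscores)),
            class = "tumor_fraction_estimate")
}

#' @export
print.tumor_fraction_estimate <- function(x, ...) {
  cat(sprintf("Tumor fraction estimate: r_hat = %.3f (n = %d reads, grid step %g)\n",
              x$r_hat, x$n_reads, x$grid_step))
  invisible(x)
}

#' Rank-based AUC for separating cancer from healthy samples
#'
#' The probability that a random cancer-sample score exceeds a random
#' healthy-sample score, ties at half weight (Mann-Whitney U divided by
#' the number of pairs).
#'
#' @param cancer,healthy Numeric score vectors (e.g. estimated tumor
#'   fractions) for the two cohorts.
#' @return AUC in `[0, 1]`.
#' @export
cohort_auc <- function(cancer, healthy) {
  if (length(cancer) == 0L || length(healthy) == 0L) {
    stop("both cohorts must be non-empty")
  }
  mwu_effect_size(healthy, cancer)
}
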