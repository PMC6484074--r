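#' Leave-one-out cross-validation of the fitted model
#'
#' Each observation is predicted from all the others by ordinary kriging
#' with plug-in REML parameters (no per-fold refit — standard geostatistical
#' practice, and a documented source of mild optimism). Because the support
#' covariance between observation `i` and the rest already carries the
#' household component for same-household pairs, the fold target geometry
#' is respected automatically. The per-record standardized squared
#' prediction error is `theta = (z - zhat)^2 / s2`.
#'
#' Computation uses the exact inverse-of-the-augmented-matrix identity
#' (one factorization for all folds): `s2_i = 1 / H_ii` and
#' `z_i - zhat_i = (H z~)_i / H_ii` with `H` the inverse of the bordered
#' kriging matrix and `z~ = (z, 0)`.
#'
#' @param table survey table.
#' @param model a fitted `se_fit`.
#' @return data.frame of class `cv_table` with `individual_id`, `observed`
#'   (log), `predicted` (log), `s2`, `theta`, `flagged`.
#' @export
loo_crossvalidate <- function(table, model) {
  ctx <- kriging_context(table, model)
  n <- ctx$n
  if (n < 3L) stop("need at least 3 observations for cross-validation")
  H <- tryCatch(solve(ctx$A), error = function(e) {
    stop("singular kriging system: ", conditionMessage(e))
  })
  hii <- diag(H)[seq_len(n)]
  Hz <- drop(H[seq_len(n), , drop = FALSE] %*% c(ctx$z, 0))
  flagged <- !(hii > 0) | !is.finite(hii)
  s2 <- ifelse(flagged, NA_real_, 1 / hii)
  resid <- ifelse(flagged, NA_real_, Hz / hii)
  predicted <- ctx$z - resid
  theta <- resid^2 / s2
  out <- data.frame(
    individual_id = table$individual_id,
    observed = ctx$z,
    predicted = predicted,
    s2 = s2,
    theta = theta,
    flagged = flagged
  )
  class(out) <- c("cv_table", "data.frame")
  out
}

#' Summaries of the standardized squared prediction error
#'
#' Median and mean of `theta` over unflagged records. Under a valid
#' covariance model with Gaussian errors, `theta` is approximately
#' chi-squared with 1 degree of freedom: mean near 1 and median near
#' 0.455 in the weak-correlation limit.
#'
#' @param records a [loo_crossvalidate()] result.
#' @param max_flagged_frac abort if more than this fraction of folds was
#'   flagged singular (default 1%).
#' @return List with `median_theta`, `mean_theta`, `n`, `n_flagged`.
#' @export
sspe_summary <- function(records, max_flagged_frac = 0.01) {
  th <- records$theta[!records$flagged]
  n_flagged <- sum(records$flagged)
  if (length(th) == 0L) stop("no unflagged cross-validation records")
  if (n_flagged > max_flagged_frac * nrow(records)) {
    stop(sprintf("%d of %d folds flagged singular (> %.0f%%)",
                 n_flagged, nrow(records), 100 * max_flagged_frac))
  }
  list(median_theta = stats::median(th), mean_theta = mean(th),
       n = length(th), n_flagged = n_flagged)
}

#' Monte-Carlo reference interval for the median SSPE
#'
#' Simulates datasets from the fitted model on the observed support
#' geometry, cross-validates each, and returns percentiles of the median
#' standardized squared prediction error. This correlation-aware interval
#' is what an observed median (e.g. 0.33) should be compared against; the
#' independent chi-squared-1 formula ignores the correlation of kriging
#' errors.
#'
#' @param table survey table defining the support geometry.
#' @param model a fitted `se_fit`.
#' @param n_sim number of simulated datasets (>= 100 recommended).
#' @param seed integer seed.
#' @param probs percentile pair for the interval.
#' @return List with `lower`, `upper`, `medians` (all simulated medians).
#' @export
median_sspe_interval <- function(table, model, n_sim = 200, seed = 1L,
                                 probs = c(0.025, 0.975)) {
  if (n_sim < 2L) stop("`n_sim` must be at least 2")
  ctx <- kriging_context(table, model)
  n <- ctx$n
  H <- solve(ctx$A)
  hii <- diag(H)[seq_len(n)]
  ok <- hii > 0 & is.finite(hii)
  if (mean(!ok) > 0.01) stop("more than 1% of folds singular")
  Hn <- H[seq_len(n), seq_len(n), drop = FALSE]
  L <- chol(ctx$C)
  set.seed(as.integer(seed))
  medians <- vapply(seq_len(n_sim), function(s) {
    zs <- model$mu_hat + drop(crossprod(L, stats::rnorm(n)))
    resid <- drop(Hn %*% zs)[ok] / hii[ok]   # constant mean drops out: H1=0
    stats::median(resid^2 * hii[ok])         # theta = resid^2 / (1/hii)
  }, numeric(1))
  q <- stats::quantile(medians, probs, names = FALSE)
  list(lower = q[1L], upper = q[2L], medians = medians)
}

#' Normality diagnostics of standardized cross-validation errors
#'
#' Descriptive only (no hypothesis-test verdict): skewness, excess
#' kurtosis and quantile-quantile data of the standardized errors
#' `(z - zhat)/sqrt(s2)`.
#'
#' @param records a [loo_crossvalidate()] result.
#' @return List with `skewness`, `excess_kurtosis`, `degenerate` flag and a
#'   `qq` data.frame (`theoretical`, `sample`).
#' @export
normality_check <- function(records) {
  e <- (records$observed - records$predicted) / sqrt(records$s2)
  e <- e[!records$flagged & is.finite(e)]
  if (length(e) < 8L) stop("need at least 8 records for diagnostics")
  m2 <- mean((e - mean(e))^2)
  if (m2 < .Machine$double.eps) {
    return(list(skewness = NA_real_, excess_kurtosis = NA_real_,
                degenerate = TRUE, qq = NULL))
  }
  m3 <- mean((e - mean(e))^3)
  m4 <- mean((e - mean(e))^4)
  qq <- data.frame(
    theoretical = stats::qnorm(stats::ppoints(length(e))),
    sample = sort(e)
  )
  list(skewness = m3 / m2^1.5, excess_kurtosis = m4 / m2^2 - 3,
       degenerate = FALSE, qq = qq)
}
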