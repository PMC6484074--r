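#' Matern correlation parameters
#'
#' Smoothness `nu` (dimensionless) and distance parameter `phi` (km) of the
#' Matern correlation family,
#' \deqn{\rho(h) = \frac{1}{2^{\nu-1}\Gamma(\nu)} (h/\phi)^\nu K_\nu(h/\phi),}
#' the convention in which `nu = 0.5` reduces exactly to the exponential
#' model \eqn{\exp(-h/\phi)} with effective range (correlation 0.05) close
#' to \eqn{3\phi}. The alternative ML convention that rescales distance by
#' \eqn{\sqrt{2\nu}} is deliberately not used.
#'
#' @param nu positive smoothness parameter.
#' @param phi positive distance parameter, km.
#' @return An object of class `matern_params`.
#' @export
matern_params <- function(nu = 0.5, phi = 39.4) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0) {
    stop("`nu` must be a single positive number")
  }
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0) {
    stop("`phi` must be a single positive number (km)")
  }
  structure(list(nu = nu, phi = phi), class = "matern_params")
}

#' Variance components of the nested spatial model
#'
#' Log-scale variances of the three nested random effects: between-cluster
#' (`sigma2_c`, spatially correlated), between-household within cluster
#' (`sigma2_h`), and between-individual within household (`sigma2_e`,
#' which also absorbs analytical error).
#'
#' @param sigma2_c,sigma2_h,sigma2_e non-negative variances (log scale).
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(sigma2_c, sigma2_h, sigma2_e) {
  v <- c(sigma2_c = sigma2_c, sigma2_h = sigma2_h, sigma2_e = sigma2_e)
  if (!is.numeric(v) || length(v) != 3L || anyNA(v) || any(v < 0)) {
    stop("variance components must be non-negative numbers")
  }
  structure(as.list(v), class = "variance_components")
}

total_variance <- function(components) {
  components$sigma2_c + components$sigma2_h + components$sigma2_e
}

#' Matern correlation function
#'
#' Evaluated in log space (exponentially scaled Bessel K) so that large
#' `nu` or large lags do not overflow. `rho(0) = 1` by continuity.
#'
#' @param h non-negative distances, km.
#' @param params a [matern_params()] object.
#' @return Correlations in (0, 1].
#' @export
matern_correlation <- function(h, params) {
  stopifnot(inherits(params, "matern_params"))
  if (any(!is.finite(h))) stop("distances must be finite")
  if (any(h < 0)) stop("distances must be non-negative")
  u <- h / params$phi
  nu <- params$nu
  rho <- numeric(length(u))
  zero <- u == 0
  rho[zero] <- 1
  if (any(!zero)) {
    uz <- u[!zero]
    # log rho = -(nu-1)log2 - lgamma(nu) + nu*log(u) + log K_nu(u)
    # with K_nu evaluated on the exp scale: K = besselK(u,, TRUE) * exp(-u)
    lrho <- -(nu - 1) * log(2) - lgamma(nu) + nu * log(uz) +
      log(besselK(uz, nu, expon.scaled = TRUE)) - uz
    rho[!zero] <- exp(lrho)
  }
  rho
}

#' Effective range of a Matern correlation
#'
#' Distance at which correlation decays to `level` (default 0.05, the
#' conventional limit of practical spatial dependence; 3*phi for the
#' exponential model).
#'
#' @param params a [matern_params()] object.
#' @param level correlation level defining the range.
#' @return Distance in km.
#' @export
effective_range <- function(params, level = 0.05) {
  stopifnot(level > 0, level < 1)
  upper <- params$phi
  while (matern_correlation(upper, params) > level) upper <- upper * 2
  stats::uniroot(function(h) matern_correlation(h, params) - level,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

# observation index: data.frame with cluster (id into cluster_coords rows)
# and household columns; internal canonical form used by the likelihood and
# kriging code
as_design_index <- function(table) {
  stopifnot(all(c("cluster_id", "household_id") %in% names(table)))
  cl <- factor(table$cluster_id, levels = unique(table$cluster_id))
  hh <- factor(table$household_id, levels = unique(table$household_id))
  data.frame(cluster = as.integer(cl), household = as.integer(hh))
}

cluster_coords_from_table <- function(table) {
  cl <- factor(table$cluster_id, levels = unique(table$cluster_id))
  first <- !duplicated(cl)
  cbind(x = table$x[first], y = table$y[first])
}

#' Observation covariance matrix of the nested spatial model
#'
#' \eqn{V_{ij} = \sigma^2_c \rho(\|x_{c(i)} - x_{c(j)}\|) + \sigma^2_h
#' 1[\mathrm{same\ household}] + \sigma^2_e 1[i = j]}; the diagonal equals
#' the total variance. Individuals in the same cluster are at distance zero.
#'
#' @param index data.frame with integer columns `cluster` and `household`
#'   (household implies cluster); `cluster` indexes rows of `cluster_coords`.
#' @param components a [variance_components()] object.
#' @param matern a [matern_params()] object.
#' @param cluster_coords matrix of cluster coordinates (km), one row per
#'   cluster id.
#' @return Symmetric positive-definite matrix.
#' @export
assemble_covariance <- function(index, components, matern, cluster_coords) {
  stopifnot(inherits(components, "variance_components"),
            inherits(matern, "matern_params"))
  cluster_coords <- as.matrix(cluster_coords)
  if (anyNA(cluster_coords) || any(!is.finite(cluster_coords))) {
    stop("cluster coordinates must be finite")
  }
  if (max(index$cluster) > nrow(cluster_coords)) {
    stop("observation references a cluster without coordinates")
  }
  D <- as.matrix(stats::dist(cluster_coords))
  R <- matern_correlation(D, matern)
  dim(R) <- dim(D)
  V <- components$sigma2_c * R[index$cluster, index$cluster, drop = FALSE]
  same_hh <- outer(index$household, index$household, "==")
  V <- V + components$sigma2_h * same_hh
  diag(V) <- diag(V) + components$sigma2_e
  dimnames(V) <- NULL
  V
}
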