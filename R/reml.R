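#' Residual (REML) log-likelihood of the nested spatial model
#'
#' The model is `z = mu + S(cluster) + H(household) + E(individual)` on the
#' natural-log scale with a constant mean as the only fixed effect. The
#' residual log-likelihood is the Harville form
#' \deqn{\ell_R = -\tfrac12\left[(n-1)\log 2\pi + \log|V| +
#'   \log(\mathbf{1}^\top V^{-1}\mathbf{1}) + z^\top P z\right],}
#' with `P` the REML projection; it is invariant to translation of `z` and
#' to relabelling of cluster/household ids.
#'
#' Two evaluation paths give identical values: a dense path (Cholesky of
#' the full n x n covariance) and, for designs whose households within each
#' cluster all have the same size, an exact orthogonal-contrast
#' decomposition (within-household, between-household and cluster-mean
#' blocks) whose cost is cubic in the number of clusters only.
#'
#' @param z numeric vector of natural-log concentrations.
#' @param index data.frame with integer columns `cluster` and `household`
#'   (see [assemble_covariance()]).
#' @param components a [variance_components()] object.
#' @param matern a [matern_params()] object.
#' @param cluster_coords matrix of cluster coordinates (km).
#' @param method `"auto"` (nested decomposition when the design allows,
#'   else dense), `"dense"`, or `"nested"`.
#' @return REML log-likelihood (scalar).
#' @export
reml_loglik <- function(z, index, components, matern, cluster_coords,
                        method = c("auto", "dense", "nested")) {
  method <- match.arg(method)
  n <- length(z)
  if (n < 2L) stop("need at least 2 observations")
  if (nrow(index) != n) stop("`z` and `index` lengths differ")
  if (anyNA(z) || any(!is.finite(z))) stop("log values must be finite")
  if (method == "auto") {
    method <- if (is_balanced_within_cluster(index)) "nested" else "dense"
  }
  if (method == "nested") {
    pre <- nested_precompute(z, index, cluster_coords)
    nested_loglik(pre, components, matern)
  } else {
    dense_loglik(z, index, components, matern, cluster_coords)
  }
}

is_balanced_within_cluster <- function(index) {
  hh_size <- tabulate(index$household)
  hh_cluster <- index$cluster[!duplicated(index$household)]
  sizes_by_cluster <- split(hh_size[unique(index$household)], hh_cluster)
  all(vapply(sizes_by_cluster, function(s) length(unique(s)) == 1L, logical(1)))
}

dense_loglik <- function(z, index, components, matern, cluster_coords) {
  V <- assemble_covariance(index, components, matern, cluster_coords)
  L <- tryCatch(chol(V), error = function(e) {
    stop("observation covariance is singular for these parameters: ",
         conditionMessage(e))
  })
  n <- length(z)
  logdet <- 2 * sum(log(diag(L)))
  Vi_z <- backsolve(L, forwardsolve(t(L), z))
  Vi_1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  s11 <- sum(Vi_1)                       # 1' V^-1 1
  s1z <- sum(Vi_z)                       # 1' V^-1 z
  quad <- sum(z * Vi_z) - s1z^2 / s11    # z' P z
  -0.5 * ((n - 1) * log(2 * pi) + logdet + log(s11) + quad)
}

# design- and data-dependent summaries that do not involve the covariance
# parameters; computed once per fit
nested_precompute <- function(z, index, cluster_coords) {
  hh <- index$household
  cl <- index$cluster
  hh_mean <- tapply(z, hh, mean)
  hh_size <- tabulate(hh)
  ss_e <- sum((z - hh_mean[as.character(hh)])^2)
  df_e <- sum(hh_size - 1L)

  hh_ids <- sort(unique(hh))
  hh_cl <- cl[match(hh_ids, hh)]
  hmeans <- as.numeric(hh_mean[as.character(hh_ids)])

  cl_ids <- sort(unique(cl))
  k_c <- vapply(split(hh_size[hh_ids], hh_cl), function(s) s[1L], numeric(1))
  m_c <- as.numeric(table(factor(hh_cl, levels = cl_ids)))
  cl_mean <- as.numeric(tapply(hmeans, hh_cl, mean))
  ss_b <- as.numeric(tapply(seq_along(hmeans), hh_cl, function(ii) {
    sum((hmeans[ii] - mean(hmeans[ii]))^2)
  }))
  n_c <- m_c * k_c
  D <- as.matrix(stats::dist(cluster_coords[cl_ids, , drop = FALSE]))
  list(ss_e = ss_e, df_e = df_e, k_c = k_c, m_c = m_c, n_c = n_c,
       ss_b = ss_b, cl_mean = cl_mean, D = D, n = length(z))
}

nested_loglik <- function(pre, components, matern, return_mu = FALSE) {
  s2c <- components$sigma2_c
  s2h <- components$sigma2_h
  s2e <- components$sigma2_e
  ll <- 0
  if (pre$df_e > 0L) {
    ll <- ll - 0.5 * (pre$df_e * log(2 * pi * s2e) + pre$ss_e / s2e)
  } else if (pre$ss_e > 0) {
    stop("internal: within-household variation with zero df")
  }
  v_b <- pre$k_c * s2h + s2e
  db <- pre$m_c - 1L
  ll <- ll - 0.5 * sum(db * log(2 * pi * v_b) + pre$k_c * pre$ss_b / v_b)

  # cluster-mean block: w_c = sqrt(n_c) * mean_c, REML over mean mu
  C <- length(pre$n_c)
  sq <- sqrt(pre$n_c)
  R <- matern_correlation(pre$D, matern)
  dim(R) <- dim(pre$D)
  Vt <- s2c * (sq %o% sq) * R
  diag(Vt) <- pre$n_c * s2c + pre$k_c * s2h + s2e
  L <- tryCatch(chol(Vt), error = function(e) {
    stop("cluster-mean covariance is singular for these parameters")
  })
  w <- sq * pre$cl_mean
  Vi_w <- backsolve(L, forwardsolve(t(L), w))
  Vi_x <- backsolve(L, forwardsolve(t(L), sq))
  sxx <- sum(sq * Vi_x)
  sxw <- sum(sq * Vi_w)
  quad <- sum(w * Vi_w) - sxw^2 / sxx
  ll <- ll - 0.5 * ((C - 1) * log(2 * pi) + 2 * sum(log(diag(L))) +
                      log(sxx) + quad)
  if (return_mu) list(loglik = ll, mu_hat = sxw / sxx) else ll
}

#' Fit the nested spatial model by REML at fixed smoothness
#'
#' Maximizes the residual log-likelihood over the three variance components
#' and the Matern distance parameter, with the smoothness `nu` held fixed.
#' Optimization is on the log scale (log variances, log phi) with a
#' derivative-free simplex search from several deterministic starting
#' points, because REML surfaces for Matern models can be multimodal.
#' The constant mean is recovered by generalized least squares at the
#' optimum.
#'
#' @param table survey table with `cluster_id`, `household_id`, `x`, `y`
#'   and `plasma_se` columns; concentrations are log-transformed internally
#'   unless `log_values` is supplied.
#' @param nu fixed Matern smoothness.
#' @param log_values optional vector of natural-log values overriding
#'   `log(table$plasma_se)`.
#' @param start optional named start vector
#'   (`sigma2_c`, `sigma2_h`, `sigma2_e`, `phi`).
#' @param n_starts number of deterministic starting points (default 3).
#' @param maxit simplex iteration cap per start.
#' @param var_floor lower bound for variances (effective zero, keeps the
#'   covariance positive definite).
#' @return An object of class `se_fit` with elements `mu_hat`, `components`,
#'   `matern`, `reml_loglik`, `n_obs`, `converged`, `phi_identifiable`,
#'   `n_evals` and (after [profile_smoothness()]) `nu_profile`.
#' @export
fit_variance_components <- function(table, nu = 0.5, log_values = NULL,
                                    start = NULL, n_starts = 3,
                                    maxit = 1000, var_floor = 1e-10) {
  z <- if (is.null(log_values)) log(table$plasma_se) else log_values
  if (any(!is.finite(z))) stop("non-positive or non-finite concentrations")
  index <- as_design_index(table)
  coords <- cluster_coords_from_table(table)
  n_cl <- nrow(coords)
  if (n_cl < 2L) {
    stop("at least 2 clusters are required to estimate the ",
         "between-cluster component")
  }
  if (anyDuplicated(coords)) stop("duplicate cluster coordinates")

  balanced <- is_balanced_within_cluster(index)
  pre <- if (balanced) nested_precompute(z, index, coords) else NULL
  negloglik <- function(par) {
    comps <- variance_components(max(exp(par[1L]), var_floor),
                                 max(exp(par[2L]), var_floor),
                                 max(exp(par[3L]), var_floor))
    mat <- matern_params(nu, exp(par[4L]))
    ll <- tryCatch({
      if (balanced) nested_loglik(pre, comps, mat)
      else dense_loglik(z, index, comps, mat, coords)
    }, error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- reml_starts(z, index, coords, start, n_starts)
  best <- NULL
  n_evals <- 0L
  for (s in starts) {
    opt <- stats::optim(log(s), negloglik, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    n_evals <- n_evals + opt$counts[["function"]]
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  par <- best$par
  comps <- variance_components(max(exp(par[1L]), var_floor),
                               max(exp(par[2L]), var_floor),
                               max(exp(par[3L]), var_floor))
  mat <- matern_params(nu, exp(par[4L]))
  if (balanced) {
    at_opt <- nested_loglik(pre, comps, mat, return_mu = TRUE)
    ll <- at_opt$loglik
    mu_hat <- at_opt$mu_hat
  } else {
    ll <- dense_loglik(z, index, comps, mat, coords)
    mu_hat <- dense_gls_mean(z, index, comps, mat, coords)
  }

  # with a negligible spatial share of the variance, phi is practically
  # non-identifiable (the likelihood is flat in it)
  phi_identifiable <- comps$sigma2_c > 0.01 * total_variance(comps)
  structure(list(
    mu_hat = mu_hat,
    components = comps,
    matern = mat,
    reml_loglik = ll,
    n_obs = length(z),
    converged = best$convergence == 0L,
    phi_identifiable = phi_identifiable,
    n_evals = n_evals,
    nu_profile = NULL
  ), class = "se_fit")
}

dense_gls_mean <- function(z, index, components, matern, cluster_coords) {
  V <- assemble_covariance(index, components, matern, cluster_coords)
  L <- chol(V)
  Vi_z <- backsolve(L, forwardsolve(t(L), z))
  Vi_1 <- backsolve(L, forwardsolve(t(L), rep(1, length(z))))
  sum(Vi_z) / sum(Vi_1)
}

# moment-based start plus deterministic perturbations (no RNG so that seed
# bookkeeping stays with the data generators)
reml_starts <- function(z, index, coords, start, n_starts) {
  if (!is.null(start)) {
    s <- start[c("sigma2_c", "sigma2_h", "sigma2_e", "phi")]
    if (anyNA(s)) stop("`start` must name sigma2_c, sigma2_h, sigma2_e, phi")
    base <- pmax(as.numeric(s), 1e-6)
  } else {
    hh_mean <- tapply(z, index$household, mean)
    cl_mean <- tapply(z, index$cluster, mean)
    s2e <- stats::var(z - hh_mean[as.character(index$household)]) * 2
    s2c <- stats::var(as.numeric(cl_mean))
    tot <- stats::var(z)
    s2h <- max(tot - s2c - s2e, 0.1 * tot)
    diam <- sqrt(diff(range(coords[, 1L]))^2 + diff(range(coords[, 2L]))^2)
    base <- pmax(c(s2c, s2h, s2e, diam / 8), 1e-6)
    if (!is.finite(base[1L]) || base[1L] <= 1e-6) base[1L] <- 0.3 * tot
    if (!is.finite(base[3L]) || base[3L] <= 1e-6) base[3L] <- 0.3 * tot
  }
  mults <- list(c(1, 1, 1, 1), c(0.25, 2, 2, 3), c(3, 0.5, 0.5, 1 / 3),
                c(1, 0.2, 1.5, 2), c(0.5, 1, 0.5, 0.5))
  lapply(mults[seq_len(min(n_starts, length(mults)))],
         function(m) base * m)
}

#' Profile likelihood over the Matern smoothness parameter
#'
#' Refits the model by REML at each smoothness value on a grid and keeps
#' the fit with the largest maximized residual log-likelihood; ties (within
#' `tie_tol`) break toward smaller smoothness for parsimony. The full
#' profile is retained in `nu_profile`.
#'
#' @param table survey table (see [fit_variance_components()]).
#' @param nu_grid increasing grid of smoothness values.
#' @param tie_tol log-likelihood tie tolerance.
#' @param keep_fits if `TRUE`, attach the per-grid-point fits as `$fits`.
#' @param ... passed to [fit_variance_components()].
#' @return An `se_fit` whose `nu_profile` is a data.frame of
#'   (`nu`, `loglik`, `converged`).
#' @export
profile_smoothness <- function(table, nu_grid = c(0.1, 0.25, 0.5, 1, 1.5, 2),
                               tie_tol = 1e-6, keep_fits = FALSE, ...) {
  if (length(nu_grid) < 1L) stop("`nu_grid` must be non-empty")
  nu_grid <- sort(nu_grid)
  fits <- vector("list", length(nu_grid))
  errs <- character(0)
  warm <- NULL
  for (i in seq_along(nu_grid)) {
    fits[[i]] <- tryCatch(
      fit_variance_components(table, nu = nu_grid[i], start = warm, ...),
      error = function(e) e
    )
    if (inherits(fits[[i]], "se_fit")) {
      f <- fits[[i]]
      warm <- c(sigma2_c = f$components$sigma2_c,
                sigma2_h = f$components$sigma2_h,
                sigma2_e = f$components$sigma2_e,
                phi = f$matern$phi)
    } else {
      errs <- c(errs, sprintf("nu=%g: %s", nu_grid[i],
                              conditionMessage(fits[[i]])))
    }
  }
  ok <- vapply(fits, inherits, logical(1), "se_fit")
  if (!any(ok)) {
    stop("profile likelihood failed at every grid point:\n",
         paste(errs, collapse = "\n"))
  }
  ll <- vapply(fits, function(f) {
    if (inherits(f, "se_fit")) f$reml_loglik else -Inf
  }, numeric(1))
  # grid is ascending, so the first index within tie_tol of the maximum is
  # the smallest qualifying nu
  pick <- which(ll >= max(ll) - tie_tol)[1L]
  out <- fits[[pick]]
  out$nu_profile <- data.frame(
    nu = nu_grid[ok],
    loglik = ll[ok],
    converged = vapply(fits[ok], function(f) f$converged, logical(1))
  )
  if (keep_fits) out$fits <- fits
  out
}

#' @export
print.se_fit <- function(x, ...) {
  cat("Nested spatial LMM fit (REML)\n")
  cat(sprintf("  n = %d observations, mean (log scale) mu = %.4f\n",
              x$n_obs, x$mu_hat))
  cat(sprintf("  sigma2_c = %.4g  sigma2_h = %.4g  sigma2_e = %.4g\n",
              x$components$sigma2_c, x$components$sigma2_h,
              x$components$sigma2_e))
  cat(sprintf("  Matern nu = %.3g, phi = %.4g km (effective range %.1f km)\n",
              x$matern$nu, x$matern$phi, effective_range(x$matern)))
  cat(sprintf("  REML log-likelihood = %.4f (converged: %s)\n",
              x$reml_loglik, x$converged))
  if (!x$phi_identifiable) {
    cat("  note: sigma2_c ~ 0; phi is not identifiable\n")
  }
  if (!is.null(x$nu_profile)) {
    cat("  profile over nu:\n")
    print(x$nu_profile, row.names = FALSE)
  }
  invisible(x)
}
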