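iid_fit <- function(sigma2_e = 0.04, mu = log(80)) {
  structure(list(
    mu_hat = mu,
    components = variance_components(0, 0, sigma2_e),
    matern = matern_params(0.5, 39.4),
    reml_loglik = NA_real_, n_obs = NA_integer_, converged = TRUE,
    phi_identifiable = FALSE, n_evals = 0L, nu_profile = NULL
  ), class = "se_fit")
}

spatial_fit <- function() {
  structure(list(
    mu_hat = log(80),
    components = variance_components(0.15, 0.018, 0.028),
    matern = matern_params(0.5, 39.4),
    reml_loglik = NA_real_, n_obs = NA_integer_, converged = TRUE,
    phi_identifiable = TRUE, n_evals = 0L, nu_profile = NULL
  ), class = "se_fit")
}

test_that("LOO under the iid model matches the closed form", {
  # without spatial or household structure the OK prediction of each
  # observation is the mean of the others, with variance s2*(1 + 1/(n-1))
  n <- 12
  d <- generate_design(n_clusters = n, households_per_cluster = 1,
                       individuals_per_household = 1, seed = 5)
  p <- generative_params(components = variance_components(0, 0, 0.04))
  tab <- simulate_survey(d, p, seed = 6)
  z <- log(tab$plasma_se)
  cv <- loo_crossvalidate(tab, iid_fit(0.04))
  for (i in seq_len(n)) {
    expect_equal(cv$predicted[i], mean(z[-i]), tolerance = 1e-10)
    expect_equal(cv$s2[i], 0.04 * (1 + 1 / (n - 1)), tolerance = 1e-10)
    theta_i <- (z[i] - mean(z[-i]))^2 / (0.04 * (1 + 1 / (n - 1)))
    expect_equal(cv$theta[i], theta_i, tolerance = 1e-10)
  }
})

test_that("LOO matches brute-force per-fold kriging on a small instance", {
  tab <- small_survey(n_clusters = 4, households_per_cluster = 2,
                      individuals_per_household = 2, seed = 91)
  model <- spatial_fit()
  z <- log(tab$plasma_se)
  V <- brute_covariance_exp(tab, 0.15, 0.018, 0.028, 39.4)
  cv <- loo_crossvalidate(tab, model)
  for (i in seq_len(nrow(tab))) {
    Vi <- V[-i, -i]
    c0 <- V[-i, i]   # same-household pairs carry the household component
    A <- rbind(cbind(Vi, 1), c(rep(1, nrow(Vi)), 0))
    sol <- solve(A, c(c0, 1))
    lam <- sol[seq_len(nrow(Vi))]
    expect_equal(cv$predicted[i], sum(lam * z[-i]), tolerance = 1e-8)
    s2_i <- 0.196 - 2 * sum(lam * c0) + drop(t(lam) %*% Vi %*% lam)
    expect_equal(cv$s2[i], s2_i, tolerance = 1e-8)
  }
})

test_that("LOO thetas are translation invariant and order invariant", {
  tab <- small_survey(seed = 92)
  model <- spatial_fit()
  cv <- loo_crossvalidate(tab, model)

  tab_shift <- tab
  tab_shift$plasma_se <- tab$plasma_se * exp(1.3)
  cv_shift <- loo_crossvalidate(tab_shift, model)
  expect_equal(cv_shift$theta, cv$theta, tolerance = 1e-8)

  set.seed(3)
  perm <- sample(nrow(tab))
  cv_perm <- loo_crossvalidate(tab[perm, ], model)
  expect_equal(cv_perm$theta[order(perm)], cv$theta, tolerance = 1e-8)
})

test_that("SSPE summary computes median and mean and guards flags", {
  rec <- data.frame(theta = c(0.1, 0.4, 0.9), flagged = FALSE)
  s <- sspe_summary(rec)
  expect_equal(s$median_theta, 0.4)
  expect_equal(s$mean_theta, mean(c(0.1, 0.4, 0.9)), tolerance = 1e-12)

  rec2 <- data.frame(theta = rep(0.7, 5), flagged = FALSE)
  s2 <- sspe_summary(rec2)
  expect_equal(s2$median_theta, 0.7)
  expect_equal(s2$mean_theta, 0.7)

  rec3 <- data.frame(theta = c(1, NA, 1, 1), flagged = c(FALSE, TRUE,
                                                         FALSE, FALSE))
  expect_error(sspe_summary(rec3), "flagged")
})

test_that("valid-model calibration: mean SSPE ~ 1, median ~ chi-sq(1)", {
  # weak-correlation limit: many clusters far apart relative to phi
  d <- generate_design(n_clusters = 600, households_per_cluster = 1,
                       individuals_per_household = 1,
                       region = region_rectangle(800, 800), seed = 7)
  p <- generative_params(
    components = variance_components(0.10, 0, 0.06),
    matern = matern_params(0.5, 10))
  tab <- simulate_survey(d, p, seed = 8)
  model <- structure(list(
    mu_hat = log(80), components = p$components, matern = p$matern,
    reml_loglik = NA_real_, n_obs = nrow(tab), converged = TRUE,
    phi_identifiable = TRUE, n_evals = 0L, nu_profile = NULL
  ), class = "se_fit")
  cv <- loo_crossvalidate(tab, model)
  s <- sspe_summary(cv)
  expect_gt(s$mean_theta, 0.9)
  expect_lt(s$mean_theta, 1.1)
  # median of chi-squared with 1 df is 0.4549
  expect_equal(s$median_theta, qchisq(0.5, 1), tolerance = 0.15)
})

test_that("Monte-Carlo median-SSPE interval behaves as a reference band", {
  tab <- small_survey(n_clusters = 10, households_per_cluster = 3,
                      individuals_per_household = 2, seed = 93)
  model <- spatial_fit()
  iv <- median_sspe_interval(tab, model, n_sim = 120, seed = 4)
  expect_lt(iv$lower, iv$upper)
  # the chi-squared(1) median lies inside the band for a valid model
  expect_gt(qchisq(0.5, 1), iv$lower)
  expect_lt(qchisq(0.5, 1), iv$upper)
  # reproducible under the seed
  iv2 <- median_sspe_interval(tab, model, n_sim = 120, seed = 4)
  expect_identical(iv$medians, iv2$medians)
  # degenerate but well-defined small-sample interval
  iv3 <- median_sspe_interval(tab, model, n_sim = 2, seed = 5)
  expect_true(is.finite(iv3$lower) && is.finite(iv3$upper))

  # data simulated from the model fall inside their own reference band
  cv <- loo_crossvalidate(tab, model)
  med <- sspe_summary(cv)$median_theta
  expect_gt(med, iv$lower)
  expect_lt(med, iv$upper)
})

test_that("normality diagnostics describe standardized errors", {
  set.seed(10)
  e <- rnorm(10000)
  rec <- data.frame(observed = e, predicted = 0, s2 = 1, theta = e^2,
                    flagged = FALSE)
  nc <- normality_check(rec)
  expect_equal(nc$skewness, 0, tolerance = 0.1)
  expect_equal(nc$excess_kurtosis, 0, tolerance = 0.1)
  expect_false(nc$degenerate)
  expect_equal(nrow(nc$qq), 10000)

  # constant errors: flagged as degenerate
  recc <- data.frame(observed = rep(2, 20), predicted = 1, s2 = 1,
                     theta = 1, flagged = FALSE)
  ncc <- normality_check(recc)
  expect_true(ncc$degenerate)
  expect_true(is.na(ncc$skewness))

  # symmetric two-point sample has zero skewness
  recs <- data.frame(observed = rep(c(-1, 1), 10), predicted = 0, s2 = 1,
                     theta = 1, flagged = FALSE)
  expect_equal(normality_check(recs)$skewness, 0, tolerance = 1e-12)

  expect_error(normality_check(rec[1:5, ]), "at least 8")
})
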