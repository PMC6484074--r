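test_that("REML log-likelihood matches the iid closed form", {
  # one cluster, no cluster/household variance: the residual likelihood is
  # that of the n-1 contrasts of an iid normal sample
  z <- c(4.1, 4.5, 4.3, 4.9, 4.2)
  n <- length(z)
  idx <- data.frame(cluster = rep(1L, n), household = seq_len(n))
  coords <- cbind(0, 0)
  comps0 <- function(s2) variance_components(0, 0, s2)
  mat <- matern_params(0.5, 10)

  # Harville form with V = s2*I simplifies to the contrast likelihood:
  # -0.5[(n-1)log(2 pi s2) + log n + SS/s2]
  closed_form <- function(s2) {
    ss <- sum((z - mean(z))^2)
    -0.5 * ((n - 1) * log(2 * pi * s2) + log(n) + ss / s2)
  }
  for (s2 in c(0.05, 0.2, 1)) {
    expect_equal(reml_loglik(z, idx, comps0(s2), mat, coords,
                             method = "dense"),
                 closed_form(s2), tolerance = 1e-10)
  }
  # the REML maximizer is the n-1 divisor sample variance
  prof <- vapply(seq(0.01, 1, by = 0.0005), function(s2) {
    reml_loglik(z, idx, comps0(s2), mat, coords, method = "dense")
  }, numeric(1))
  s2_hat <- seq(0.01, 1, by = 0.0005)[which.max(prof)]
  expect_equal(s2_hat, var(z), tolerance = 2e-3)
})

test_that("REML log-likelihood is invariant to translation and permutation", {
  tab <- small_survey(seed = 31)
  z <- log(tab$plasma_se)
  idx <- table_index(tab)
  coords <- table_coords(tab)
  comps <- published_components()
  mat <- published_matern()
  base <- reml_loglik(z, idx, comps, mat, coords)
  expect_equal(reml_loglik(z + 3.7, idx, comps, mat, coords), base,
               tolerance = 1e-8)
  set.seed(1)
  perm <- sample(length(z))
  expect_equal(reml_loglik(z[perm], idx[perm, ], comps, mat, coords), base,
               tolerance = 1e-8)
})

test_that("nested fast path equals the dense likelihood", {
  for (seed in c(51, 52)) {
    tab <- small_survey(n_clusters = 6, households_per_cluster = 4,
                        individuals_per_household = 3, seed = seed)
    z <- log(tab$plasma_se)
    idx <- table_index(tab)
    coords <- table_coords(tab)
    for (comps in list(published_components(),
                       variance_components(0.02, 0.1, 0.3))) {
      for (mat in list(published_matern(), matern_params(1.3, 15))) {
        expect_equal(
          reml_loglik(z, idx, comps, mat, coords, method = "nested"),
          reml_loglik(z, idx, comps, mat, coords, method = "dense"),
          tolerance = 1e-8
        )
      }
    }
  }
})

test_that("fitting recovers generative parameters on a modest design", {
  est <- t(vapply(1:6, function(s) {
    d <- generate_design(n_clusters = 40, households_per_cluster = 6,
                         individuals_per_household = 2, seed = s)
    tab <- simulate_survey(d, generative_params(), seed = 600 + s)
    f <- fit_variance_components(tab, nu = 0.5)
    expect_true(f$converged)
    c(f$components$sigma2_c, f$components$sigma2_h, f$components$sigma2_e,
      f$matern$phi, f$mu_hat)
  }, numeric(5)))
  means <- colMeans(est)
  # generous desk-scale tolerances; the acceptance suite runs the full
  # 102-cluster experiment at the published +/-20%
  expect_equal(means[1], 0.15, tolerance = 0.4)
  expect_equal(means[2], 0.018, tolerance = 0.5)
  expect_equal(means[3], 0.028, tolerance = 0.25)
  expect_equal(means[4], 39.4, tolerance = 0.5)
  expect_equal(means[5], log(80), tolerance = 0.05)
})

test_that("the GLS mean at the optimum matches a direct computation", {
  tab <- small_survey(seed = 61)
  f <- fit_variance_components(tab, nu = 0.5)
  z <- log(tab$plasma_se)
  V <- assemble_covariance(table_index(tab), f$components, f$matern,
                           table_coords(tab))
  Vi <- solve(V)
  ones <- rep(1, length(z))
  mu_gls <- drop(ones %*% Vi %*% z) / drop(ones %*% Vi %*% ones)
  expect_equal(f$mu_hat, mu_gls, tolerance = 1e-6)
})

test_that("estimates are invariant to cluster and household relabeling", {
  tab <- small_survey(seed = 71)
  tab2 <- tab
  tab2$cluster_id <- paste0("relabelled_", tab$cluster_id)
  tab2$household_id <- paste0("relabelled_", tab$household_id)
  f1 <- fit_variance_components(tab, nu = 0.5)
  f2 <- fit_variance_components(tab2, nu = 0.5)
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-8)
  expect_equal(f1$components$sigma2_c, f2$components$sigma2_c,
               tolerance = 1e-6)
})

test_that("degenerate inputs are handled as contracted", {
  # a single cluster cannot support a between-cluster component
  d <- generate_design(n_clusters = 1, households_per_cluster = 5,
                       individuals_per_household = 2, seed = 1)
  tab <- simulate_survey(d, generative_params(), seed = 1)
  expect_error(fit_variance_components(tab), "2 clusters")

  # no spatial signal: sigma2_c shrinks to zero and phi is flagged
  d2 <- generate_design(n_clusters = 30, households_per_cluster = 4,
                        individuals_per_household = 2, seed = 1)
  p0 <- generative_params(components = variance_components(0, 0.05, 0.05))
  tab2 <- simulate_survey(d2, p0, seed = 101)
  f <- fit_variance_components(tab2, nu = 0.5)
  expect_lt(f$components$sigma2_c, 0.01)
  expect_false(f$phi_identifiable)
})

test_that("profile over a length-1 grid equals the fixed-nu fit", {
  tab <- small_survey(seed = 81)
  f1 <- fit_variance_components(tab, nu = 0.5)
  fp <- profile_smoothness(tab, nu_grid = 0.5)
  expect_equal(fp$reml_loglik, f1$reml_loglik, tolerance = 1e-6)
  expect_equal(nrow(fp$nu_profile), 1L)
  expect_true(all(is.finite(fp$nu_profile$loglik)))
  expect_equal(fp$matern$nu, 0.5)
})
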