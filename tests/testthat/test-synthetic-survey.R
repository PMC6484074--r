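test_that("generate_design produces the survey structure it promises", {
  d <- generate_design(n_clusters = 102, urban_fraction = 18 / 102,
                       households_per_cluster = 9,
                       individuals_per_household = 2, seed = 3)
  expect_equal(nrow(d$clusters), 102)
  expect_equal(sum(d$clusters$urban), 18)
  expect_equal(sum(!d$clusters$urban), 84)
  expect_equal(nrow(d$households), 102 * 9)
  expect_equal(nrow(d$individuals), 102 * 9 * 2)
  expect_false(anyDuplicated(d$clusters$cluster_id) > 0)
  expect_true(all(d$households$cluster_id %in% d$clusters$cluster_id))
  expect_true(all(d$individuals$household_id %in% d$households$household_id))
  expect_true(all(point_in_region(d$clusters$x, d$clusters$y,
                                  region_rectangle())))
  expect_true(all(d$individuals$wealth_quintile %in% 1:5))

  # minimal design: one row at every level
  d1 <- generate_design(n_clusters = 1, households_per_cluster = 1,
                        individuals_per_household = 1, seed = 1)
  expect_equal(vapply(d1[c("clusters", "households", "individuals")],
                      nrow, integer(1)),
               c(clusters = 1L, households = 1L, individuals = 1L))

  expect_error(generate_design(n_clusters = 0), ">= 1")
  expect_error(generate_design(urban_fraction = 1.4), "\\[0, 1\\]")
})

test_that("design and survey are reproducible for a fixed seed", {
  d1 <- generate_design(n_clusters = 12, seed = 9)
  d2 <- generate_design(n_clusters = 12, seed = 9)
  d3 <- generate_design(n_clusters = 12, seed = 10)
  expect_identical(d1, d2)
  expect_false(isTRUE(all.equal(d1$clusters$x, d3$clusters$x)))

  t1 <- simulate_survey(d1, generative_params(), seed = 5)
  t2 <- simulate_survey(d1, generative_params(), seed = 5)
  t3 <- simulate_survey(d1, generative_params(), seed = 6)
  expect_identical(t1, t2)
  expect_false(isTRUE(all.equal(t1$plasma_se, t3$plasma_se)))
})

test_that("degenerate variance settings give exact constants", {
  d <- generate_design(n_clusters = 5, households_per_cluster = 2,
                       individuals_per_household = 2, seed = 2)
  p <- generative_params(mu = log(80),
                         components = variance_components(0, 0, 0))
  tab <- simulate_survey(d, p, seed = 1)
  expect_equal(tab$plasma_se, rep(80, nrow(tab)), tolerance = 1e-12)

  # cluster-only variance: all individuals in a cluster share one value
  pc <- generative_params(components = variance_components(0.15, 0, 0))
  tabc <- simulate_survey(d, pc, seed = 1)
  per_cl <- tapply(tabc$plasma_se, tabc$cluster_id,
                   function(v) length(unique(v)))
  expect_true(all(per_cl == 1L))
})

test_that("simulated log variance matches the generative components", {
  # between-cluster variance over many clusters (cluster component only)
  vars <- vapply(1:4, function(s) {
    d <- generate_design(n_clusters = 250, households_per_cluster = 1,
                         individuals_per_household = 1, seed = s)
    tab <- simulate_survey(
      d, generative_params(components = variance_components(0.15, 0, 0)),
      seed = 100 + s)
    var(log(tab$plasma_se))
  }, numeric(1))
  expect_equal(mean(vars), 0.15, tolerance = 0.15)

  # pooled variance with all three printed components ~ 0.196
  pooled <- vapply(1:5, function(s) {
    d <- generate_design(seed = s)
    tab <- simulate_survey(d, generative_params(), seed = 200 + s)
    var(log(tab$plasma_se))
  }, numeric(1))
  expect_equal(mean(pooled), 0.15 + 0.018 + 0.028, tolerance = 0.15)
})

test_that("cluster field variogram flattens near sigma2_c at long lags", {
  # mean squared half-difference of cluster values at lags far beyond the
  # effective range (~118 km) estimates the sill sigma2_c
  sq_half_diff <- 0
  n_pairs <- 0
  for (s in 1:60) {
    d <- generate_design(n_clusters = 40, households_per_cluster = 1,
                         individuals_per_household = 1, seed = s)
    tab <- simulate_survey(
      d, generative_params(components = variance_components(0.15, 0, 0)),
      seed = 300 + s)
    z <- log(tab$plasma_se)
    D <- as.matrix(dist(cbind(tab$x, tab$y)))
    far <- which(D > 250 & upper.tri(D), arr.ind = TRUE)
    sq_half_diff <- sq_half_diff +
      sum(0.5 * (z[far[, 1]] - z[far[, 2]])^2)
    n_pairs <- n_pairs + nrow(far)
  }
  expect_gt(n_pairs, 1000)
  expect_equal(sq_half_diff / n_pairs, 0.15, tolerance = 0.15)
})

test_that("log concentrations are Gaussian across replicates", {
  pvals <- vapply(1:40, function(s) {
    d <- generate_design(n_clusters = 30, households_per_cluster = 3,
                         individuals_per_household = 2, seed = s)
    tab <- simulate_survey(d, generative_params(), seed = 400 + s)
    # remove cluster means so the Shapiro statistic sees the iid part
    z <- log(tab$plasma_se)
    resid <- z - ave(z, tab$cluster_id)
    shapiro.test(resid)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("proximity covariates measure planar distance to features", {
  vert <- feature(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), "polygon")
  water <- feature(rbind(c(0, -50), c(0, 50)), "line")
  tab <- data.frame(individual_id = c("a", "b", "c"),
                    household_id = c("h1", "h2", "h3"),
                    cluster_id = c("c1", "c2", "c3"),
                    x = c(5, 10, 25), y = c(5, 0, 5),
                    plasma_se = c(80, 90, 100))
  out <- attach_proximity_covariates(tab, list(vert), list(water))
  expect_equal(out$dist_vertisol, c(0, 0, 15))   # inside; on edge; 15 km off
  expect_equal(out$dist_water, c(5, 10, 25))     # distance to the x = 0 line

  # equidistant from two features: the common distance
  two <- list(feature(rbind(c(-10, -1), c(-10, 1)), "line"),
              feature(rbind(c(20, -1), c(20, 1)), "line"))
  d2 <- dist_to_features(5, 0, two)
  expect_equal(d2, 15)
})

test_that("duplicate cluster coordinates are rejected with spatial variance", {
  d <- generate_design(n_clusters = 3, households_per_cluster = 1,
                       individuals_per_household = 1, seed = 1)
  d$clusters$x <- c(10, 10, 20)
  d$clusters$y <- c(10, 10, 20)
  expect_error(simulate_survey(d, generative_params(), seed = 1),
               "duplicate cluster coordinates")
  # but fine when the spatial component is off
  p0 <- generative_params(components = variance_components(0, 0.01, 0.01))
  expect_silent(simulate_survey(d, p0, seed = 1))
})

test_that("wealth gradient option shifts the outcome monotonically", {
  d <- generate_design(n_clusters = 60, households_per_cluster = 4,
                       individuals_per_household = 2, seed = 21)
  tab <- simulate_survey(d, generative_params(), seed = 22,
                         quintile_effect = 0.15)
  mlog <- tapply(log(tab$plasma_se), tab$wealth_quintile, mean)
  expect_gt(mlog[["5"]], mlog[["1"]])
})
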