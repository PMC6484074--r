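# Shared fixtures: everything is generated in code at test time.

published_components <- function() variance_components(0.15, 0.018, 0.028)
published_matern <- function() matern_params(0.5, 39.4)

small_survey <- function(n_clusters = 8, households_per_cluster = 3,
                         individuals_per_household = 2, seed = 11,
                         params = generative_params(), region = NULL) {
  if (is.null(region)) region <- region_rectangle(120, 200)
  d <- generate_design(n_clusters = n_clusters,
                       households_per_cluster = households_per_cluster,
                       individuals_per_household = individuals_per_household,
                       region = region, seed = seed)
  simulate_survey(d, params, seed = seed + 1000)
}

# independent brute-force covariance assembly: double loop, exponential
# correlation written out directly (only valid for nu = 0.5)
brute_covariance_exp <- function(table, sigma2_c, sigma2_h, sigma2_e, phi) {
  n <- nrow(table)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      h <- sqrt((table$x[i] - table$x[j])^2 + (table$y[i] - table$y[j])^2)
      V[i, j] <- sigma2_c * exp(-h / phi) +
        sigma2_h * (table$household_id[i] == table$household_id[j]) +
        sigma2_e * (i == j)
    }
  }
  V
}

# brute-force ordinary kriging at x0 from an explicit covariance matrix:
# augmented bordered system solved directly
brute_ok <- function(x0, table, z, V, sigma2_c, phi, sigma2_tot) {
  n <- nrow(table)
  c0 <- sigma2_c * exp(-sqrt((table$x - x0[1])^2 +
                               (table$y - x0[2])^2) / phi)
  A <- rbind(cbind(V, 1), c(rep(1, n), 0))
  sol <- solve(A, c(c0, 1))
  lambda <- sol[1:n]
  list(m = sum(lambda * z),
       s2 = sigma2_tot - 2 * sum(lambda * c0) +
         drop(t(lambda) %*% V %*% lambda),
       weights = lambda)
}

table_index <- function(table) segeostat:::as_design_index(table)
table_coords <- function(table) segeostat:::cluster_coords_from_table(table)
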