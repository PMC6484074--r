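#' Generate a nested survey design
#'
#' Emulates the structure of a national micronutrient survey: clusters
#' (enumeration areas) placed uniformly at random inside a region polygon,
#' households nested in clusters, individuals nested in households. A
#' fraction of clusters is flagged urban. Cluster locations are resampled
#' on exact coordinate duplication so that spatial covariance matrices are
#' positive definite by construction.
#'
#' Random numbers are consumed in a fixed order (cluster locations, then
#' urban assignment, then group labels, then wealth quintiles) so seeds are
#' portable across versions.
#'
#' @param n_clusters number of clusters (default 102, the analysed survey).
#' @param urban_fraction fraction of clusters flagged urban (default 18/102).
#' @param households_per_cluster households sampled per cluster.
#' @param individuals_per_household individuals per household. The default 2
#'   matters: with 1 individual per household the household and individual
#'   variance components are not separately identifiable.
#' @param region an `se_region` polygon; default 160 x 850 km rectangle.
#' @param group_probs named probabilities of demographic group labels
#'   (default all women of reproductive age, `WRA`).
#' @param seed integer seed; fixed seed gives an identical design.
#' @return A list of class `survey_design` with data frames `clusters`
#'   (`cluster_id`, `x`, `y`, `urban`), `households` (`household_id`,
#'   `cluster_id`) and `individuals` (`individual_id`, `household_id`,
#'   `group`, `wealth_quintile`).
#' @export
generate_design <- function(n_clusters = 102, urban_fraction = 18 / 102,
                            households_per_cluster = 9,
                            individuals_per_household = 2,
                            region = region_rectangle(),
                            group_probs = c(WRA = 1),
                            seed = 1L) {
  stopifnot(inherits(region, "se_region"))
  if (n_clusters < 1 || households_per_cluster < 1 ||
      individuals_per_household < 1) {
    stop("design counts must be >= 1")
  }
  if (urban_fraction < 0 || urban_fraction > 1) {
    stop("`urban_fraction` must lie in [0, 1]")
  }
  if (is.null(names(group_probs)) || any(group_probs < 0) ||
      sum(group_probs) <= 0) {
    stop("`group_probs` must be named non-negative weights")
  }
  set.seed(as.integer(seed))

  bb <- region_bbox(region)
  xy <- matrix(NA_real_, n_clusters, 2L)
  filled <- 0L
  while (filled < n_clusters) {
    need <- n_clusters - filled
    # rejection sampling against the polygon; oversample to cut iterations
    m <- max(16L, ceiling(need * 4))
    cx <- stats::runif(m, bb["xmin"], bb["xmax"])
    cy <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- which(point_in_region(cx, cy, region))
    if (length(keep) > need) keep <- keep[seq_len(need)]
    if (length(keep) > 0L) {
      xy[filled + seq_along(keep), ] <- cbind(cx[keep], cy[keep])
      filled <- filled + length(keep)
    }
  }
  # resample exact duplicates (vanishing probability, but contract-bound)
  while (anyDuplicated(xy)) {
    dup <- which(duplicated(xy))
    xy[dup, ] <- cbind(stats::runif(length(dup), bb["xmin"], bb["xmax"]),
                       stats::runif(length(dup), bb["ymin"], bb["ymax"]))
  }

  n_urban <- round(urban_fraction * n_clusters)
  urban <- logical(n_clusters)
  if (n_urban > 0L) urban[sample.int(n_clusters, n_urban)] <- TRUE

  clusters <- data.frame(cluster_id = sprintf("c%03d", seq_len(n_clusters)),
                         x = xy[, 1L], y = xy[, 2L], urban = urban)
  households <- data.frame(
    household_id = sprintf("c%03d_h%02d",
                           rep(seq_len(n_clusters),
                               each = households_per_cluster),
                           rep(seq_len(households_per_cluster), n_clusters)),
    cluster_id = rep(clusters$cluster_id, each = households_per_cluster)
  )
  n_ind <- nrow(households) * individuals_per_household
  group <- names(group_probs)[sample.int(length(group_probs), n_ind,
                                         replace = TRUE, prob = group_probs)]
  quintile <- sample.int(5L, n_ind, replace = TRUE)
  individuals <- data.frame(
    individual_id = sprintf("i%05d", seq_len(n_ind)),
    household_id = rep(households$household_id,
                       each = individuals_per_household),
    group = group,
    wealth_quintile = quintile
  )
  structure(list(clusters = clusters, households = households,
                 individuals = individuals, region = region),
            class = "survey_design")
}

#' Generative parameters of the plasma Se model
#'
#' The survey model on the natural-log scale: a constant mean `mu`
#' (log ng/mL) plus three zero-mean Gaussian random effects whose variances
#' are the [variance_components()], the cluster effect spatially correlated
#' under the [matern_params()] Matern model. Defaults are the fitted values
#' reported for the Malawi women-of-reproductive-age survey.
#'
#' @param mu mean of log plasma Se (log ng/mL).
#' @param components a [variance_components()] object.
#' @param matern a [matern_params()] object.
#' @return A list of class `generative_params`.
#' @export
generative_params <- function(mu = log(80),
                              components = variance_components(0.15, 0.018,
                                                               0.028),
                              matern = matern_params(0.5, 39.4)) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            inherits(components, "variance_components"),
            inherits(matern, "matern_params"))
  structure(list(mu = mu, components = components, matern = matern),
            class = "generative_params")
}

#' Simulate plasma Se concentrations on a survey design
#'
#' Draws `log(plasma_se) = mu + S + H + E` with `S` a zero-mean Gaussian
#' field over cluster locations (covariance `sigma2_c * rho_Matern`), `H`
#' iid household effects (`sigma2_h`) and `E` iid individual effects
#' (`sigma2_e`); returns concentrations on the natural ng/mL scale. Random
#' numbers are consumed in the order S, H, E.
#'
#' @param design a [generate_design()] result.
#' @param params a [generative_params()] object.
#' @param seed integer seed.
#' @param quintile_effect optional monotone shift of `mu` per unit of wealth
#'   quintile (log scale, centred on quintile 3); default 0.
#' @return A `data.frame` survey table with one row per individual:
#'   `individual_id`, `household_id`, `cluster_id`, `x`, `y`, `urban`,
#'   `group`, `wealth_quintile`, `plasma_se` (ng/mL).
#' @export
simulate_survey <- function(design, params, seed = 1L, quintile_effect = 0) {
  stopifnot(inherits(design, "survey_design"),
            inherits(params, "generative_params"))
  set.seed(as.integer(seed))
  cl <- design$clusters
  comps <- params$components

  if (comps$sigma2_c > 0 && anyDuplicated(cl[, c("x", "y")])) {
    stop("duplicate cluster coordinates with sigma2_c > 0: ",
         "covariance is singular (regenerate the design)")
  }

  n_cl <- nrow(cl)
  S <- numeric(n_cl)
  if (comps$sigma2_c > 0) {
    D <- as.matrix(stats::dist(cl[, c("x", "y")]))
    R <- matern_correlation(D, params$matern)
    dim(R) <- dim(D)
    C <- comps$sigma2_c * R
    L <- tryCatch(chol(C), error = function(e) {
      stop("cluster covariance is not positive definite: ",
           conditionMessage(e))
    })
    S <- drop(crossprod(L, stats::rnorm(n_cl)))
  }
  H <- stats::rnorm(nrow(design$households), 0, sqrt(comps$sigma2_h))
  E <- stats::rnorm(nrow(design$individuals), 0, sqrt(comps$sigma2_e))

  hh <- design$households
  ind <- design$individuals
  cl_of_hh <- match(hh$cluster_id, cl$cluster_id)
  hh_of_ind <- match(ind$household_id, hh$household_id)

  logz <- params$mu +
    quintile_effect * (ind$wealth_quintile - 3) +
    S[cl_of_hh][hh_of_ind] + H[hh_of_ind] + E

  data.frame(
    individual_id = ind$individual_id,
    household_id = ind$household_id,
    cluster_id = hh$cluster_id[hh_of_ind],
    x = cl$x[cl_of_hh][hh_of_ind],
    y = cl$y[cl_of_hh][hh_of_ind],
    urban = cl$urban[cl_of_hh][hh_of_ind],
    group = ind$group,
    wealth_quintile = ind$wealth_quintile,
    plasma_se = exp(logz)
  )
}

#' Attach proximity covariates to a survey table
#'
#' Adds `dist_vertisol` and `dist_water`: minimum planar distance (km) from
#' each record's cluster location to the nearest vertisol polygon and the
#' nearest lake/river feature (0 inside a polygon). Features must be in the
#' same projected km system as the survey coordinates.
#'
#' @param table a survey table.
#' @param vertisol_features list of `se_feature` polygons.
#' @param water_features list of `se_feature` lines/polygons.
#' @return The table with `dist_vertisol` and `dist_water` columns.
#' @export
attach_proximity_covariates <- function(table, vertisol_features,
                                        water_features) {
  table$dist_vertisol <- dist_to_features(table$x, table$y, vertisol_features)
  table$dist_water <- dist_to_features(table$x, table$y, water_features)
  table
}
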