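#' Build a prediction grid inside a boundary polygon
#'
#' Regular square lattice at the given resolution covering the boundary's
#' bounding box, using the cell-centre convention, masked to nodes inside
#' the polygon.
#'
#' @param boundary an `se_region`.
#' @param resolution_km positive cell size in km. The production choice in
#'   national mapping is 0.5 km; desk-scale work uses 5-10 km.
#' @return A data.frame of interior nodes (`x`, `y`) of class
#'   `prediction_grid` with a `resolution_km` attribute.
#' @export
build_grid <- function(boundary, resolution_km = 5) {
  stopifnot(inherits(boundary, "se_region"))
  if (!is.numeric(resolution_km) || length(resolution_km) != 1L ||
      resolution_km <= 0) {
    stop("`resolution_km` must be a positive number")
  }
  bb <- region_bbox(boundary)
  xs <- seq(bb["xmin"] + resolution_km / 2, bb["xmax"], by = resolution_km)
  ys <- seq(bb["ymin"] + resolution_km / 2, bb["ymax"], by = resolution_km)
  nodes <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  inside <- point_in_region(nodes$x, nodes$y, boundary)
  nodes <- nodes[inside, , drop = FALSE]
  if (nrow(nodes) == 0L) {
    stop("no grid nodes fall inside the boundary at this resolution")
  }
  rownames(nodes) <- NULL
  attr(nodes, "resolution_km") <- resolution_km
  class(nodes) <- c("prediction_grid", "data.frame")
  nodes
}

# shared ordinary-kriging setup: support covariance, augmented matrix and
# the pieces reused across nodes
kriging_context <- function(table, model) {
  stopifnot(inherits(model, "se_fit"))
  if (!isTRUE(model$converged)) {
    warning("kriging from a fit flagged as non-converged")
  }
  z <- log(table$plasma_se)
  if (any(!is.finite(z))) stop("non-positive concentrations in table")
  index <- as_design_index(table)
  coords <- cluster_coords_from_table(table)
  C <- assemble_covariance(index, model$components, model$matern, coords)
  n <- length(z)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  list(z = z, n = n, A = A, C = C,
       obs_cluster_xy = cbind(table$x, table$y),
       sigma2_tot = total_variance(model$components),
       sigma2_c = model$components$sigma2_c,
       matern = model$matern)
}

# covariance between a target individual at (x0, y0) and the support
# observations: only the spatially correlated cluster component is shared
# with a new, unobserved individual
target_covariance <- function(x0, y0, ctx) {
  h <- sqrt((ctx$obs_cluster_xy[, 1L] - x0)^2 +
              (ctx$obs_cluster_xy[, 2L] - y0)^2)
  ctx$sigma2_c * matern_correlation(h, ctx$matern)
}

#' Ordinary kriging of an individual-level log concentration at one point
#'
#' Solves the ordinary kriging system with the fitted covariance model:
#' weights constrained to sum to one, target an unobserved individual at
#' `x0` (so the household and individual variance components enter the
#' target variance but not the cross-covariances). The returned `m` is the
#' mean and `s2` the variance of the conditional (prediction) distribution
#' of log plasma Se.
#'
#' @param x0 numeric length-2 coordinate (km).
#' @param table survey table (the kriging support).
#' @param model a fitted `se_fit`.
#' @return List with `m` (log ng/mL), `s2`, `lagrange` and `weights`.
#' @export
krige_point <- function(x0, table, model) {
  stopifnot(is.numeric(x0), length(x0) == 2L, all(is.finite(x0)))
  ctx <- kriging_context(table, model)
  c0 <- target_covariance(x0[1L], x0[2L], ctx)
  sol <- tryCatch(solve(ctx$A, c(c0, 1)), error = function(e) {
    stop("singular kriging system (duplicate support with zero nugget?): ",
         conditionMessage(e))
  })
  lambda <- sol[seq_len(ctx$n)]
  psi <- sol[ctx$n + 1L]
  list(m = sum(lambda * ctx$z),
       s2 = max(ctx$sigma2_tot - sum(lambda * c0) - psi, 0),
       lagrange = psi,
       weights = lambda)
}

#' Ordinary kriging over a prediction grid
#'
#' Vectorized [krige_point()]: the augmented kriging matrix is factorized
#' once and reused for all nodes (global kriging, no moving neighbourhood).
#'
#' @param grid a [build_grid()] result or a data.frame with `x`, `y`.
#' @param table survey table.
#' @param model a fitted `se_fit`.
#' @param block number of nodes solved per batch (memory control).
#' @return data.frame (`x`, `y`, `m`, `s2`, `lagrange`, `median_ngml`).
#' @export
krige_grid <- function(grid, table, model, block = 2048L) {
  ctx <- kriging_context(table, model)
  n <- ctx$n
  nn <- nrow(grid)
  m <- s2 <- psi <- numeric(nn)
  for (from in seq(1L, nn, by = block)) {
    to <- min(from + block - 1L, nn)
    idx <- from:to
    C0 <- vapply(idx, function(i) {
      target_covariance(grid$x[i], grid$y[i], ctx)
    }, numeric(n))
    rhs <- rbind(C0, 1)
    sol <- solve(ctx$A, rhs)
    lambda <- sol[seq_len(n), , drop = FALSE]
    psi[idx] <- sol[n + 1L, ]
    m[idx] <- drop(crossprod(lambda, ctx$z))
    s2[idx] <- pmax(ctx$sigma2_tot - colSums(lambda * C0) - psi[idx], 0)
  }
  data.frame(x = grid$x, y = grid$y, m = m, s2 = s2, lagrange = psi,
             median_ngml = back_transform_median(m))
}

#' Median-unbiased back-transform of a log-scale prediction
#'
#' Exponentiation returns the median (not the mean) of the lognormal
#' prediction distribution; the mean would require the correction factor
#' `exp(s2/2)`.
#'
#' @param m kriging prediction on the log scale.
#' @return Concentration in ng/mL.
#' @export
back_transform_median <- function(m) {
  if (any(!is.finite(m))) stop("`m` must be finite")
  exp(m)
}
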