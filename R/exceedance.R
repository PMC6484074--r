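#' Plasma Se deficiency thresholds
#'
#' Named concentration thresholds (ng/mL) below which plasma Se indicates
#' deficiency risk: optimal activity of glutathione peroxidase 3 (GPx3,
#' 84.9), optimal activity of iodothyronine deiodinase (IDI, 64.8) and the
#' Keshan disease risk criterion (KD, 30). All configurable.
#'
#' @param ... named positive thresholds overriding or extending the
#'   defaults.
#' @return Named numeric vector of class `threshold_set`, sorted ascending.
#' @export
threshold_set <- function(...) {
  th <- c(GPx3 = 84.9, IDI = 64.8, KD = 30)
  override <- c(...)
  if (length(override) > 0L) {
    if (is.null(names(override)) || any(names(override) == "")) {
      stop("thresholds must be named")
    }
    th <- th[setdiff(names(th), names(override))]
    th <- c(th, override)
  }
  if (any(th <= 0) || anyNA(th)) stop("thresholds must be positive")
  structure(sort(th), class = "threshold_set")
}

#' Verbal scale for communicating probabilities
#'
#' Ordered probability bins with calibrated-language labels, used in map
#' legends so that lay readers can interpret exceedance probabilities. The
#' default edges 0.10/0.33/0.66/0.90 give five bins from "very unlikely"
#' to "very likely". Bins are half-open `[lower, upper)`; a probability of
#' exactly 1 falls in the top bin.
#'
#' @param edges strictly increasing interior bin edges in (0, 1).
#' @param labels one label per bin (`length(edges) + 1`).
#' @return List of class `verbal_scale`.
#' @export
verbal_scale <- function(edges = c(0.10, 0.33, 0.66, 0.90),
                         labels = c("very unlikely", "unlikely",
                                    "as likely as not", "likely",
                                    "very likely")) {
  if (any(diff(edges) <= 0) || any(edges <= 0) || any(edges >= 1)) {
    stop("`edges` must be strictly increasing and inside (0, 1)")
  }
  if (length(labels) != length(edges) + 1L) {
    stop("need exactly one label per bin (length(edges) + 1)")
  }
  structure(list(edges = edges, labels = labels), class = "verbal_scale")
}

#' Probability that the true concentration falls below a threshold
#'
#' From the conditional (prediction) distribution of log concentration,
#' `p = Phi((log T - m) / sqrt(s2))`. A degenerate distribution (`s2 = 0`)
#' is treated as a point mass with the strict-inequality convention
#' `p = 1[exp(m) < T]`.
#'
#' @param m prediction mean, log ng/mL (vectorized).
#' @param s2 prediction variance (vectorized or scalar).
#' @param threshold positive threshold in ng/mL.
#' @return Probabilities in `[0, 1]`.
#' @export
exceedance_probability <- function(m, s2, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive concentration (ng/mL)")
  }
  if (any(s2 < 0)) stop("`s2` must be non-negative")
  s2 <- rep_len(s2, length(m))
  p <- numeric(length(m))
  pos <- s2 > 0
  p[pos] <- stats::pnorm((log(threshold) - m[pos]) / sqrt(s2[pos]))
  p[!pos] <- as.numeric(exp(m[!pos]) < threshold)
  p
}

#' Classify a probability on the verbal scale
#'
#' @param p probabilities in `[0, 1]` (vectorized).
#' @param scale a [verbal_scale()].
#' @return Factor of labels, ordered by bin.
#' @export
classify_verbal <- function(p, scale = verbal_scale()) {
  stopifnot(inherits(scale, "verbal_scale"))
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("probabilities must lie in [0, 1]")
  }
  idx <- findInterval(p, c(0, scale$edges, 1), rightmost.closed = TRUE)
  factor(scale$labels[idx], levels = scale$labels, ordered = TRUE)
}

#' Map threshold exceedance over grid predictions
#'
#' For each prediction node, the probability that plasma Se falls below
#' each threshold and its verbal classification.
#'
#' @param grid_predictions [krige_grid()] output (`x`, `y`, `m`, `s2`).
#' @param thresholds a [threshold_set()].
#' @param scale a [verbal_scale()].
#' @return data.frame with `x`, `y`, and per threshold `NAME` a column
#'   `p_NAME` and `label_NAME`.
#' @export
map_exceedance <- function(grid_predictions, thresholds = threshold_set(),
                           scale = verbal_scale()) {
  stopifnot(inherits(thresholds, "threshold_set"),
            all(c("m", "s2") %in% names(grid_predictions)))
  out <- data.frame(x = grid_predictions$x, y = grid_predictions$y)
  prev <- NULL
  for (nm in names(thresholds)) {  # ascending threshold order
    p <- exceedance_probability(grid_predictions$m, grid_predictions$s2,
                                thresholds[[nm]])
    if (!is.null(prev) && any(p < prev - 1e-12)) {
      stop("internal: exceedance probability not monotone in threshold")
    }
    out[[paste0("p_", nm)]] <- p
    out[[paste0("label_", nm)]] <- classify_verbal(p, scale)
    prev <- p
  }
  out
}
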