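#' Summary statistics of plasma Se by stratum
#'
#' Per-stratum n, median, mean, SD (n-1 divisor), min and max on the
#' natural ng/mL scale — the layout of a survey cohort summary table.
#'
#' @param table survey table.
#' @param group_keys character vector of grouping columns (e.g. `"group"`,
#'   `c("group", "urban")`).
#' @return data.frame with the grouping columns plus `n`, `median`, `mean`,
#'   `sd`, `min`, `max`.
#' @export
summarize_groups <- function(table, group_keys = "group") {
  missing_keys <- setdiff(group_keys, names(table))
  if (length(missing_keys) > 0L) {
    stop("unknown group key(s): ", paste(missing_keys, collapse = ", "))
  }
  if (nrow(table) == 0L) stop("empty survey table")
  key <- interaction(table[group_keys], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(seq_len(nrow(table)), key), function(ii) {
    v <- table$plasma_se[ii]
    cbind(table[ii[1L], group_keys, drop = FALSE],
          data.frame(n = length(v), median = stats::median(v),
                     mean = mean(v),
                     sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                     min = min(v), max = max(v)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Prevalence below concentration thresholds by stratum
#'
#' Percentage of records strictly below each threshold (a value exactly at
#' the threshold is not counted as deficient), per stratum. Unweighted by
#' default; if the table has a `weight` column, weighted percentages are
#' emitted alongside as `wpct_` columns.
#'
#' @param table survey table.
#' @param thresholds a [threshold_set()].
#' @param strata grouping columns; `NULL` for a single pooled stratum.
#' @return data.frame with the strata columns, `n`, and `pct_NAME` per
#'   threshold (plus `wpct_NAME` when weights are present).
#' @export
prevalence_below <- function(table, thresholds = threshold_set(),
                             strata = "group") {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (!is.null(strata)) {
    missing_keys <- setdiff(strata, names(table))
    if (length(missing_keys) > 0L) {
      stop("unknown stratum key(s): ", paste(missing_keys, collapse = ", "))
    }
  }
  weighted <- "weight" %in% names(table)
  key <- if (is.null(strata)) factor(rep("all", nrow(table)))
         else interaction(table[strata], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(seq_len(nrow(table)), key), function(ii) {
    v <- table$plasma_se[ii]
    row <- if (is.null(strata)) data.frame(stratum = "all")
           else table[ii[1L], strata, drop = FALSE]
    row$n <- length(v)
    for (nm in rev(names(thresholds))) {  # descending T: table layout
      row[[paste0("pct_", nm)]] <- 100 * mean(v < thresholds[[nm]])
      if (weighted) {
        w <- table$weight[ii]
        row[[paste0("wpct_", nm)]] <-
          100 * sum(w * (v < thresholds[[nm]])) / sum(w)
      }
    }
    row
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Stratify plasma Se by proximity to vertisols and water bodies
#'
#' Splits records into a near group (within `vertisol_cutoff` km of a
#' mapped vertisol AND within `water_cutoff` km of the lake/river features)
#' and its complement, and summarizes each side. The defaults 10 km and
#' 30 km follow the reported stratification of elevated-status populations.
#'
#' @param table survey table with `dist_vertisol` and `dist_water`
#'   populated (see [attach_proximity_covariates()]).
#' @param vertisol_cutoff,water_cutoff distances in km.
#' @return data.frame with rows `near` and `far` and the
#'   [summarize_groups()] statistics (a side with no records has `n = 0`
#'   and missing statistics).
#' @export
stratify_by_proximity <- function(table, vertisol_cutoff = 10,
                                  water_cutoff = 30) {
  if (!all(c("dist_vertisol", "dist_water") %in% names(table))) {
    stop("proximity covariates missing: run attach_proximity_covariates()")
  }
  near <- table$dist_vertisol <= vertisol_cutoff &
    table$dist_water <= water_cutoff
  one_side <- function(label, v) {
    if (length(v) == 0L) {
      data.frame(proximity = label, n = 0L, median = NA_real_,
                 mean = NA_real_, sd = NA_real_, min = NA_real_,
                 max = NA_real_)
    } else {
      data.frame(proximity = label, n = length(v),
                 median = stats::median(v), mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                 min = min(v), max = max(v))
    }
  }
  out <- rbind(one_side("near", table$plasma_se[near]),
               one_side("far", table$plasma_se[!near]))
  rownames(out) <- NULL
  out
}
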