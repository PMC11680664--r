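#' Observation-weighted category distribution
#'
#' The share of each retention pattern in a corpus, weighted by the amount
#' of data behind each data set (sample size times observations per
#' participant) so that tiny studies do not carry the same weight as large
#' ones. Removed data sets are excluded before weighting.
#'
#' @param assignments List of `category_assignment` objects.
#' @param characteristics Characteristics data frame with `dataset_id` and
#'   `amount_of_data`; required for `weight = "amount_of_data"`.
#' @param weight `"amount_of_data"` (default) or `"unweighted"`.
#' @return A `category_distribution`: data frame with `category`, `weight`,
#'   `proportion` (summing to 1), plus attributes `total_weight` and
#'   `weighting`.
#' @export
weighted_category_distribution <- function(assignments,
                                           characteristics = NULL,
                                           weight = c("amount_of_data",
                                                      "unweighted")) {
  weight <- match.arg(weight)
  cats <- vapply(assignments, function(x) x$category, character(1))
  ids <- vapply(assignments, function(x) x$dataset_id, character(1))
  keep <- cats != "removed"
  cats <- cats[keep]
  ids <- ids[keep]
  if (!length(cats)) stop("no retained data sets to summarize", call. = FALSE)

  w <- if (weight == "unweighted") {
    rep(1, length(ids))
  } else {
    if (is.null(characteristics)) {
      stop("characteristics are required for amount-of-data weighting",
           call. = FALSE)
    }
    idx <- match(ids, characteristics$dataset_id)
    if (anyNA(idx)) {
      stop("missing weight for data set(s): ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    wt <- characteristics$amount_of_data[idx]
    if (any(!is.finite(wt) | wt <= 0)) {
      stop("weights must be positive and finite", call. = FALSE)
    }
    wt
  }

  by_cat <- tapply(w, factor(cats, levels = setdiff(retention_categories,
                                                    "removed")), sum,
                   default = 0)
  out <- data.frame(category = names(by_cat),
                    weight = as.numeric(by_cat),
                    proportion = as.numeric(by_cat) / sum(w),
                    stringsAsFactors = FALSE)
  structure(out, total_weight = sum(w), weighting = weight,
            class = c("category_distribution", "data.frame"))
}

#' Fit quality of each family where it won
#'
#' Summarizes the winning r-squared of each loss family over the data sets
#' on which that family was the best fit. Families with zero wins are
#' omitted with a message.
#'
#' @param assignments List of `category_assignment` objects.
#' @return Data frame with `family`, `n`, `mean`, `se`, `min`, `max` of the
#'   winning r-squared (`se` is `NA` for a single winner).
#' @export
best_fit_quality_summary <- function(assignments) {
  cats <- vapply(assignments, function(x) x$category, character(1))
  rows <- lapply(retention_families, function(fam) {
    r2 <- vapply(assignments[cats == fam], function(x) x$best_r2, numeric(1))
    if (!length(r2)) {
      message("family with zero wins omitted: ", fam)
      return(NULL)
    }
    data.frame(family = fam, n = length(r2), mean = mean(r2),
               se = if (length(r2) > 1L) stats::sd(r2) / sqrt(length(r2))
                    else NA_real_,
               min = min(r2), max = max(r2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Typical curve of a category
#'
#' The representative trajectory of a category, evaluated on a time grid.
#' Loss categories use their family at the element-wise median of the
#' winning `a` and `b` values; `no_net_change` is a horizontal line at the
#' median initial memory; `increasing` uses a linear curve at the median of
#' the attached linear-fit parameters.
#'
#' @param category One of [retention_categories] except `removed`.
#' @param assignments List of `category_assignment` objects.
#' @param times Evaluation grid (strictly increasing, positive); defaults to
#'   [default_time_grid()].
#' @return Data frame with `category`, `t`, `M`.
#' @export
typical_curve <- function(category, assignments,
                          times = default_time_grid()) {
  category <- match.arg(category, setdiff(retention_categories, "removed"))
  cats <- vapply(assignments, function(x) x$category, character(1))
  members <- assignments[cats == category]
  if (!length(members)) {
    stop("no data sets in category ", category, call. = FALSE)
  }
  if (category == "no_net_change") {
    level <- stats::median(vapply(members, function(x) x$initial_memory,
                                  numeric(1)))
    return(data.frame(category = category, t = times,
                      M = pmin(1, pmax(0, rep(level, length(times)))),
                      stringsAsFactors = FALSE))
  }
  fits <- Filter(Negate(is.null), lapply(members, `[[`, "winning_fit"))
  if (!length(fits)) {
    stop("category ", category, " has no attached fits", call. = FALSE)
  }
  fam <- if (category == "increasing") "linear" else category
  a <- stats::median(vapply(fits, `[[`, numeric(1), "a"))
  b <- stats::median(vapply(fits, `[[`, numeric(1), "b"))
  grid <- curve_grid(retention_curve(fam, a, b), times)
  cbind(category = category, grid, stringsAsFactors = FALSE)
}

#' Typical curves for all non-empty categories
#'
#' @param assignments List of `category_assignment` objects.
#' @param times Evaluation grid.
#' @return Stacked data frame of [typical_curve()] results.
#' @export
typical_curves <- function(assignments, times = default_time_grid()) {
  cats <- unique(vapply(assignments, function(x) x$category, character(1)))
  cats <- intersect(setdiff(retention_categories, "removed"), cats)
  do.call(rbind, lapply(cats, typical_curve, assignments = assignments,
                        times = times))
}
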