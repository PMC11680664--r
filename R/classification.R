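#' Categories a data set can be assigned to
#'
#' The five loss families, plus `no_net_change` (stable within the +/-.01
#' band), `increasing` (net gain beyond the band), and `removed` (a loss
#' data set whose best fit falls below the trimming threshold).
#' @export
retention_categories <- c(
  "logarithmic", "power", "exponential_power", "hyperbolic_power", "linear",
  "no_net_change", "increasing", "removed"
)

#' Net proportion change across a data set's retention intervals
#'
#' Proportion correct at the longest delay minus proportion correct at the
#' shortest delay. The sum of successive interval-to-interval changes
#' telescopes to the same value.
#'
#' @param ds A [retention_dataset()].
#' @return Signed scalar proportion.
#' @export
net_change <- function(ds) {
  stopifnot(inherits(ds, "retention_dataset"))
  ds$proportions[length(ds$proportions)] - ds$proportions[1L]
}

#' Mean successive change between adjacent retention intervals
#'
#' Diagnostic used in the trim report: the average of the
#' interval-to-interval changes in proportion correct.
#'
#' @param ds A [retention_dataset()].
#' @return Scalar mean of `diff(proportions)`.
#' @export
mean_successive_change <- function(ds) {
  stopifnot(inherits(ds, "retention_dataset"))
  mean(diff(ds$proportions))
}

#' Classify a data set into a retention pattern
#'
#' The checks run in order: a net change inside the closed stability band
#' `[-band, band]` makes the data set `no_net_change` (no fit is consulted);
#' a net gain beyond the band makes it `increasing` (a linear fit is
#' attached for typical-curve rendering when the data admit one); otherwise
#' the data set shows net loss and is labeled with its best-fitting family
#' if that fit reaches `r2 >= trim_threshold`, or `removed` if not. Stable
#' and increasing data sets are never removed, whatever their fit quality.
#'
#' @param ds A [retention_dataset()].
#' @param fs Optional `fit_set` from [fit_all()]; required when the data set
#'   shows net loss.
#' @param band Half-width of the stability band on net change (default .01).
#' @param trim_threshold Minimum best-fit r-squared for a loss data set to
#'   be retained (default .5, around two within-corpus standard deviations
#'   below the mean best fit in the corpora this rule was developed for).
#' @return A `category_assignment`: list with `dataset_id`, `category`,
#'   `net_change`, `initial_memory`, `best_r2` (`NA` for stable/increasing),
#'   `winning_fit` (a `fit_result` or `NULL`), and `tie`.
#' @export
categorize <- function(ds, fs = NULL, band = 0.01, trim_threshold = 0.5) {
  stopifnot(inherits(ds, "retention_dataset"))
  nc <- net_change(ds)
  init <- ds$proportions[1L]
  if (abs(nc) <= band) {
    return(new_assignment(ds$dataset_id, "no_net_change", nc, init))
  }
  if (nc > band) {
    lin <- if (stats::var(ds$proportions) > 0) fit_family(ds, "linear")
           else NULL
    return(new_assignment(ds$dataset_id, "increasing", nc, init,
                          winning_fit = lin))
  }
  if (is.null(fs)) {
    stop("data set ", ds$dataset_id,
         " shows net loss; a fit_set is required to categorize it",
         call. = FALSE)
  }
  stopifnot(inherits(fs, "fit_set"))
  bf <- best_fit(fs)
  category <- if (bf$fit$r2 >= trim_threshold) bf$family else "removed"
  new_assignment(ds$dataset_id, category, nc, init, best_r2 = bf$fit$r2,
                 winning_fit = bf$fit, tie = bf$tie)
}

new_assignment <- function(dataset_id, category, nc, init,
                           best_r2 = NA_real_, winning_fit = NULL,
                           tie = FALSE) {
  structure(
    list(dataset_id = dataset_id, category = category, net_change = nc,
         initial_memory = init, best_r2 = best_r2,
         winning_fit = winning_fit, tie = tie),
    class = "category_assignment"
  )
}

#' @export
print.category_assignment <- function(x, ...) {
  cat(sprintf("<category_assignment> %s -> %s (net change %+.3f%s)\n",
              x$dataset_id, x$category, x$net_change,
              if (is.na(x$best_r2)) "" else sprintf(", best r2 %.3f",
                                                    x$best_r2)))
  invisible(x)
}

#' Tidy table of category assignments
#'
#' @param assignments List of `category_assignment` objects.
#' @return Data frame with one row per data set: `dataset_id`, `category`,
#'   `net_change`, `initial_memory`, `best_r2`, `a`, `b` (of the winning or
#'   attached fit, `NA` otherwise).
#' @export
assignments_table <- function(assignments) {
  out <- do.call(rbind, lapply(assignments, function(x) {
    data.frame(
      dataset_id = x$dataset_id, category = x$category,
      net_change = x$net_change, initial_memory = x$initial_memory,
      best_r2 = x$best_r2,
      a = if (is.null(x$winning_fit)) NA_real_ else x$winning_fit$a,
      b = if (is.null(x$winning_fit)) NA_real_ else x$winning_fit$b,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Partition a corpus into retained and removed data sets
#'
#' Splits the assignments on the `removed` label and summarizes both groups
#' so the consequences of the trimming rule can be inspected: count, mean
#' best r-squared, mean sample size, mean observations per participant,
#' proportion of multiple-study data sets, mean number of retention
#' intervals, mean longest interval, mean initial memory, and mean
#' successive change. Characteristics-derived columns are `NA` when no
#' characteristics table is supplied.
#'
#' @param assignments List of `category_assignment` objects.
#' @param characteristics Optional characteristics data frame (from
#'   [read_corpus()] or [generate_corpus()]).
#' @param datasets Optional named list of [retention_dataset()] used for the
#'   mean successive change.
#' @return List with `retained` (assignments), `removed` (assignments), and
#'   `report` (two-row data frame, one row per group).
#' @export
apply_trimming <- function(assignments, characteristics = NULL,
                           datasets = NULL) {
  cats <- vapply(assignments, function(x) x$category, character(1))
  ids <- vapply(assignments, function(x) x$dataset_id, character(1))
  is_removed <- cats == "removed"

  group_report <- function(keep) {
    sub_ids <- ids[keep]
    ch <- if (!is.null(characteristics)) {
      characteristics[match(sub_ids, characteristics$dataset_id), ,
                      drop = FALSE]
    } else NULL
    col <- function(nm) {
      if (!is.null(ch) && nm %in% names(ch)) mean(ch[[nm]], na.rm = TRUE)
      else NA_real_
    }
    msc <- if (!is.null(datasets)) {
      mean(vapply(datasets[sub_ids], mean_successive_change, numeric(1)))
    } else NA_real_
    data.frame(
      n = sum(keep),
      mean_best_r2 = mean(vapply(assignments[keep],
                                 function(x) x$best_r2, numeric(1)),
                          na.rm = TRUE),
      mean_sample_size = col("sample_size"),
      mean_obs_per_participant = col("obs_per_participant"),
      prop_multiple_study = col("multiple_study"),
      mean_n_retention_intervals = col("n_retention_intervals"),
      mean_longest_ri = col("longest_ri"),
      mean_initial_memory = mean(vapply(assignments[keep],
                                        function(x) x$initial_memory,
                                        numeric(1))),
      mean_successive_change = msc
    )
  }

  report <- rbind(
    cbind(group = "retained", group_report(!is_removed)),
    cbind(group = "removed",
          if (any(is_removed)) group_report(is_removed) else
            data.frame(n = 0L, mean_best_r2 = NA_real_,
                       mean_sample_size = NA_real_,
                       mean_obs_per_participant = NA_real_,
                       prop_multiple_study = NA_real_,
                       mean_n_retention_intervals = NA_real_,
                       mean_longest_ri = NA_real_,
                       mean_initial_memory = NA_real_,
                       mean_successive_change = NA_real_))
  )
  list(retained = assignments[!is_removed],
       removed = assignments[is_removed],
       report = report)
}
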