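#' Construct a retention data set
#'
#' One study condition's retention series: strictly increasing delays in
#' seconds and the proportion correct observed at each delay. At least three
#' retention intervals are required, because three points are needed to fit
#' the two-parameter families.
#'
#' @param dataset_id Identifier (coerced to character scalar).
#' @param times Numeric vector of delays in seconds, strictly increasing.
#'   All delays must be positive unless `allow_zero_first = TRUE`, which
#'   tolerates a single leading zero pending [adjust_zero_delays()].
#' @param proportions Numeric vector in `[0, 1]`, same length as `times`.
#' @param allow_zero_first Permit a zero first delay (unadjusted data)?
#' @return An object of class `retention_dataset`.
#' @examples
#' retention_dataset("ds1", c(60, 3600, 86400), c(0.9, 0.7, 0.5))
#' @export
retention_dataset <- function(dataset_id, times, proportions,
                              allow_zero_first = FALSE) {
  dataset_id <- as.character(dataset_id)[1L]
  times <- as.numeric(times)
  proportions <- as.numeric(proportions)
  if (length(times) != length(proportions)) {
    stop("`times` and `proportions` must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("a retention data set needs at least 3 retention intervals",
         call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(proportions))) {
    stop("`times` and `proportions` must be finite", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  lower_ok <- if (allow_zero_first) {
    times[1L] >= 0 && all(times[-1L] > 0)
  } else {
    all(times > 0)
  }
  if (!lower_ok) {
    stop("all delays must be > 0 (run adjust_zero_delays() on immediate ",
         "tests coded as 0 s)", call. = FALSE)
  }
  if (any(proportions < 0 | proportions > 1)) {
    stop("`proportions` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(dataset_id = dataset_id, times = times, proportions = proportions),
    class = "retention_dataset"
  )
}

#' @export
print.retention_dataset <- function(x, ...) {
  cat(sprintf("<retention_dataset> %s: %d intervals, %.3g s to %.3g s, M %.2f to %.2f\n",
              x$dataset_id, length(x$times), x$times[1L],
              x$times[length(x$times)], x$proportions[1L],
              x$proportions[length(x$proportions)]))
  invisible(x)
}

#' Replace a zero first delay
#'
#' Some studies report their first memory assessment as "immediate" (0 s).
#' The power and logarithmic families are undefined at zero delay, so the
#' zero is replaced either by a nominal epsilon of .01 s (a delay too short
#' to be psychologically meaningful) or by an educated estimate of the true
#' test delay, 30 s by default (roughly the duration of test instructions).
#'
#' @param ds A [retention_dataset()] (a zero delay may only appear first).
#' @param policy `"fixed_epsilon"` or `"estimate"`.
#' @param epsilon Replacement under `"fixed_epsilon"` (seconds).
#' @param estimate Replacement under `"estimate"` (seconds).
#' @return A valid `retention_dataset` with all-positive delays.
#' @export
adjust_zero_delays <- function(ds, policy = c("fixed_epsilon", "estimate"),
                               epsilon = 0.01, estimate = 30) {
  stopifnot(inherits(ds, "retention_dataset"))
  policy <- match.arg(policy)
  times <- ds$times
  if (any(times[-1L] == 0)) {
    stop("zero delay at a non-first position in data set ", ds$dataset_id,
         call. = FALSE)
  }
  if (times[1L] == 0) {
    times[1L] <- switch(policy, fixed_epsilon = epsilon, estimate = estimate)
  }
  retention_dataset(ds$dataset_id, times, ds$proportions)
}

#' Derive retention-interval statistics for one data set
#'
#' @param ds A [retention_dataset()].
#' @return A one-row data frame with `shortest_ri`, `longest_ri`,
#'   `average_ri`, `ri_range` (all seconds), `initial_memory` (proportion at
#'   the shortest delay) and `n_retention_intervals`.
#' @export
derive_retention_stats <- function(ds) {
  stopifnot(inherits(ds, "retention_dataset"))
  data.frame(
    dataset_id = ds$dataset_id,
    shortest_ri = min(ds$times),
    longest_ri = max(ds$times),
    average_ri = mean(ds$times),
    ri_range = max(ds$times) - min(ds$times),
    initial_memory = ds$proportions[1L],
    n_retention_intervals = length(ds$times),
    stringsAsFactors = FALSE
  )
}

#' Derive the degree-of-learning level
#'
#' A 1-4 ordinal code combining the material-complexity band with the number
#' of explicit study exposures: level 1 is complexity 1-4 studied once,
#' level 2 complexity 1-4 studied more than once, level 3 complexity 5-7
#' studied once, level 4 complexity 5-7 studied more than once.
#'
#' @param complexity Integer vector in 1..7.
#' @param multiple_study 0/1 vector (1 = multiple study opportunities).
#' @return Integer vector in 1..4.
#' @examples
#' derive_degree_of_learning(c(3, 2, 6), c(0, 1, 1))
#' @export
derive_degree_of_learning <- function(complexity, multiple_study) {
  if (any(!complexity %in% 1:7)) {
    stop("`complexity` must be in 1..7", call. = FALSE)
  }
  if (any(!multiple_study %in% 0:1)) {
    stop("`multiple_study` must be 0/1", call. = FALSE)
  }
  ifelse(complexity <= 4, 1L, 3L) + as.integer(multiple_study)
}

#' Known assessment-type labels
#' @keywords internal
known_assessment_types <- c(
  "free_recall", "cued_recall", "yes_no_recognition", "forced_choice",
  "savings", "stem_completion", "fragment_completion", "anagram",
  "matching", "problem_solution", "source_monitoring", "completion"
)

#' Default column mapping for corpus files
#'
#' The measurement table is long format (one row per delay) and the
#' characteristics table is wide (one row per data set). Deposited corpora
#' differ in their headers, so the reader takes an explicit mapping from the
#' canonical names to the source column names rather than hard-coding any
#' particular layout.
#'
#' @param ... Overrides, e.g. `time = "delay_seconds"`.
#' @return Named list with elements `measurements` and `characteristics`.
#' @export
corpus_mapping <- function(...) {
  mapping <- list(
    measurements = c(dataset_id = "dataset_id", time = "time_s",
                     proportion = "prop_correct"),
    characteristics = c(
      dataset_id = "dataset_id", paper_id = "paper_id", year = "year",
      sample_size = "sample_size", obs_per_participant = "obs_per_participant",
      material_type = "material_type", complexity = "complexity",
      multiple_study = "multiple_study", distractor = "distractor",
      assessment_type = "assessment_type", design = "design"
    )
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    tab <- if (nm %in% names(mapping$measurements)) "measurements"
           else "characteristics"
    mapping[[tab]][[nm]] <- overrides[[nm]]
  }
  mapping
}

map_columns <- function(df, map, what) {
  missing <- setdiff(unname(map), names(df))
  if (length(missing)) {
    stop("missing ", what, " column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- df[, unname(map), drop = FALSE]
  names(out) <- names(map)
  out
}

#' Read and validate a retention corpus
#'
#' Joins a long-format measurement table with a per-data-set study
#' characteristics table, validates both, and derives the retention-interval
#' statistics, degree of learning, and amount of data
#' (`sample_size * obs_per_participant`).
#'
#' @param measurements Data frame or path to a CSV with one row per
#'   (data set, delay, proportion correct).
#' @param characteristics Data frame or path to a CSV with one row per data
#'   set of coded covariates.
#' @param mapping Column mapping, see [corpus_mapping()].
#' @param zero_delay_policy If non-`NULL`, [adjust_zero_delays()] is applied
#'   with this policy (`"fixed_epsilon"` or `"estimate"`); otherwise a zero
#'   first delay is a validation error.
#' @return An object of class `retention_corpus`: a list with `datasets`
#'   (named list of [retention_dataset()]) and `characteristics` (data frame
#'   including derived variables). Unknown assessment labels are kept but
#'   flagged via a warning and the `"unknown_assessment"` attribute.
#' @export
read_corpus <- function(measurements, characteristics,
                        mapping = corpus_mapping(),
                        zero_delay_policy = NULL) {
  if (is.character(measurements)) {
    measurements <- utils::read.csv(measurements, stringsAsFactors = FALSE)
  }
  if (is.character(characteristics)) {
    characteristics <- utils::read.csv(characteristics,
                                       stringsAsFactors = FALSE)
  }
  meas <- map_columns(measurements, mapping$measurements, "measurement")
  chars <- map_columns(characteristics, mapping$characteristics,
                       "characteristics")
  meas$dataset_id <- as.character(meas$dataset_id)
  chars$dataset_id <- as.character(chars$dataset_id)

  bad <- which(meas$proportion < 0 | meas$proportion > 1 |
                 !is.finite(meas$proportion))
  if (length(bad)) {
    stop("proportion outside [0, 1] in measurement row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  only_meas <- setdiff(unique(meas$dataset_id), chars$dataset_id)
  only_char <- setdiff(chars$dataset_id, unique(meas$dataset_id))
  if (length(only_meas) || length(only_char)) {
    stop("join error; data sets without a match - measurements: [",
         paste(only_meas, collapse = ", "), "], characteristics: [",
         paste(only_char, collapse = ", "), "]", call. = FALSE)
  }
  if (anyDuplicated(chars$dataset_id)) {
    stop("duplicated dataset_id in characteristics table", call. = FALSE)
  }

  datasets <- lapply(split(meas, meas$dataset_id), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    ds <- retention_dataset(d$dataset_id[1L], d$time, d$proportion,
                            allow_zero_first = !is.null(zero_delay_policy))
    if (!is.null(zero_delay_policy)) {
      ds <- adjust_zero_delays(ds, zero_delay_policy)
    }
    ds
  })
  datasets <- datasets[chars$dataset_id]

  unknown <- setdiff(unique(chars$assessment_type), known_assessment_types)
  if (length(unknown)) {
    warning("unknown assessment type(s) kept but flagged: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!chars$complexity %in% 1:7)) {
    stop("complexity outside 1..7 in characteristics table", call. = FALSE)
  }

  chars$amount_of_data <- chars$sample_size * chars$obs_per_participant
  chars$degree_of_learning <-
    derive_degree_of_learning(chars$complexity, chars$multiple_study)
  ri <- do.call(rbind, lapply(datasets, derive_retention_stats))
  chars <- merge(chars, ri, by = "dataset_id", sort = FALSE)
  chars <- chars[match(names(datasets), chars$dataset_id), , drop = FALSE]
  rownames(chars) <- NULL

  structure(
    list(datasets = datasets, characteristics = chars),
    unknown_assessment = unknown,
    class = "retention_corpus"
  )
}

#' @export
print.retention_corpus <- function(x, ...) {
  cat(sprintf("<retention_corpus> %d data sets, %d measurements\n",
              length(x$datasets),
              sum(vapply(x$datasets, function(d) length(d$times), 1L))))
  invisible(x)
}

#' Write a corpus back to its two-table CSV form
#'
#' Inverse of [read_corpus()] under the default column mapping: a long
#' measurement CSV and a wide characteristics CSV (coded columns only;
#' derived columns are recomputed on read).
#'
#' @param corpus A `retention_corpus`.
#' @param measurements_path,characteristics_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_corpus <- function(corpus, measurements_path, characteristics_path) {
  stopifnot(inherits(corpus, "retention_corpus"))
  meas <- do.call(rbind, lapply(corpus$datasets, function(d) {
    data.frame(dataset_id = d$dataset_id, time_s = d$times,
               prop_correct = d$proportions, stringsAsFactors = FALSE)
  }))
  rownames(meas) <- NULL
  coded <- c("dataset_id", "paper_id", "year", "sample_size",
             "obs_per_participant", "material_type", "complexity",
             "multiple_study", "distractor", "assessment_type", "design")
  chars <- corpus$characteristics[, coded, drop = FALSE]
  utils::write.csv(meas, measurements_path, row.names = FALSE)
  utils::write.csv(chars, characteristics_path, row.names = FALSE)
  invisible(c(measurements_path, characteristics_path))
}

#' Collapse and filter rare assessment types for the factor analyses
#'
#' Stem and fragment completion are methodologically close and are collapsed
#' into a single `completion` level. Assessment types represented by fewer
#' than `min_count` data sets carry too little information for group
#' comparisons and are flagged for exclusion from the characteristic
#' analyses (the data sets themselves stay in the corpus).
#'
#' @param chars Characteristics data frame with an `assessment_type` column.
#' @param min_count Minimum data sets an assessment type needs to enter the
#'   characteristic analyses.
#' @param collapse_completion Collapse stem/fragment completion?
#' @return `chars` with `assessment_type` recoded and a logical column
#'   `in_characteristic_analyses`.
#' @export
prepare_assessment_types <- function(chars, min_count = 8,
                                     collapse_completion = TRUE) {
  at <- chars$assessment_type
  if (collapse_completion) {
    at[at %in% c("stem_completion", "fragment_completion")] <- "completion"
  }
  counts <- table(at)
  chars$assessment_type <- at
  chars$in_characteristic_analyses <- counts[at] >= min_count
  chars
}
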