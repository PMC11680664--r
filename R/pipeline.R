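#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: input locations (or
#' in-memory tables), the zero-delay policy, the stability band, the
#' trimming threshold, the weighting scheme, the predictor set and reduction
#' mode, and the output directory. Thresholds and defaults match the
#' package-wide defaults of the individual stages.
#'
#' @param measurements,characteristics Paths to the two corpus CSVs, or
#'   data frames, or `NULL` when `corpus` is supplied directly.
#' @param corpus Optional pre-built `retention_corpus` (e.g. from
#'   [generate_corpus()]); takes precedence over the file inputs.
#' @param mapping Column mapping for [read_corpus()].
#' @param zero_delay_policy Passed to [read_corpus()].
#' @param band Stability band half-width for [categorize()].
#' @param trim_threshold Best-fit r-squared below which loss data sets are
#'   removed.
#' @param weight Weighting scheme for the category distribution.
#' @param predictors Predictor columns for the characteristic analyses.
#' @param reduction_mode Collinearity reduction mode, see
#'   [reduce_predictors()].
#' @param log_longest_ri Log10-transform the longest retention interval (and
#'   other interval predictors present) before ANOVA/regression? Delays span
#'   ten orders of magnitude, so this is on by default.
#' @param min_positives Minimum positives per one-vs-rest regression.
#' @param tree Fit the guide tree stage?
#' @param out_dir Output directory for the report bundle (created if
#'   needed); `NULL` skips writing.
#' @param seed Seed recorded in the manifest and used for any stochastic
#'   stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(measurements = NULL, characteristics = NULL,
                            corpus = NULL, mapping = corpus_mapping(),
                            zero_delay_policy = "fixed_epsilon",
                            band = 0.01, trim_threshold = 0.5,
                            weight = "amount_of_data",
                            predictors = numeric_predictors,
                            reduction_mode = "documented",
                            log_longest_ri = TRUE,
                            min_positives = 10L, tree = TRUE,
                            out_dir = NULL, seed = 1L) {
  if (is.null(corpus) &&
      (is.null(measurements) || is.null(characteristics))) {
    stop("supply either `corpus` or both `measurements` and ",
         "`characteristics`", call. = FALSE)
  }
  for (p in c(measurements, characteristics)) {
    if (is.character(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  if (!(trim_threshold > 0 && trim_threshold < 1)) {
    stop("`trim_threshold` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(measurements = measurements, characteristics = characteristics,
         corpus = corpus, mapping = mapping,
         zero_delay_policy = zero_delay_policy, band = band,
         trim_threshold = trim_threshold, weight = weight,
         predictors = predictors, reduction_mode = reduction_mode,
         log_longest_ri = log_longest_ri, min_positives = min_positives,
         tree = tree, out_dir = out_dir, seed = seed),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full retention-analysis pipeline
#'
#' Executes read -> zero-delay adjustment -> fit -> categorize -> trim ->
#' prevalence -> characteristics, returns every intermediate table, and
#' (when `out_dir` is set) writes the report bundle as CSV/JSON/text plus a
#' run manifest listing the completed stages, the seed, and the
#' configuration. Any stage error aborts with the stage name attached.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `corpus`,
#'   `fitsets`, `fits` (tidy table), `assignments`, `assignments_df`,
#'   `trim`, `distribution`, `quality`, `typical`, `fit_correlations`,
#'   `predictor_correlations`, `reduction`, `anova`, `tukey`, `logistic`,
#'   `tree`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stages_done <- character()

  corpus <- stage("read", {
    if (!is.null(config$corpus)) config$corpus
    else read_corpus(config$measurements, config$characteristics,
                     mapping = config$mapping,
                     zero_delay_policy = config$zero_delay_policy)
  })
  stages_done <- c(stages_done, "read")
  # read_corpus applies the zero-delay policy inline; record it as its own
  # stage so partial reruns can see both completed.
  stages_done <- c(stages_done, "adjust")

  fitsets <- stage("fit", {
    lapply(corpus$datasets, function(ds) {
      if (stats::var(ds$proportions) == 0) NULL else fit_all(ds)
    })
  })
  stages_done <- c(stages_done, "fit")

  assignments <- stage("categorize", {
    lapply(names(corpus$datasets), function(id) {
      categorize(corpus$datasets[[id]], fitsets[[id]],
                 band = config$band,
                 trim_threshold = config$trim_threshold)
    })
  })
  stages_done <- c(stages_done, "categorize")

  trim <- stage("trim", {
    apply_trimming(assignments, corpus$characteristics, corpus$datasets)
  })
  stages_done <- c(stages_done, "trim")

  prevalence <- stage("prevalence", {
    list(
      distribution = weighted_category_distribution(
        assignments, corpus$characteristics, weight = config$weight),
      quality = best_fit_quality_summary(trim$retained),
      typical = typical_curves(trim$retained,
                               times = default_time_grid(60)),
      fit_correlations = fit_quality_correlations(
        Filter(Negate(is.null), fitsets))
    )
  })
  stages_done <- c(stages_done, "prevalence")

  characteristics_out <- stage("characteristics", {
    chars <- prepare_assessment_types(corpus$characteristics)
    retained_ids <- vapply(trim$retained, `[[`, character(1), "dataset_id")
    keep <- chars$dataset_id %in% retained_ids & chars$in_characteristic_analyses
    chars <- chars[keep, , drop = FALSE]
    labels <- vapply(trim$retained, `[[`, character(1), "category")
    names(labels) <- retained_ids
    labels <- labels[chars$dataset_id]

    if (config$log_longest_ri) {
      for (col in intersect(c("shortest_ri", "longest_ri", "average_ri",
                              "ri_range"), names(chars))) {
        chars[[paste0("log10_", col)]] <- log10(pmax(chars[[col]], 0.01))
      }
    }
    pred_all <- config$predictors
    cm <- predictor_correlation_matrix(chars, pred_all)
    red <- reduce_predictors(cm, mode = config$reduction_mode)
    analysis_preds <- red$retained
    if (config$log_longest_ri) {
      analysis_preds <- ifelse(
        analysis_preds %in% c("shortest_ri", "longest_ri", "average_ri",
                              "ri_range"),
        paste0("log10_", analysis_preds), analysis_preds)
    }

    constant <- vapply(analysis_preds,
                       function(p) stats::sd(chars[[p]]) == 0, logical(1))
    if (any(constant)) {
      message("constant predictor(s) excluded from the group analyses: ",
              paste(analysis_preds[constant], collapse = ", "))
      analysis_preds <- analysis_preds[!constant]
    }
    anova_rows <- list()
    tukey_rows <- list()
    for (p in analysis_preds) {
      an <- one_way_anova(chars[[p]], labels, factor_label = p)
      anova_rows[[p]] <- data.frame(factor = p, F = an$F, p = an$p,
                                    eta_p2 = an$eta_p2,
                                    df1 = an$df[1L], df2 = an$df[2L],
                                    stringsAsFactors = FALSE)
      if (an$p < 0.10) {
        tukey_rows[[p]] <- tukey_pairwise(chars[[p]], labels,
                                          factor_label = p)
      }
    }
    logistic <- all_logistic_regressions(
      chars, labels, analysis_preds, min_positives = config$min_positives)
    tree_fit <- if (config$tree && length(labels) >= 50L) {
      train_guide_tree(chars, labels, analysis_preds)
    } else NULL
    list(predictor_correlations = cm, reduction = red,
         anova = do.call(rbind, anova_rows),
         tukey = do.call(rbind, tukey_rows), logistic = logistic,
         tree = tree_fit, analysis_predictors = analysis_preds)
  })
  stages_done <- c(stages_done, "characteristics")

  manifest <- list(
    package = "forgetcurve",
    package_version = as.character(utils::packageVersion("forgetcurve")),
    r_version = R.version.string,
    seed = config$seed,
    n_datasets = length(corpus$datasets),
    stages = stages_done,
    settings = list(band = config$band,
                    trim_threshold = config$trim_threshold,
                    weight = config$weight,
                    reduction_mode = config$reduction_mode,
                    log_longest_ri = config$log_longest_ri)
  )

  result <- structure(
    list(corpus = corpus, fitsets = fitsets,
         fits = fitsets_table(Filter(Negate(is.null), fitsets)),
         assignments = assignments,
         assignments_df = assignments_table(assignments), trim = trim,
         distribution = prevalence$distribution,
         quality = prevalence$quality, typical = prevalence$typical,
         fit_correlations = prevalence$fit_correlations,
         predictor_correlations = characteristics_out$predictor_correlations,
         reduction = characteristics_out$reduction,
         anova = characteristics_out$anova,
         tukey = characteristics_out$tukey,
         logistic = characteristics_out$logistic,
         tree = characteristics_out$tree, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' Write a pipeline report bundle to disk
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  w(result$fits, "fits.csv")
  w(result$assignments_df, "assignments.csv")
  w(result$trim$report, "trim_report.csv")
  w(as.data.frame(result$distribution), "distribution.csv")
  w(result$quality, "best_fit_quality.csv")
  w(result$typical, "typical_curves.csv")
  w(as.data.frame(result$fit_correlations), "fit_correlations.csv")
  w(as.data.frame(result$predictor_correlations),
    "predictor_correlations.csv")
  w(result$reduction$dropped, "predictor_drops.csv")
  w(result$anova, "anova.csv")
  w(result$tukey, "tukey.csv")
  w(result$logistic, "logistic.csv")
  if (!is.null(result$tree)) {
    writeLines(format(result$tree), file.path(out_dir, "guide_tree.txt"))
    writeLines(as.character(guide_tree_json(result$tree)),
               file.path(out_dir, "guide_tree.json"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d data sets; stages: %s\n",
              x$manifest$n_datasets,
              paste(x$manifest$stages, collapse = " -> ")))
  invisible(x)
}
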