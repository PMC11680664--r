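#' The thirteen numeric study-characteristic predictors
#'
#' Canonical predictor set for the collinearity screen: publication year,
#' material complexity, multiple-study flag, degree of learning, distractor
#' flag, design, amount of data, number of retention intervals, the four
#' retention-interval statistics, and initial memory.
#' @export
numeric_predictors <- c(
  "year", "complexity", "multiple_study", "degree_of_learning", "distractor",
  "design", "amount_of_data", "n_retention_intervals", "shortest_ri",
  "longest_ri", "average_ri", "ri_range", "initial_memory"
)

#' Pairwise Pearson correlations among predictors
#'
#' @param characteristics Characteristics data frame.
#' @param predictors Character vector of numeric or 0/1-coded columns.
#' @return Symmetric correlation matrix; entries involving a constant
#'   predictor are `NA` (with a message).
#' @export
predictor_correlation_matrix <- function(characteristics,
                                         predictors = numeric_predictors) {
  missing <- setdiff(predictors, names(characteristics))
  if (length(missing)) {
    stop("predictor column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(characteristics[, predictors, drop = FALSE])
  if (nrow(x) < 3L) stop("need at least 3 records", call. = FALSE)
  constant <- apply(x, 2L, function(v) stats::var(v, na.rm = TRUE) == 0)
  if (any(constant)) {
    message("constant predictor(s), correlations reported as NA: ",
            paste(predictors[constant], collapse = ", "))
  }
  suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
}

#' Reduce collinear predictors
#'
#' Predictors correlated at `|r| >= threshold` are treated as collinear. In
#' `"documented"` mode the standard reduction for this predictor set is
#' applied: retention range is dropped in favor of the longest interval
#' (`r ~ .99`), the shortest and average intervals are dropped in favor of
#' the longest, and degree of learning is dropped in favor of complexity
#' (with which it is strongly correlated, and it is also correlated with the
#' multiple-study flag) - reducing the canonical 13 predictors to 9. In
#' `"greedy"` mode the pair with the largest `|r|` at or above the
#' threshold is found repeatedly and the member with the larger mean
#' absolute correlation against the remaining predictors is dropped.
#'
#' @param cormat Correlation matrix from [predictor_correlation_matrix()].
#' @param threshold Collinearity criterion (default .70).
#' @param mode `"documented"` or `"greedy"`.
#' @return List with `retained` (character vector) and `dropped` (data frame
#'   of variable, the partner that triggered the drop, and their r).
#' @export
reduce_predictors <- function(cormat, threshold = 0.70,
                              mode = c("documented", "greedy")) {
  mode <- match.arg(mode)
  vars <- colnames(cormat)
  dropped <- data.frame(variable = character(), trigger = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  if (mode == "documented") {
    plan <- list(ri_range = "longest_ri", shortest_ri = "longest_ri",
                 average_ri = "longest_ri", degree_of_learning = "complexity")
    for (v in names(plan)) {
      partner <- plan[[v]]
      if (v %in% vars && partner %in% vars) {
        dropped <- rbind(dropped, data.frame(
          variable = v, trigger = partner, r = cormat[v, partner],
          stringsAsFactors = FALSE))
        vars <- setdiff(vars, v)
      }
    }
    return(list(retained = vars, dropped = dropped))
  }
  repeat {
    sub <- abs(cormat[vars, vars, drop = FALSE])
    diag(sub) <- 0
    sub[is.na(sub)] <- 0
    if (max(sub) < threshold) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    pair <- vars[idx]
    mean_abs <- vapply(pair, function(v) {
      mean(abs(cormat[v, setdiff(vars, v)]), na.rm = TRUE)
    }, numeric(1))
    drop_v <- pair[which.max(mean_abs)]
    keep_v <- setdiff(pair, drop_v)
    dropped <- rbind(dropped, data.frame(
      variable = drop_v, trigger = keep_v, r = cormat[drop_v, keep_v],
      stringsAsFactors = FALSE))
    vars <- setdiff(vars, drop_v)
  }
  list(retained = vars, dropped = dropped)
}

# Drop groups with fewer than 2 members, with a message.
usable_groups <- function(values, groups) {
  groups <- as.character(groups)
  keep_lvls <- names(which(table(groups) >= 2L))
  excluded <- setdiff(unique(groups), keep_lvls)
  if (length(excluded)) {
    message("group(s) with < 2 members excluded: ",
            paste(excluded, collapse = ", "))
  }
  keep <- groups %in% keep_lvls
  list(values = values[keep], groups = factor(groups[keep]))
}

#' One-way ANOVA of a characteristic across categories
#'
#' Standard one-way decomposition via [stats::aov()], with partial eta
#' squared computed as `SSbetween / (SSbetween + SSwithin)`. Groups with
#' fewer than two members are excluded with a message.
#'
#' @param values Numeric vector, one value per data set.
#' @param groups Category label per data set.
#' @param factor_label Optional name of the characteristic, for reporting.
#' @return An `anova_result`: list with `factor`, `F`, `p`, `eta_p2`, `df`,
#'   and `group_stats` (per-group n, mean, se).
#' @export
one_way_anova <- function(values, groups, factor_label = "factor") {
  u <- usable_groups(values, groups)
  if (nlevels(u$groups) < 2L) {
    stop("need at least 2 groups with >= 2 members", call. = FALSE)
  }
  fit <- stats::aov(u$values ~ u$groups)
  tab <- summary(fit)[[1L]]
  ssb <- tab[["Sum Sq"]][1L]
  ssw <- tab[["Sum Sq"]][2L]
  gs <- do.call(rbind, lapply(levels(u$groups), function(g) {
    v <- u$values[u$groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
  }))
  structure(
    list(factor = factor_label, F = tab[["F value"]][1L],
         p = tab[["Pr(>F)"]][1L], eta_p2 = ssb / (ssb + ssw),
         df = c(tab[["Df"]][1L], tab[["Df"]][2L]), group_stats = gs),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s: F(%d, %d) = %.2f, p = %.4g, eta_p2 = %.3f\n",
              x$factor, x$df[1L], x$df[2L], x$F, x$p, x$eta_p2))
  invisible(x)
}

#' Tukey pairwise comparisons across categories
#'
#' All pairwise category contrasts with studentized-range-adjusted p values
#' ([stats::TukeyHSD()]), the t statistic of each contrast (difference over
#' its standard error from the pooled ANOVA mean square), and Cohen's d from
#' the pooled within-group standard deviation of the pair. Comparisons with
#' adjusted `p < .05` are labeled significant, `p < .10` marginal.
#'
#' @inheritParams one_way_anova
#' @return Data frame with `group1`, `group2`, `diff`, `t`, `p_adj`, `d`,
#'   `label`.
#' @export
tukey_pairwise <- function(values, groups, factor_label = "factor") {
  u <- usable_groups(values, groups)
  if (nlevels(u$groups) < 2L) {
    stop("need at least 2 groups with >= 2 members", call. = FALSE)
  }
  fit <- stats::aov(u$values ~ u$groups)
  msw <- summary(fit)[[1L]][["Mean Sq"]][2L]
  th <- stats::TukeyHSD(fit)[[1L]]
  pairs <- strsplit(rownames(th), "-", fixed = TRUE)
  out <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    g2 <- pairs[[i]][1L]  # TukeyHSD labels are "lvl2-lvl1" with diff = lvl2 - lvl1
    g1 <- pairs[[i]][2L]
    v1 <- u$values[u$groups == g1]
    v2 <- u$values[u$groups == g2]
    n1 <- length(v1); n2 <- length(v2)
    se <- sqrt(msw * (1 / n1 + 1 / n2))
    pooled_sd <- sqrt(((n1 - 1) * stats::var(v1) + (n2 - 1) * stats::var(v2)) /
                        (n1 + n2 - 2))
    diff <- th[i, "diff"]
    data.frame(
      factor = factor_label, group1 = g1, group2 = g2, diff = diff,
      t = diff / se, p_adj = th[i, "p adj"],
      d = if (pooled_sd > 0) diff / pooled_sd else 0,
      stringsAsFactors = FALSE
    )
  }))
  out$label <- ifelse(out$p_adj < 0.05, "significant",
                      ifelse(out$p_adj < 0.10, "marginal", "ns"))
  rownames(out) <- NULL
  out
}

# Ridge-penalized logistic log-likelihood fit, used only as the fallback
# when maximum likelihood separates. Returns coefficients on the same
# (standardized) scale as the glm path.
ridge_logistic <- function(x, y, lambda = 1e-2) {
  x1 <- cbind(1, x)
  nll <- function(beta) {
    eta <- drop(x1 %*% beta)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda / 2 * sum(beta[-1L]^2)
  }
  gr <- function(beta) {
    p <- stats::plogis(drop(x1 %*% beta))
    drop(crossprod(x1, p - y)) + lambda * c(0, beta[-1L])
  }
  fit <- stats::optim(rep(0, ncol(x1)), nll, gr, method = "BFGS",
                      control = list(maxit = 500))
  fit$par[-1L]
}

#' One-vs-rest logistic regression for a category
#'
#' Fits a maximum-likelihood logistic regression of the indicator
#' "assignment equals `category`" on the retained predictors, which are
#' z-scored first so coefficients and z statistics are scale-free. Perfect
#' or quasi-perfect separation is flagged and the coefficients are then
#' reported from a ridge-penalized fallback fit (z and p set to `NA`).
#' Predicted probabilities from independently fitted one-vs-rest models need
#' not sum to 1 across categories.
#'
#' @param characteristics Characteristics data frame.
#' @param labels Category label per row of `characteristics`.
#' @param category The positive-class category (>= 10 positives required).
#' @param predictors Columns of `characteristics` to use.
#' @return Data frame with `category`, `predictor`, `estimate`, `z`, `p`,
#'   `separation`.
#' @export
one_vs_rest_logistic <- function(characteristics, labels, category,
                                 predictors) {
  y <- as.integer(as.character(labels) == category)
  if (sum(y) < 10L) {
    stop("category ", category, " has fewer than 10 positives", call. = FALSE)
  }
  x <- as.matrix(characteristics[, predictors, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor(s): ",
         paste(predictors[sds == 0], collapse = ", "), call. = FALSE)
  }
  xr <- cor(x)
  diag(xr) <- 0
  if (any(abs(xr) > 0.999, na.rm = TRUE)) {
    warning("near-duplicate predictors supplied to the logistic regression",
            call. = FALSE)
  }
  xz <- scale(x)
  df <- data.frame(y = y, xz)
  names(df) <- c("y", predictors)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial())
  )
  co <- summary(fit)$coefficients
  separated <- !fit$converged ||
    isTRUE(any(abs(stats::coef(fit)[-1L]) > 15, na.rm = TRUE))
  if (separated) {
    beta <- ridge_logistic(xz, y)
    out <- data.frame(category = category, predictor = predictors,
                      estimate = beta, z = NA_real_, p = NA_real_,
                      separation = TRUE, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(category = category,
                      predictor = rownames(co)[-1L],
                      estimate = co[-1L, "Estimate"],
                      z = co[-1L, "z value"],
                      p = co[-1L, "Pr(>|z|)"],
                      separation = FALSE, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' One-vs-rest logistic regressions for every category with enough positives
#'
#' @inheritParams one_vs_rest_logistic
#' @param min_positives Categories with fewer positives are skipped with a
#'   message.
#' @return Stacked data frame of [one_vs_rest_logistic()] results.
#' @export
all_logistic_regressions <- function(characteristics, labels, predictors,
                                     min_positives = 10L) {
  sds <- vapply(predictors,
                function(p) stats::sd(characteristics[[p]]), numeric(1))
  if (any(sds == 0)) {
    message("constant predictor(s) dropped from the regressions: ",
            paste(predictors[sds == 0], collapse = ", "))
    predictors <- predictors[sds > 0]
  }
  cats <- setdiff(unique(as.character(labels)), "removed")
  rows <- lapply(cats, function(cat) {
    if (sum(labels == cat) < min_positives) {
      message("category skipped (too few positives): ", cat)
      return(NULL)
    }
    one_vs_rest_logistic(characteristics, labels, cat, predictors)
  })
  do.call(rbind, rows)
}
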