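#!/usr/bin/env Rscript
# Relate study characteristics to the retention patterns: collinearity
# screen, per-factor ANOVA with Tukey comparisons, one-vs-rest logistic
# regressions, and the gain-ratio guide tree.

suppressPackageStartupMessages(library(forgetcurve))

corpus <- read_corpus("results/corpus/measurements.csv",
                      "results/corpus/characteristics.csv")
assign_df <- utils::read.csv("results/assignments.csv")

chars <- prepare_assessment_types(corpus$characteristics)
keep <- assign_df$category != "removed" & chars$in_characteristic_analyses
chars <- chars[keep, , drop = FALSE]
labels <- assign_df$category[keep]

cm <- predictor_correlation_matrix(chars, numeric_predictors)
red <- reduce_predictors(cm, mode = "documented")
utils::write.csv(as.data.frame(cm), "results/predictor_correlations.csv")
utils::write.csv(red$dropped, "results/predictor_drops.csv",
                 row.names = FALSE)
cat(sprintf("collinearity screen: %d predictors -> %d retained\n",
            ncol(cm), length(red$retained)))
print(red$dropped, row.names = FALSE, digits = 2)

# interval predictors are log10-scaled before the group analyses
chars$log10_longest_ri <- log10(chars$longest_ri)
preds <- ifelse(red$retained == "longest_ri", "log10_longest_ri",
                red$retained)
# the simulated design fixes some features (e.g. the interval count), which
# leaves nothing for a group comparison to explain
constant <- vapply(preds, function(p) stats::sd(chars[[p]]) == 0, logical(1))
if (any(constant)) {
  cat("constant in this corpus, skipped:",
      paste(preds[constant], collapse = ", "), "\n")
  preds <- preds[!constant]
}

anova_tab <- do.call(rbind, lapply(preds, function(p) {
  an <- one_way_anova(chars[[p]], labels, factor_label = p)
  data.frame(factor = p, F = an$F, p = an$p, eta_p2 = an$eta_p2,
             df1 = an$df[1L], df2 = an$df[2L])
}))
utils::write.csv(anova_tab, "results/anova.csv", row.names = FALSE)
cat("\nper-factor ANOVA across categories:\n")
print(anova_tab[order(-anova_tab$F), ], row.names = FALSE, digits = 3)

tukey_tab <- do.call(rbind, lapply(
  anova_tab$factor[anova_tab$p < 0.10], function(p) {
    tukey_pairwise(chars[[p]], labels, factor_label = p)
  }))
if (!is.null(tukey_tab)) {
  sig <- tukey_tab[tukey_tab$label != "ns", ]
  utils::write.csv(sig, "results/tukey.csv", row.names = FALSE)
  cat(sprintf("\n%d significant or marginal Tukey contrasts (see tukey.csv)\n",
              nrow(sig)))
}

logistic <- all_logistic_regressions(chars, labels, preds)
utils::write.csv(logistic, "results/logistic.csv", row.names = FALSE)
strongest <- logistic[!is.na(logistic$p) & logistic$p < 0.05, ]
cat(sprintf("\n%d logistic predictor effects at p < .05; strongest:\n",
            nrow(strongest)))
print(utils::head(strongest[order(strongest$p),
                            c("category", "predictor", "estimate", "z", "p")],
                  8), row.names = FALSE, digits = 3)

if (length(labels) >= 50L) {
  tree <- train_guide_tree(chars, labels, preds)
  writeLines(format(tree), "results/guide_tree.txt")
  writeLines(as.character(guide_tree_json(tree)), "results/guide_tree.json")
  acc <- mean(predict_category(tree, chars)$category == labels)
  cat(sprintf("\nguide tree training accuracy %.2f (majority baseline %.2f)\n",
              acc, max(table(labels)) / length(labels)))
}
cat("wrote characteristics tables and guide tree to results/\n")
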