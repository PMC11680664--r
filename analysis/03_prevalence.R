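#!/usr/bin/env Rscript
# Summarize pattern prevalence: the observation-weighted category
# distribution, how well each family fit where it won, the cross-family fit
# correlations, and the typical curve of each category.

suppressPackageStartupMessages(library(forgetcurve))

corpus <- read_corpus("results/corpus/measurements.csv",
                      "results/corpus/characteristics.csv")
assign_df <- utils::read.csv("results/assignments.csv")
fits <- utils::read.csv("results/fits.csv")

# rebuild assignment objects from the tidy tables
assignments <- lapply(seq_len(nrow(assign_df)), function(i) {
  row <- assign_df[i, ]
  fit <- if (!is.na(row$a)) {
    fam <- if (row$category == "increasing") "linear" else row$category
    forgetcurve:::new_fit_result(fam, row$a, row$b, row$best_r2, TRUE)
  } else NULL
  forgetcurve:::new_assignment(row$dataset_id, row$category, row$net_change,
                               row$initial_memory, row$best_r2, fit)
})
retained <- Filter(function(a) a$category != "removed", assignments)

dist <- weighted_category_distribution(retained, corpus$characteristics)
utils::write.csv(as.data.frame(dist), "results/distribution.csv",
                 row.names = FALSE)
cat("observation-weighted category shares (retained corpus):\n")
print(dist[order(-dist$proportion), c("category", "proportion")],
      row.names = FALSE, digits = 3)

quality <- best_fit_quality_summary(retained)
utils::write.csv(quality, "results/best_fit_quality.csv", row.names = FALSE)
cat("\nwinning r2 per family:\n")
print(quality, row.names = FALSE, digits = 3)

fitsets <- lapply(split(fits, fits$dataset_id), function(d) {
  fl <- lapply(seq_len(nrow(d)), function(i) {
    forgetcurve:::new_fit_result(d$family[i], d$a[i], d$b[i], d$r2[i],
                                 d$converged[i])
  })
  names(fl) <- d$family
  structure(list(dataset_id = d$dataset_id[1L],
                 fits = fl[retention_families]), class = "fit_set")
})
fc <- fit_quality_correlations(fitsets)
utils::write.csv(as.data.frame(fc), "results/fit_correlations.csv")
cat(sprintf("\nfit-quality correlations: log-power %.2f, exp-hyp %.2f, log-linear %.2f\n",
            fc["logarithmic", "power"],
            fc["exponential_power", "hyperbolic_power"],
            fc["logarithmic", "linear"]))

tc <- typical_curves(retained, times = default_time_grid(120))
utils::write.csv(tc, "results/typical_curves.csv", row.names = FALSE)
cat("wrote distribution.csv, best_fit_quality.csv, fit_correlations.csv,",
    "typical_curves.csv to results/\n")
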