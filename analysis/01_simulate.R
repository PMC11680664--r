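#!/usr/bin/env Rscript
# Simulate the study corpus: 500 retention data sets with known generating
# categories, curve parameters, and covariate-category associations, written
# out in the package's two-table CSV schema plus the ground-truth labels.

suppressPackageStartupMessages(library(forgetcurve))

out_dir <- "results/corpus"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

config <- generator_config(n_datasets = 500, noise_sd = 0.01,
                           n_intervals_fixed = 5L, seed = 1L)
corpus <- generate_corpus(config)

write_corpus(corpus,
             file.path(out_dir, "measurements.csv"),
             file.path(out_dir, "characteristics.csv"))
utils::write.csv(corpus$truth, file.path(out_dir, "truth.csv"),
                 row.names = FALSE)

cat(sprintf("simulated %d data sets (noise sd %.2f, %d intervals each)\n",
            length(corpus$datasets), config$noise_sd, 5L))
print(table(corpus$labels))
cat(sprintf("initial memory: mean %.2f; longest interval: median %.3g s\n",
            mean(corpus$characteristics$initial_memory),
            stats::median(corpus$characteristics$longest_ri)))
cat("wrote measurements.csv, characteristics.csv, truth.csv to",
    out_dir, "\n")
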