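# Shared fixtures, all built in code.

# Noise-free data set generated exactly from one family.
exact_dataset <- function(family, a, b, times = c(1, 30, 600, 7200, 86400),
                          id = paste0("exact_", family)) {
  mu <- forgetcurve:::family_value(family, a, b, times)
  stopifnot(all(mu >= 0 & mu <= 1))
  retention_dataset(id, times, mu)
}

# Reference parameters per family on the default fixture grid, chosen so
# trajectories stay inside [0, 1].
reference_params <- list(
  logarithmic       = c(a = 0.9, b = 0.05),
  power             = c(a = 0.8, b = -0.15),
  exponential_power = c(a = 0.85, b = 0.02),
  hyperbolic_power  = c(a = 1.2, b = 0.05),
  linear            = c(a = 0.8, b = -5e-6)
)

# A small hand-built two-table corpus in the default CSV schema.
toy_corpus_tables <- function() {
  measurements <- data.frame(
    dataset_id = rep(c("d1", "d2"), each = 3),
    time_s = c(60, 3600, 86400, 0, 300, 7200),
    prop_correct = c(0.9, 0.7, 0.5, 0.8, 0.75, 0.7),
    stringsAsFactors = FALSE
  )
  characteristics <- data.frame(
    dataset_id = c("d1", "d2"), paper_id = c("p1", "p1"),
    year = c(1990L, 2005L), sample_size = c(20L, 40L),
    obs_per_participant = c(10L, 5L),
    material_type = c("words", "stories"), complexity = c(2L, 7L),
    multiple_study = c(0L, 1L), distractor = c(0L, 1L),
    assessment_type = c("free_recall", "cued_recall"),
    design = c(0L, 1L), stringsAsFactors = FALSE
  )
  list(measurements = measurements, characteristics = characteristics)
}

# Independent dense-lattice least-squares oracle for the nonlinear
# families: the best SSE over a fixed a x b grid. Ranges are broad and
# family-specific; they do not depend on the fitted values.
grid_search_sse <- function(family, t, m) {
  grids <- switch(family,
    power = list(a = seq(0.01, 2, length.out = 80),
                 b = seq(-2, 1, length.out = 80)),
    exponential_power = list(a = seq(0.01, 2, length.out = 80),
                             b = seq(-0.2, 0.5, length.out = 80)),
    hyperbolic_power = list(a = seq(0.1, 20, length.out = 80),
                            b = seq(-0.5, 2, length.out = 80))
  )
  best <- Inf
  for (a in grids$a) {
    for (b in grids$b) {
      sse <- forgetcurve:::family_sse(family, a, b, t, m)
      if (sse < best) best <- sse
    }
  }
  best
}

# Classify one data set end to end (fit only when it shows net loss).
classify_dataset <- function(ds, ...) {
  nc <- net_change(ds)
  fs <- if (nc < -0.01 && stats::var(ds$proportions) > 0) fit_all(ds)
        else NULL
  categorize(ds, fs, ...)
}

# Classify a whole corpus; returns the assignment list, named by id.
classify_corpus <- function(corpus, ...) {
  out <- lapply(corpus$datasets, function(ds) {
    fs <- if (stats::var(ds$proportions) > 0) fit_all(ds) else NULL
    categorize(ds, fs, ...)
  })
  names(out) <- names(corpus$datasets)
  out
}
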