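test_that("net change is last minus first observed proportion", {
  expect_equal(net_change(retention_dataset("d", 1:3, c(0.8, 0.7, 0.6))),
               -0.2)
  expect_equal(net_change(retention_dataset("d", 1:3, c(0.5, 0.48, 0.505))),
               0.005)
  expect_equal(net_change(retention_dataset("d", 1:3, c(0.5, 0.6, 0.65))),
               0.15)
  # telescoping: equal to the sum of successive changes
  ds <- retention_dataset("d", 1:5, c(0.9, 0.6, 0.7, 0.4, 0.45))
  expect_equal(net_change(ds), sum(diff(ds$proportions)))
  expect_equal(mean_successive_change(ds), mean(diff(ds$proportions)))
})

test_that("the stability band and increasing rule apply before any fit", {
  flat <- retention_dataset("f", c(1, 10, 100), c(0.6, 0.6, 0.6))
  expect_equal(categorize(flat)$category, "no_net_change")
  up <- retention_dataset("u", c(1, 10, 100), c(0.5, 0.6, 0.7))
  a_up <- categorize(up)
  expect_equal(a_up$category, "increasing")
  expect_equal(a_up$winning_fit$family, "linear")
  # the band is closed: a net change exactly at +/-band is stable, one ulp
  # past it is not (binary-exact band so the equality is tested exactly)
  band <- 1 / 128
  at_band <- retention_dataset("b1", c(1, 10, 100),
                               c(0.5, 0.495, 0.5 - band))
  expect_equal(net_change(at_band), -band)
  expect_equal(categorize(at_band, band = band)$category, "no_net_change")
  up_band <- retention_dataset("b2", c(1, 10, 100), c(0.5, 0.51, 0.5 + band))
  expect_equal(categorize(up_band, band = band)$category, "no_net_change")
  past_band <- retention_dataset("b3", c(1, 10, 100),
                                 c(0.5, 0.51, 0.5 + band + 2^-20))
  expect_equal(categorize(past_band, band = band)$category, "increasing")
  expect_error(
    categorize(retention_dataset("l", c(1, 10, 100), c(0.8, 0.6, 0.4))),
    "fit_set is required")
})

test_that("loss data sets get their best family or are removed at the threshold", {
  good <- exact_dataset("power", 0.8, -0.2, times = c(1, 10, 100, 1000))
  a <- categorize(good, fit_all(good))
  expect_equal(a$category, "power")
  expect_equal(a$best_r2, 1, tolerance = 1e-9)
  # oscillating series with net loss: no monotone family fits it well
  noisy <- retention_dataset("n", c(1, 5, 25, 125, 625, 3125),
                             c(0.8, 0.25, 0.75, 0.2, 0.7, 0.15))
  fs <- fit_all(noisy)
  expect_lt(best_fit(fs)$fit$r2, 0.5)
  expect_equal(categorize(noisy, fs)$category, "removed")
  # the same data set is retained once the threshold drops below its fit
  r2 <- best_fit(fs)$fit$r2
  expect_false(categorize(noisy, fs,
                          trim_threshold = r2 / 2)$category == "removed")
})

test_that("lowering the trim threshold never removes more data sets", {
  set.seed(31)
  corpus <- generate_corpus(generator_config(n_datasets = 40, noise_sd = 0.08,
                                             seed = 31))
  for (id in names(corpus$datasets)) {
    ds <- corpus$datasets[[id]]
    fs <- if (var(ds$proportions) > 0) fit_all(ds) else NULL
    strict <- categorize(ds, fs, trim_threshold = 0.5)$category
    lax <- categorize(ds, fs, trim_threshold = 0.3)$category
    if (lax == "removed") expect_equal(strict, "removed")
    if (strict != "removed") expect_equal(lax, strict)
  }
})

test_that("stable and increasing data sets are never removed", {
  jagged_flat <- retention_dataset("jf", c(1, 10, 100, 1000),
                                   c(0.5, 0.9, 0.1, 0.5))
  expect_equal(categorize(jagged_flat)$category, "no_net_change")
  jagged_up <- retention_dataset("ju", c(1, 10, 100, 1000),
                                 c(0.3, 0.9, 0.1, 0.8))
  expect_equal(categorize(jagged_up)$category, "increasing")
})

test_that("apply_trimming partitions the corpus and reports group summaries", {
  corpus <- generate_corpus(generator_config(n_datasets = 30, noise_sd = 0.01,
                                             seed = 8))
  assignments <- classify_corpus(corpus)
  # append two constructed sub-threshold loss data sets
  bad <- retention_dataset("bad1", c(1, 5, 25, 125, 625, 3125),
                           c(0.8, 0.25, 0.75, 0.2, 0.7, 0.15))
  bad2 <- retention_dataset("bad2", c(1, 5, 25, 125, 625),
                            c(0.9, 0.2, 0.85, 0.15, 0.3))
  assignments <- c(assignments, list(categorize(bad, fit_all(bad)),
                                     categorize(bad2, fit_all(bad2))))
  expect_equal(sum(vapply(assignments, function(x)
    x$category == "removed", logical(1))), 2L)
  all_datasets <- c(corpus$datasets, list(bad1 = bad, bad2 = bad2))
  trim <- apply_trimming(assignments, corpus$characteristics, all_datasets)
  expect_equal(length(trim$retained) + length(trim$removed),
               length(assignments))
  expect_equal(trim$report$n, c(30L, 2L))
  expect_length(intersect(
    vapply(trim$retained, `[[`, character(1), "dataset_id"),
    vapply(trim$removed, `[[`, character(1), "dataset_id")), 0L)
  ret_row <- trim$report[trim$report$group == "retained", ]
  expect_true(ret_row$mean_best_r2 > 0.5)
  expect_true(is.finite(ret_row$mean_sample_size))
  expect_true(is.finite(ret_row$mean_successive_change))
  # no removed data sets: empty removed set, counts preserved
  trim0 <- apply_trimming(assignments[seq_len(30)], corpus$characteristics,
                          corpus$datasets)
  expect_length(trim0$removed, 0L)
  expect_equal(trim0$report$n, c(30L, 0L))
})

test_that("every data set receives exactly one category", {
  corpus <- generate_corpus(generator_config(n_datasets = 25, noise_sd = 0.05,
                                             seed = 12))
  assignments <- classify_corpus(corpus)
  tab <- assignments_table(assignments)
  expect_equal(nrow(tab), 25L)
  expect_equal(anyDuplicated(tab$dataset_id), 0L)
  expect_true(all(tab$category %in% retention_categories))
})
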