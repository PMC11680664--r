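test_that("sample_times is seeded, log-spaced, and strictly increasing", {
  g1 <- sample_times(3, 60, 86400, seed = 1)
  g2 <- sample_times(3, 60, 86400, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(g1, sample_times(3, 60, 86400, seed = 2)))
  for (i in 1:20) {
    g <- sample_times(sample(3:10, 1), 1, 1e8, seed = i)
    expect_true(all(diff(g) > 0))
  }
  # zero jitter gives the exact log-spaced grid
  expect_equal(sample_times(3, 1, 100, jitter = 0), c(1, 10, 100),
               tolerance = 1e-12)
  expect_error(sample_times(2, 1, 100), ">= 3")
  expect_error(sample_times(3, 100, 1), "span")
})

test_that("generate_dataset reproduces its trajectory under a seed", {
  times <- sample_times(5, 60, 86400, seed = 3)
  d1 <- generate_dataset("power", list(a = 0.8, b = -0.2), times,
                         noise_sd = 0.02, seed = 11)
  d2 <- generate_dataset("power", list(a = 0.8, b = -0.2), times,
                         noise_sd = 0.02, seed = 11)
  expect_identical(d1$proportions, d2$proportions)
  expect_equal(attr(d1, "true_category"), "power")
  expect_equal(attr(d1, "true_b"), -0.2)
})

test_that("noise-free generation classifies back to its category", {
  times <- c(1, 30, 600, 7200, 86400)
  lin <- generate_dataset("linear", list(a = 0.9, b = -1e-6), times,
                          noise_sd = 0)
  expect_equal(classify_dataset(lin)$category, "linear")
  flat <- generate_dataset("no_net_change", list(level = 0.6), times,
                           noise_sd = 0)
  expect_equal(net_change(flat), 0)
  expect_equal(classify_dataset(flat)$category, "no_net_change")
  up <- generate_dataset("increasing", list(a = 0.4, b = 5e-6), times,
                         noise_sd = 0)
  expect_equal(classify_dataset(up)$category, "increasing")
  expect_error(
    generate_dataset("power", list(a = 40, b = 0.1), times, noise_sd = 0),
    "outside \\[0, 1\\]")
})

test_that("stable datasets keep their defining band under noise", {
  times <- sample_times(5, 60, 86400, seed = 4)
  for (i in 1:50) {
    ds <- generate_dataset("no_net_change", list(level = 0.7), times,
                           noise_sd = 0.01, seed = i)
    expect_lte(abs(net_change(ds)), 0.01)
  }
})

test_that("generated parameters are recovered with small bias under noise", {
  set.seed(27)
  n_rep <- 200
  for (family in retention_families) {
    rel_err <- replicate(n_rep, {
      times <- sample_times(5, 60, 60 * 86400)
      m0 <- runif(1, 0.6, 0.9)
      drop <- runif(1, 0.15, min(0.5, m0 - 0.05))
      p <- forgetcurve:::solve_endpoint_params(family, min(times),
                                               max(times), m0, m0 - drop)
      ds <- generate_dataset(family, p, times, noise_sd = 0.02)
      fit <- fit_family(ds, family)
      (fit$b - p$b) / p$b
    })
    expect_lt(abs(mean(rel_err)), 0.10)
  }
})

test_that("generate_corpus is deterministic and mixture-faithful", {
  cfg <- generator_config(n_datasets = 50, seed = 101)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$characteristics, c2$characteristics)
  expect_identical(lapply(c1$datasets, `[[`, "proportions"),
                   lapply(c2$datasets, `[[`, "proportions"))
  expect_identical(c1$labels, c2$labels)
  # degenerate mixture: every label is the chosen category
  only_up <- generator_config(
    n_datasets = 20,
    mixture = c(logarithmic = 0, power = 0, exponential_power = 0,
                hyperbolic_power = 0, linear = 0, no_net_change = 0,
                increasing = 1),
    seed = 5)
  cu <- generate_corpus(only_up)
  expect_true(all(cu$labels == "increasing"))
  expect_error(generator_config(n_datasets = 10, mixture = c(bad = 1)),
               "named over")
})

test_that("generated corpora pass corpus validation on re-read", {
  corpus <- generate_corpus(generator_config(n_datasets = 25, seed = 77))
  ch <- corpus$characteristics
  expect_equal(ch$amount_of_data, ch$sample_size * ch$obs_per_participant)
  expect_equal(ch$ri_range, ch$longest_ri - ch$shortest_ri)
  expect_true(all(ch$complexity %in% 1:7))
  expect_true(all(ch$degree_of_learning %in% 1:4))
  expect_true(all(ch$initial_memory >= 0 & ch$initial_memory <= 1))
  # the CSV round trip re-runs the full read_corpus validation
  mpath <- tempfile(fileext = ".csv")
  cpath <- tempfile(fileext = ".csv")
  write_corpus(corpus, mpath, cpath)
  expect_s3_class(read_corpus(mpath, cpath), "retention_corpus")
  unlink(c(mpath, cpath))
})

test_that("planted covariate shifts surface in the generated corpus", {
  corpus <- generate_corpus(generator_config(n_datasets = 600, seed = 55))
  ch <- corpus$characteristics
  labs <- unname(corpus$labels)
  # long-retention categories get longer longest intervals than power
  expect_gt(mean(log10(ch$longest_ri[labs == "linear"])),
            mean(log10(ch$longest_ri[labs == "power"])))
  expect_gt(mean(log10(ch$longest_ri[labs == "increasing"])),
            mean(log10(ch$longest_ri[labs == "logarithmic"])))
  # power datasets use simpler materials and fewer repeated exposures
  expect_lt(mean(ch$complexity[labs == "power"]),
            mean(ch$complexity[labs == "linear"]))
  expect_lt(mean(ch$multiple_study[labs == "power"]),
            mean(ch$multiple_study[labs == "increasing"]))
  # increasing datasets start lower; exponential-power starts higher
  expect_lt(mean(ch$initial_memory[labs == "increasing"]),
            mean(ch$initial_memory[labs == "exponential_power"]))
})
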