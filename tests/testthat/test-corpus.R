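test_that("retention_dataset enforces its invariants", {
  expect_error(retention_dataset("d", c(1, 2), c(0.5, 0.4)), "at least 3")
  expect_error(retention_dataset("d", c(1, 2, 2), c(0.5, 0.4, 0.3)),
               "strictly increasing")
  expect_error(retention_dataset("d", c(0, 2, 3), c(0.5, 0.4, 0.3)),
               "> 0")
  expect_error(retention_dataset("d", c(1, 2, 3), c(0.5, 0.4, 1.3)),
               "\\[0, 1\\]")
  expect_error(retention_dataset("d", c(1, 2, 3), c(0.5, 0.4)),
               "equal length")
})

test_that("zero-delay adjustment implements both policies", {
  ds0 <- retention_dataset("d", c(0, 60, 3600), c(0.9, 0.8, 0.7),
                           allow_zero_first = TRUE)
  expect_equal(adjust_zero_delays(ds0, "fixed_epsilon")$times,
               c(0.01, 60, 3600))
  expect_equal(adjust_zero_delays(ds0, "estimate")$times, c(30, 60, 3600))
  expect_equal(adjust_zero_delays(ds0, "estimate", estimate = 10)$times,
               c(10, 60, 3600))
  # already-positive times are unchanged
  ds1 <- retention_dataset("d", c(5, 60, 3600), c(0.9, 0.8, 0.7))
  expect_equal(adjust_zero_delays(ds1, "fixed_epsilon")$times,
               c(5, 60, 3600))
})

test_that("degree of learning combines complexity band and exposures", {
  expect_equal(derive_degree_of_learning(3, 0), 1L)
  expect_equal(derive_degree_of_learning(2, 1), 2L)
  expect_equal(derive_degree_of_learning(6, 0), 3L)
  expect_equal(derive_degree_of_learning(6, 1), 4L)
  expect_equal(derive_degree_of_learning(c(1, 4, 5, 7), c(1, 0, 1, 0)),
               c(2L, 1L, 4L, 3L))
  expect_error(derive_degree_of_learning(8, 0), "1..7")
  expect_error(derive_degree_of_learning(3, 2), "0/1")
})

test_that("retention statistics are derived correctly and idempotently", {
  ds <- retention_dataset("d", c(60, 3600, 86400), c(0.9, 0.7, 0.5))
  st <- derive_retention_stats(ds)
  expect_equal(st$shortest_ri, 60)
  expect_equal(st$longest_ri, 86400)
  expect_equal(st$average_ri, 30020)
  expect_equal(st$ri_range, 86340)
  expect_equal(st$initial_memory, 0.9)
  expect_equal(st$n_retention_intervals, 3L)
  expect_identical(derive_retention_stats(ds), st)
})

test_that("read_corpus joins, validates, and derives", {
  tabs <- toy_corpus_tables()
  corpus <- read_corpus(tabs$measurements, tabs$characteristics,
                        zero_delay_policy = "fixed_epsilon")
  expect_s3_class(corpus, "retention_corpus")
  expect_length(corpus$datasets, 2L)
  expect_equal(corpus$datasets$d2$times[1L], 0.01)  # zero delay adjusted
  ch <- corpus$characteristics
  expect_equal(ch$amount_of_data, ch$sample_size * ch$obs_per_participant)
  expect_equal(ch$degree_of_learning, c(1L, 4L))
  expect_equal(ch$ri_range, ch$longest_ri - ch$shortest_ri)
  expect_true(all(ch$shortest_ri <= ch$average_ri &
                    ch$average_ri <= ch$longest_ri))
  expect_equal(ch$n_retention_intervals, c(3L, 3L))

  # invalid proportion is rejected with row coordinates
  bad <- tabs
  bad$measurements$prop_correct[2L] <- 1.2
  expect_error(read_corpus(bad$measurements, bad$characteristics),
               "row")
  # zero delay without a policy is a validation error
  expect_error(read_corpus(tabs$measurements, tabs$characteristics),
               "> 0")
  # join mismatches name the offenders
  orphan <- tabs
  orphan$characteristics <- orphan$characteristics[1L, , drop = FALSE]
  expect_error(read_corpus(orphan$measurements, orphan$characteristics,
                           zero_delay_policy = "fixed_epsilon"),
               "d2")
  # unknown assessment labels are kept but flagged
  odd <- tabs
  odd$characteristics$assessment_type[1L] <- "telepathy"
  expect_warning(
    corpus2 <- read_corpus(odd$measurements, odd$characteristics,
                           zero_delay_policy = "fixed_epsilon"),
    "telepathy")
  expect_equal(attr(corpus2, "unknown_assessment"), "telepathy")
})

test_that("column mapping resolves non-default headers", {
  tabs <- toy_corpus_tables()
  names(tabs$measurements) <- c("id", "delay", "score")
  corpus <- read_corpus(tabs$measurements, tabs$characteristics,
                        mapping = corpus_mapping(dataset_id = "id",
                                                 time = "delay",
                                                 proportion = "score"),
                        zero_delay_policy = "fixed_epsilon")
  expect_length(corpus$datasets, 2L)
  expect_error(read_corpus(tabs$measurements, tabs$characteristics,
                           zero_delay_policy = "fixed_epsilon"),
               "missing measurement column")
})

test_that("a corpus round-trips through its CSV form", {
  corpus <- generate_corpus(generator_config(n_datasets = 12, seed = 4))
  mpath <- tempfile(fileext = ".csv")
  cpath <- tempfile(fileext = ".csv")
  write_corpus(corpus, mpath, cpath)
  back <- read_corpus(mpath, cpath)
  expect_equal(names(back$datasets), names(corpus$datasets))
  for (id in names(corpus$datasets)) {
    expect_equal(back$datasets[[id]]$times, corpus$datasets[[id]]$times)
    expect_equal(back$datasets[[id]]$proportions,
                 corpus$datasets[[id]]$proportions)
  }
  shared <- intersect(names(back$characteristics),
                      names(corpus$characteristics))
  expect_equal(back$characteristics[, shared],
               corpus$characteristics[, shared])
  unlink(c(mpath, cpath))
})

test_that("assessment types are collapsed and rare levels flagged", {
  chars <- data.frame(
    dataset_id = sprintf("d%02d", 1:20),
    assessment_type = c(rep("free_recall", 10), rep("stem_completion", 4),
                        rep("fragment_completion", 4), "anagram", "matching"),
    stringsAsFactors = FALSE
  )
  out <- prepare_assessment_types(chars, min_count = 8)
  expect_equal(sum(out$assessment_type == "completion"), 8L)
  expect_true(all(out$in_characteristic_analyses[
    out$assessment_type %in% c("free_recall", "completion")]))
  expect_false(any(out$in_characteristic_analyses[
    out$assessment_type %in% c("anagram", "matching")]))
})
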