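test_that("predictor correlations detect duplicates and derived identities", {
  set.seed(2)
  chars <- data.frame(year = rnorm(30), complexity = rnorm(30))
  chars$year_copy <- chars$year
  cm <- predictor_correlation_matrix(chars, c("year", "complexity",
                                              "year_copy"))
  expect_equal(cm["year", "year_copy"], 1)
  expect_true(isSymmetric(cm))
  # with a constant shortest interval, range and longest are identical
  chars2 <- data.frame(longest_ri = 10^runif(30, 3, 8))
  chars2$shortest_ri <- 60
  chars2$ri_range <- chars2$longest_ri - chars2$shortest_ri
  cm2 <- predictor_correlation_matrix(chars2, c("longest_ri", "ri_range",
                                                "shortest_ri"))
  expect_equal(cm2["longest_ri", "ri_range"], 1, tolerance = 1e-12)
  expect_message(
    cm3 <- predictor_correlation_matrix(chars2, c("longest_ri",
                                                  "shortest_ri")),
    "constant")
  expect_true(is.na(cm3["longest_ri", "shortest_ri"]))
  expect_error(predictor_correlation_matrix(chars, "absent"), "not found")
})

test_that("documented reduction takes the canonical 13 predictors to 9", {
  corpus <- generate_corpus(generator_config(n_datasets = 120, seed = 9))
  cm <- predictor_correlation_matrix(corpus$characteristics,
                                     numeric_predictors)
  red <- reduce_predictors(cm, mode = "documented")
  expect_length(red$retained, 9L)
  expect_setdiff <- function(a, b) expect_true(all(!a %in% b))
  expect_setdiff(c("ri_range", "shortest_ri", "average_ri",
                   "degree_of_learning"), red$retained)
  expect_true(all(c("longest_ri", "complexity") %in% red$retained))
  expect_equal(nrow(red$dropped), 4L)
  expect_true(all(is.finite(red$dropped$r)))
})

test_that("greedy reduction never retains a collinear pair", {
  set.seed(14)
  n <- 60
  x1 <- rnorm(n)
  chars <- data.frame(x1 = x1, x2 = x1 + rnorm(n, 0, 0.01),
                      x3 = rnorm(n), x4 = rnorm(n))
  cm <- predictor_correlation_matrix(chars, c("x1", "x2", "x3", "x4"))
  red <- reduce_predictors(cm, threshold = 0.7, mode = "greedy")
  expect_length(intersect(c("x1", "x2"), red$retained), 1L)
  sub <- abs(cm[red$retained, red$retained])
  diag(sub) <- 0
  expect_lt(max(sub), 0.7)
  # nothing above threshold: everything is retained
  red2 <- reduce_predictors(cm[c("x3", "x4"), c("x3", "x4")],
                            threshold = 0.7, mode = "greedy")
  expect_equal(sort(red2$retained), c("x3", "x4"))
  expect_equal(nrow(red2$dropped), 0L)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  an <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(an$F, 1.5)
  expect_equal(an$eta_p2, 1.5 / 5.5, tolerance = 1e-12)
  expect_equal(an$df, c(1L, 4L))
  expect_equal(an$group_stats$mean, c(2, 3))
  # identical groups: F = 0
  an0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(an0$F, 0)
  # equal means, unequal variance: zero numerator
  an1 <- one_way_anova(c(1.9, 2.0, 2.1, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(an1$F, 0, tolerance = 1e-12)
  # singleton groups are excluded with a message
  expect_message(
    an2 <- one_way_anova(c(1, 2, 3, 2, 3, 4, 9), c(rep(c("g1", "g2"), 3),
                                                   "solo")),
    "solo")
  expect_equal(an2$df[1L], 1L)
  expect_error(one_way_anova(1:4, c("a", "a", "a", "b")), "2 groups")
})

test_that("Tukey pairwise results carry t, adjusted p, and Cohen's d", {
  # two identical groups: d = 0, p near 1
  tk0 <- tukey_pairwise(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(tk0$d, 0)
  expect_gt(tk0$p_adj, 0.99)
  # three-group case against TukeyHSD's own adjusted p
  set.seed(7)
  vals <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 3))
  grp <- rep(c("a", "b", "c"), each = 10)
  tk <- tukey_pairwise(vals, grp)
  expect_equal(nrow(tk), 3L)
  th <- stats::TukeyHSD(stats::aov(vals ~ factor(grp)))[[1L]]
  expect_equal(sort(tk$p_adj), sort(unname(th[, "p adj"])))
  # d for unit-separated groups with pooled sd ~1
  big <- tk[tk$group1 == "a" & tk$group2 == "c", ]
  expect_gt(abs(big$d), 1)
  expect_equal(big$label, "significant")
  # t is the contrast difference over its pooled-MS standard error
  ms_w <- summary(stats::aov(vals ~ factor(grp)))[[1L]][["Mean Sq"]][2L]
  expect_equal(big$t, big$diff / sqrt(ms_w * (2 / 10)), tolerance = 1e-12)
})

test_that("Tukey adjusted p agrees with a permutation oracle on a toy case", {
  set.seed(42)
  vals <- c(2.1, 2.5, 1.9, 2.3, 3.6, 3.9, 3.2, 3.8, 2.2, 2.6, 2.0, 2.4)
  grp <- rep(c("a", "b", "c"), each = 4)
  tk <- tukey_pairwise(vals, grp)
  # permutation distribution of the maximum |pairwise t| (the studentized
  # range family-wise reference, up to the sqrt(2) rescaling)
  max_abs_t <- function(v) {
    max(abs(tukey_pairwise(v, grp)$t))
  }
  obs <- tk$t[tk$group1 == "a" & tk$group2 == "b"]
  perm <- replicate(400, max_abs_t(sample(vals)))
  p_perm <- mean(perm >= abs(obs))
  p_tukey <- tk$p_adj[tk$group1 == "a" & tk$group2 == "b"]
  expect_lt(abs(p_perm - p_tukey), 0.05)
})

test_that("one-vs-rest logistic recovers a planted coefficient sign", {
  set.seed(23)
  n <- 400
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  eta <- -0.5 + 1.2 * x1
  y <- rbinom(n, 1, plogis(eta))
  labels <- ifelse(y == 1, "linear", "other")
  chars <- data.frame(x1 = x1, x2 = x2)
  res <- one_vs_rest_logistic(chars, labels, "linear", c("x1", "x2"))
  expect_false(any(res$separation))
  expect_gt(res$estimate[res$predictor == "x1"], 0)
  expect_lt(res$p[res$predictor == "x1"], 0.001)
  # null predictor: z near zero on average
  expect_gt(res$p[res$predictor == "x2"], 0.01)
  expect_true(all(plogis(as.matrix(cbind(1, scale(chars))) %*%
                           c(0, res$estimate)) > 0))
})

test_that("logistic preconditions and degenerate designs are caught", {
  set.seed(3)
  chars <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  labels <- c(rep("rare", 5), rep("other", 35))
  expect_error(one_vs_rest_logistic(chars, labels, "rare", c("x1", "x2")),
               "fewer than 10")
  chars$x3 <- chars$x1
  labels2 <- rep(c("a", "b"), each = 20)
  expect_warning(one_vs_rest_logistic(chars, labels2, "a",
                                      c("x1", "x3", "x2")),
                 "near-duplicate")
  chars$c0 <- 1
  expect_error(one_vs_rest_logistic(chars, labels2, "a", c("x1", "c0")),
               "constant")
})

test_that("perfect separation triggers the penalized fallback", {
  chars <- data.frame(x1 = c(seq(-2, -0.1, length.out = 15),
                             seq(0.1, 2, length.out = 15)),
                      x2 = rnorm(30))
  labels <- rep(c("neg", "pos"), each = 15)
  res <- one_vs_rest_logistic(chars, labels, "pos", c("x1", "x2"))
  expect_true(all(res$separation))
  expect_true(all(is.na(res$z)))
  expect_gt(res$estimate[res$predictor == "x1"], 0)
})

test_that("ANOVA type-I error under label shuffling is nominal", {
  set.seed(19)
  corpus <- generate_corpus(generator_config(n_datasets = 150, seed = 19))
  vals <- corpus$characteristics$complexity
  labs <- unname(corpus$labels)
  pv <- replicate(500, one_way_anova(vals, sample(labs))$p)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.03)
})
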