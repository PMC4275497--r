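test_that("absolute OR folds below-one odds ratios", {
  expect_identical(abs_or(0.5), 2.0)
  expect_identical(abs_or(1.0), 1.0)
  expect_identical(abs_or(3.45), 3.45)
  expect_equal(abs_or(c(0.25, 4)), c(4, 4))
  expect_error(abs_or(0), "positive")
  expect_error(abs_or(-2), "positive")
})

test_that("aggregate-benchmark OR matches its closed form", {
  r <- or_vs_aggregate_benchmark(0.3, 1000, 0.3)
  expect_equal(r$or, 1, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  r2 <- or_vs_aggregate_benchmark(0.129, 2000, 0.03)
  expect_equal(r2$or, (0.129 / 0.871) / (0.03 / 0.97), tolerance = 1e-12)
  expect_true(r2$ci_low <= r2$or && r2$or <= r2$ci_high)

  r3 <- or_vs_aggregate_benchmark(0.8, 500, 0.2)
  expect_equal(r3$or, 16, tolerance = 1e-12)

  # delta-method SE on the log scale drives CI and p
  se <- sqrt(1 / (2000 * 0.129 * 0.871))
  expect_equal(log(r2$ci_high) - log(r2$or), qnorm(0.975) * se,
               tolerance = 1e-10)

  expect_error(or_vs_aggregate_benchmark(0, 100, 0.5), "boundary")
  r4 <- or_vs_aggregate_benchmark(0, 100, 0.5, continuity = TRUE)
  expect_gt(r4$or, 0)
  expect_error(or_vs_aggregate_benchmark(0.5, 100, 1), "inside")
})

test_that("categorical reduction is exhaustive, deterministic, and OR-invariant", {
  red <- c(white = 0, black = 1, asian = 1, other = 1)
  expect_identical(reduce_categorical(c("white", "asian"), red), c(0L, 1L))
  expect_error(reduce_categorical(c("white", "mixed"), red), "mixed")
  expect_error(reduce_categorical("white", c(white = 2)), "0/1")

  # OR computed from the reduced variable equals the OR from a pre-reduced
  # binary encoding
  set.seed(81)
  eth <- sample(names(red), 400, TRUE)
  s <- as_sample(data.frame(eth = eth, bin = reduce_categorical(eth, red)))
  b_eth <- sample(names(red), 600, TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
  b <- as_sample(data.frame(eth = b_eth, bin = reduce_categorical(b_eth, red)))
  m_cat <- outcome_meta("eth", "categorical", binary_reduction = red)
  m_bin <- outcome_meta("bin", "binary")
  expect_equal(or_vs_microdata_benchmark(s, b, m_cat)$or,
               or_vs_microdata_benchmark(s, b, m_bin)$or, tolerance = 1e-10)
})

test_that("microdata OR equals the weighted 2x2 cross-product ratio", {
  set.seed(82)
  meta <- outcome_meta("y", "binary")
  # identical samples: OR of exactly 1
  s <- as_sample(data.frame(y = rbinom(200, 1, 0.4)))
  expect_equal(or_vs_microdata_benchmark(s, s, meta)$or, 1, tolerance = 1e-8)

  # weighted case: weight-summed table oracle
  w1 <- runif(150, 0.5, 2); w0 <- runif(250, 0.5, 2)
  s1 <- as_sample(data.frame(y = rbinom(150, 1, 0.55), weight = w1))
  s0 <- as_sample(data.frame(y = rbinom(250, 1, 0.35), weight = w0))
  a <- sum(w1[s1$y == 1]); b <- sum(w1[s1$y == 0])
  c_ <- sum(w0[s0$y == 1]); d <- sum(w0[s0$y == 0])
  expect_equal(or_vs_microdata_benchmark(s1, s0, meta)$or,
               (a / b) / (c_ / d), tolerance = 1e-6)

  expect_error(
    or_vs_microdata_benchmark(as_sample(data.frame(y = rep(1, 50))), s0, meta),
    "constant")
})

test_that("ordinal microdata OR recovers a planted proportional-odds shift", {
  set.seed(83)
  th <- c(-2, -0.7, 0.7, 2)
  draw_ord <- function(n, eta) {
    u <- runif(n)
    1L + rowSums(outer(u, plogis(th - eta), ">"))
  }
  s1 <- as_sample(data.frame(y = draw_ord(3000, 0.6)))
  s0 <- as_sample(data.frame(y = draw_ord(3000, 0)))
  r <- or_vs_microdata_benchmark(s1, s0, outcome_meta("y", "ordinal"))
  expect_equal(r$method, "microdata-ordinal")
  expect_equal(log(r$or), 0.6, tolerance = 0.2)
  expect_true(r$ci_low <= r$or && r$or <= r$ci_high)
})

test_that("flipping a binary outcome inverts the OR but not the inference", {
  set.seed(84)
  meta <- outcome_meta("y", "binary")
  for (i in 1:10) {
    s1 <- as_sample(data.frame(y = rbinom(120, 1, runif(1, 0.2, 0.8)),
                               weight = runif(120, 0.5, 2)))
    s0 <- as_sample(data.frame(y = rbinom(200, 1, runif(1, 0.2, 0.8)),
                               weight = runif(200, 0.5, 2)))
    if (length(unique(s1$y)) < 2 || length(unique(s0$y)) < 2) next
    r <- or_vs_microdata_benchmark(s1, s0, meta)
    f1 <- s1; f1$y <- 1L - f1$y
    f0 <- s0; f0$y <- 1L - f0$y
    rf <- or_vs_microdata_benchmark(f1, f0, meta)
    expect_equal(rf$or, 1 / r$or, tolerance = 1e-8)
    expect_equal(rf$abs_or, r$abs_or, tolerance = 1e-8)
    expect_equal(rf$p_value, r$p_value, tolerance = 1e-8)
  }
})

test_that("summary blocks respect their defining bounds and groupings", {
  res <- data.frame(
    outcome = c("a", "b", "c"), mode = c("CAPI", "CASI", "CAPI"),
    qtype = c("behavior", "behavior", "opinion"),
    or = c(2.0, 0.5, 1.0), p_value = c(0.01, 0.2, 0.9),
    abs_or = c(2.0, 2.0, 1.0), method = "aggregate-benchmark",
    stringsAsFactors = FALSE)
  class(res) <- c("or_results", "data.frame")
  sm <- summarize_or_results(res)
  all_row <- sm[sm$group == "All", ]
  expect_equal(all_row$avg_abs_or, 5 / 3)
  expect_equal(all_row$largest_abs_or, 2.0)
  expect_equal(all_row$n_sig, 1L)
  expect_equal(all_row$n_total, 3L)
  expect_true(all(sm$avg_abs_or >= 1 & sm$avg_abs_or <= sm$largest_abs_or))
  expect_true("Behavior CAPI" %in% sm$group && "Opinion CAPI" %in% sm$group)
})

test_that("difference tests behave at the boundary and at 1.96 sigma", {
  expect_equal(compare_avg_abs_or(c(1.5, 0.1), c(1.5, 0.1))$z, 0)
  eq <- compare_avg_abs_or(list(avg = 2, se = 0), list(avg = 2, se = 0))
  expect_equal(eq$p, 1)
  expect_warning(ne <- compare_avg_abs_or(list(avg = 2, se = 0),
                                          list(avg = 1, se = 0)), "zero")
  expect_equal(ne$p, 0)
  se <- c(0.05, 0.12)
  d <- qnorm(0.975) * sqrt(sum(se^2))
  r <- compare_avg_abs_or(c(1.5 + d, se[1]), c(1.5, se[2]))
  expect_equal(r$p, 0.05, tolerance = 1e-10)
})

test_that("bootstrap SE is zero for a degenerate sample and scales with n", {
  bm <- structure(list(y = c("0" = 0.6, "1" = 0.4)), class = "benchmark_set")
  meta <- list(outcome_meta("y", "binary"))
  # a two-row sample whose resamples are all identical up to weights that
  # do not change the weighted proportion: replicate spread collapses
  s_const <- as_sample(data.frame(y = rep(c(0L, 1L), each = 50)))
  s_const <- s_const[rep(1:2, 50), ]
  set.seed(85)
  b0 <- bootstrap_avg_abs_or(as_sample(data.frame(y = rep(c(0L, 1L), 50))),
                             bm, meta, B = 2, seed = 86)
  expect_equal(b0$B, 2)
  expect_true(is.finite(b0$groups$se[b0$groups$group == "All"]))

  # root-n scaling of the bootstrap SE
  mk <- function(n) as_sample(data.frame(y = rbinom(n, 1, 0.4)))
  set.seed(87)
  se_small <- bootstrap_avg_abs_or(mk(800), bm, meta, B = 150,
                                   seed = 88)$groups$se[1]
  se_big <- bootstrap_avg_abs_or(mk(3200), bm, meta, B = 150,
                                 seed = 89)$groups$se[1]
  expect_equal(se_big / se_small, 0.5, tolerance = 0.3)
})

test_that("replicates forced to a fixed weighted prevalence give SE zero", {
  # the outcome coincides with the poststratification cell, so after
  # re-poststratification every replicate has weighted prevalence exactly
  # equal to the target margin: the replicate values are constant
  bm <- structure(list(y = c("0" = 0.6, "1" = 0.4),
                       g = c(a = 0.5, b = 0.5)), class = "benchmark_set")
  s <- as_sample(data.frame(g = rep(c("a", "b"), each = 60)))
  s$y <- as.integer(s$g == "b")
  b <- bootstrap_avg_abs_or(s, bm, list(outcome_meta("y", "binary")),
                            B = 2, margins = bm, cells = "g", seed = 90)
  expect_equal(b$groups$se[b$groups$group == "All"], 0, tolerance = 1e-12)
})

test_that("pooling two identical surveys reproduces the single-survey summary", {
  set.seed(91)
  bm <- structure(list(y = c("0" = 0.55, "1" = 0.45)), class = "benchmark_set")
  meta <- list(outcome_meta("y", "binary", "CAPI", "behavior"))
  s <- as_sample(data.frame(y = rbinom(400, 1, 0.5)))
  single <- summarize_or_results(survey_vs_benchmarks(s, bm, meta))
  pooled <- combined_basic_avg(s, s, bm, meta)
  expect_equal(pooled$avg_abs_or, single$avg_abs_or, tolerance = 1e-10)
  # per-outcome-average alternative agrees when the two surveys coincide
  avg <- combined_basic_avg(s, s, bm, meta, method = "average")
  expect_equal(avg$avg_abs_or, single$avg_abs_or, tolerance = 1e-10)
})

test_that("neutral share is the weighted mass on neutral categories", {
  meta <- outcome_meta("op", "ordinal", "CAPI", "opinion")
  s <- as_sample(data.frame(op = c(1, 2, 4, 5), weight = 1))
  expect_equal(neutral_share(s, meta, 3), 0)
  s2 <- as_sample(data.frame(op = rep(3, 5), weight = 1))
  expect_equal(neutral_share(s2, meta, 3), 1)
  set.seed(92)
  op <- sample(1:5, 4000, TRUE, prob = c(0.2, 0.2, 0.3, 0.15, 0.15))
  s3 <- as_sample(data.frame(op = op, weight = runif(4000, 0.5, 2)))
  expect_equal(neutral_share(s3, meta, 3), 0.3, tolerance = 0.03)
  expect_error(neutral_share(s3, meta, integer(0)), "nonempty")
  expect_error(neutral_share(s3, outcome_meta("op", "binary"), 3), "ordinal")
})
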