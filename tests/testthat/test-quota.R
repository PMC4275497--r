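make_bench <- function(...) structure(list(...), class = "benchmark_set")

test_that("quota targets use largest-remainder apportionment", {
  bm <- make_bench(v = c(a = 0.5, b = 0.5),
                   w = c(a = 0.335, b = 0.333, c = 0.332))
  spec <- build_quota_spec(bm, list("v"), 2000)
  expect_equal(spec$target, c(1000L, 1000L))
  spec2 <- build_quota_spec(bm, list("w"), 1000)
  expect_equal(spec2$target, c(335L, 333L, 332L))
  # property: targets sum exactly to the total within every grouping
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- as.vector(prop.table(runif(k)))
    bmk <- make_bench(v = setNames(p, letters[1:k]))
    sp <- build_quota_spec(bmk, list("v"), sample(100:3000, 1))
    expect_equal(sum(sp$target), attr(sp, "total_target"))
  }
})

test_that("a panel matching the quota composition fills without relaxation", {
  cfg <- tiny_config(3000, joining_model = selection_model(intercept = 40))
  pop <- generate_population(cfg, seed = 51)
  panel <- recruit_panel(pop, seed = 52)
  bm <- true_benchmarks(pop, list(c("sex", "x")))
  spec <- build_quota_spec(bm, list(c("sex", "x")), 600)
  res <- run_quota_survey(panel, spec, seed = 53)
  expect_equal(nrow(res$sample), 600)
  expect_equal(nrow(res$log), 0)
  expect_false(any(res$spec$relaxed))
  expect_equal(attr(res$sample, "provenance"), "panel-quota")
})

test_that("an impossible cell is relaxed and the shortfall logged", {
  cfg <- tiny_config(4000, joining_model = selection_model(intercept = 40))
  pop <- generate_population(cfg, seed = 54)
  bm <- true_benchmarks(pop, list("x"))
  panel <- recruit_panel(pop, seed = 55)
  panel$data <- panel$data[panel$data$x == "0", ] # no x=1 members at all
  spec <- build_quota_spec(bm, list("x"), 800)
  res <- run_quota_survey(panel, spec, seed = 56)
  expect_gt(nrow(res$log), 0)
  expect_true(any(res$log$cell == "1"))
  expect_equal(res$spec$achieved[res$spec$cell == "1"], 0L)
  expect_equal(nrow(res$sample), 800) # met by overfilling the open cell
  expect_true(res$spec$relaxed[res$spec$cell == "1"])
})

test_that("caps are respected for unrelaxed cells and counts conserve", {
  cfg <- tiny_config(6000, px = 0.25,
                     joining_model = selection_model(
                       intercept = 0, coef = list(x = c("1" = -1.5))))
  pop <- generate_population(cfg, seed = 57)
  bm <- true_benchmarks(pop, list(c("sex", "x"), "x"))
  panel <- recruit_panel(pop, seed = 58)
  spec <- build_quota_spec(bm, list(c("sex", "x"), "x"), 900)
  for (sd in 1:8) {
    res <- run_quota_survey(panel, spec, seed = sd)
    over <- res$spec$achieved > res$spec$target & !res$spec$relaxed
    expect_false(any(over))
    # every grouping's achieved counts sum to the accepted sample size
    for (g in unique(res$spec$grouping))
      expect_equal(sum(res$spec$achieved[res$spec$grouping == g]),
                   nrow(res$sample))
    expect_lte(nrow(res$sample), nrow(panel$data))
  }
})

test_that("the accepted set is seed-deterministic but composition is stable in expectation", {
  cfg <- tiny_config(4000, joining_model = selection_model(intercept = 1))
  pop <- generate_population(cfg, seed = 59)
  bm <- true_benchmarks(pop, list(c("sex", "x")))
  panel <- recruit_panel(pop, seed = 60)
  spec <- build_quota_spec(bm, list(c("sex", "x")), 400)
  r1 <- run_quota_survey(panel, spec, seed = 99)
  r2 <- run_quota_survey(panel, spec, seed = 99)
  expect_identical(r1$sample$person_id, r2$sample$person_id)
  r3 <- run_quota_survey(panel, spec, seed = 100)
  expect_false(identical(r1$sample$person_id, r3$sample$person_id))
  # mean cell composition over two disjoint seed batches agrees
  comp <- function(seeds) {
    rowMeans(vapply(seeds, function(sd)
      run_quota_survey(panel, spec, seed = sd)$spec$achieved,
      numeric(nrow(spec))))
  }
  expect_equal(comp(1:25), comp(26:50), tolerance = 0.02)
})

test_that("fill rates report one-decimal percentages with NA for empty targets", {
  spec <- structure(
    data.frame(grouping = "g", cell = c("a", "b", "c"),
               target = c(267L, 267L, 0L), achieved = c(211L, 267L, 0L),
               relaxed = FALSE, stringsAsFactors = FALSE),
    total_target = 534L, groupings = list("g"),
    class = c("quota_spec", "data.frame"))
  fr <- fill_rate(spec)
  expect_equal(fr$percent, c(79.0, 100.0, NA_real_))
})

test_that("omnibus pre-screen flags the requested subset", {
  cfg <- tiny_config(12000, joining_model = selection_model(intercept = 40))
  pop <- generate_population(cfg, seed = 61)
  panel <- recruit_panel(pop, seed = 62)
  p1 <- omnibus_prescreen(panel, c("x"), 9176, seed = 63)
  expect_equal(sum(p1$data$.screened), 9176)
  p2 <- omnibus_prescreen(panel, c("x"), 0, seed = 64)
  expect_equal(sum(p2$data$.screened), 0)
  expect_warning(p3 <- omnibus_prescreen(panel, c("x"), 20000, seed = 65),
                 "exceeds panel size")
  expect_equal(sum(p3$data$.screened), nrow(panel$data))
  expect_error(omnibus_prescreen(panel, c("missing_var"), 10), "not in panel")
})
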