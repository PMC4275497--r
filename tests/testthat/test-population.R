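test_that("config validation names the offending field", {
  covs <- list(sex = list(categories = c("m", "f"), probs = c(0.5, 0.5)))
  outs <- list(y = outcome_spec("binary"))
  expect_error(population_config(0, covs, outs), "'n'")
  expect_error(
    population_config(10, list(sex = list(categories = c("m", "f"),
                                          probs = c(0.7, 0.7))), outs),
    "sum to 1")
  expect_error(
    population_config(10, covs, list(y = outcome_spec(
      "binary", coef = list(age = c(a = 1))))),
    "unknown covariate 'age'")
  expect_error(
    population_config(10, covs, outs,
                      joining_model = selection_model(outcome_coef = c(z = 1))),
    "unknown outcome 'z'")
  expect_error(outcome_spec("ordinal", thresholds = c(1, 0.5)),
               "strictly increasing")
})

test_that("binary outcome prevalences match their logistic models", {
  cfg <- tiny_config(100000, outcomes = list(
    null = outcome_spec("binary", intercept = 0),
    rare = outcome_spec("binary", intercept = -3.476),
    covdep = outcome_spec("binary", intercept = -1,
                          coef = list(x = c("1" = 0.8)))))
  pop <- generate_population(cfg, seed = 101)
  # intercept-only: prevalence = expit(intercept), tolerance ~4 MC SE
  expect_equal(mean(pop$data$null), 0.5, tolerance = 0.008)
  p_rare <- plogis(-3.476) # 0.0299...: the rare-behavior anchor
  expect_equal(mean(pop$data$rare), p_rare, tolerance = 4 * sqrt(p_rare / 1e5))
  # covariate-dependent: marginal equals the mixture over covariate cells
  p_mix <- 0.5 * plogis(-1) + 0.5 * plogis(-0.2)
  expect_equal(enumerate_prevalence(cfg, "covdep"), p_mix, tolerance = 1e-12)
  expect_equal(mean(pop$data$covdep), p_mix, tolerance = 0.008)
})

test_that("ordinal generation follows the proportional-odds model", {
  th <- c(-1.5, -0.5, 0.5, 1.5)
  cfg <- tiny_config(80000, outcomes = list(
    op = outcome_spec("ordinal", "CAPI", "opinion", thresholds = th,
                      coef = list(x = c("1" = 1)))))
  pop <- generate_population(cfg, seed = 7)
  for (xv in c("0", "1")) {
    y <- pop$data$op[pop$data$x == xv]
    eta <- if (xv == "1") 1 else 0
    cum_expected <- plogis(th - eta)
    cum_observed <- cumsum(prop.table(table(factor(y, levels = 1:5))))[1:4]
    expect_true(all(diff(cum_expected) > 0)) # coherent cumulative scale
    expect_equal(unname(cum_observed), cum_expected, tolerance = 0.015)
  }
})

test_that("generation is reproducible and digest-stamped", {
  cfg <- tiny_config(500)
  a <- generate_population(cfg, seed = 3)
  b <- generate_population(cfg, seed = 3)
  expect_identical(a$data, b$data)
  expect_identical(a$digest, b$digest)
  c <- generate_population(cfg, seed = 4)
  expect_false(identical(a$data, c$data))
})

test_that("planted logistic coefficients are recovered at large n", {
  cfg <- tiny_config(100000, outcomes = list(
    y = outcome_spec("binary", intercept = -0.5,
                     coef = list(x = c("1" = 0.6)))))
  pop <- generate_population(cfg, seed = 11)
  fit <- glm(y ~ x, family = binomial(), data = pop$data)
  est <- coef(fit)[["x1"]]
  se <- sqrt(diag(vcov(fit)))[["x1"]]
  expect_lt(abs(est - 0.6), 3 * se)
})

test_that("true benchmarks are exact tabulations that sum to one", {
  cfg <- tiny_config(4000)
  pop <- generate_population(cfg, seed = 5)
  bm <- true_benchmarks(pop, list("x", c("sex", "x")))
  for (key in names(bm)) expect_equal(sum(bm[[key]]), 1, tolerance = 1e-12)
  expect_equal(unname(bm$x["1"]), mean(pop$data$x == "1"), tolerance = 1e-15)
  expect_equal(names(bm[["sex:x"]]),
               sort(unique(paste(pop$data$sex, pop$data$x, sep = "|"))))
  expect_error(true_benchmarks(pop, "nope"), "unknown variable")
})

test_that("probability sampling follows the response propensities", {
  # constant propensity: a simple random subsample
  cfg <- tiny_config(30000, px = 0.3)
  pop <- generate_population(cfg, seed = 21)
  s <- draw_probability_sample(pop, 5000, seed = 22)
  expect_equal(attr(s, "provenance"), "probability")
  expect_true(all(s$weight == 1))
  expect_equal(mean(s$x == "1"), mean(pop$data$x == "1"), tolerance = 0.06)
  expect_error(draw_probability_sample(pop, 30001), "exceeds")

  # identity case: target the whole population under constant propensity
  small <- generate_population(tiny_config(300), seed = 1)
  all_s <- draw_probability_sample(small, 300, seed = 2)
  expect_equal(nrow(all_s), 300)

  # covariate-dependent propensity shifts the realized distribution the
  # expected amount (closed-form expected cell share)
  cfg2 <- tiny_config(40000, px = 0.5,
                      response_model = selection_model(
                        intercept = 0, coef = list(x = c("1" = 1))))
  pop2 <- generate_population(cfg2, seed = 23)
  s2 <- draw_probability_sample(pop2, 6000, seed = 24)
  n1 <- sum(pop2$data$x == "1"); n0 <- sum(pop2$data$x == "0")
  expected_share <- n1 * plogis(1) / (n1 * plogis(1) + n0 * plogis(0))
  expect_equal(mean(s2$x == "1"), expected_share, tolerance = 0.04)
})

test_that("panel recruitment reproduces the joining model", {
  # p_join == 1: panel equals the population
  cfg <- tiny_config(2000, joining_model = selection_model(intercept = 40))
  pop <- generate_population(cfg, seed = 31)
  expect_equal(nrow(recruit_panel(pop, seed = 32)$data), 2000)

  # membership odds ratio equals exp(joining coefficient)
  cfg2 <- tiny_config(150000, joining_model = selection_model(
    intercept = -1, coef = list(x = c("1" = 0.8))))
  pop2 <- generate_population(cfg2, seed = 33)
  panel <- recruit_panel(pop2, seed = 34)
  joined <- pop2$data$person_id %in% panel$data$person_id
  tab <- table(joined, pop2$data$x)
  or <- (tab["TRUE", "1"] * tab["FALSE", "0"]) /
    (tab["TRUE", "0"] * tab["FALSE", "1"])
  expect_equal(log(or), 0.8, tolerance = 0.06)

  # joining on a CASI outcome plants non-ignorable bias
  cfg3 <- tiny_config(100000, outcomes = list(
    y = outcome_spec("binary", "CASI", "behavior", intercept = -2)),
    joining_model = selection_model(intercept = -1,
                                    outcome_coef = c(y = 1)))
  pop3 <- generate_population(cfg3, seed = 35)
  panel3 <- recruit_panel(pop3, seed = 36)
  expect_gt(mean(panel3$data$y), mean(pop3$data$y))
  expect_error(recruit_panel(generate_population(tiny_config(50), seed = 1)),
               "joining_model")
})
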