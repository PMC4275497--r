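## Odds-ratio comparison of a survey against benchmarks, the absolute-OR
## summary battery, and bootstrap inference for differences in average
## absolute ORs.
##
## Two benchmark routes:
##  * aggregate: the benchmark proportion is an external constant (census /
##    large official survey analog); only the survey side contributes
##    variance, via the delta method on the logit with the Kish effective
##    sample size.
##  * microdata: the benchmark is itself a (weighted) sample; both samples
##    are stacked with a membership indicator and the OR is the indicator's
##    coefficient from weighted binary logistic or proportional-odds
##    regression, with a robust (sandwich) variance.

#' Describe an outcome for benchmark comparison
#'
#' @param name Column name of the outcome.
#' @param scale `"binary"`, `"ordinal"` or `"categorical"`.
#' @param mode `"CAPI"` or `"CASI"` grouping tag.
#' @param qtype `"behavior"` or `"opinion"` grouping tag.
#' @param binary_reduction For categorical outcomes (required) or as an
#'   override elsewhere: named vector mapping every category to 0 or 1.
#' @param cut For ordinal outcomes: values strictly above `cut` code 1 in
#'   the fallback binary reduction.
#' @return An `outcome_meta` object.
#' @export
outcome_meta <- function(name, scale = c("binary", "ordinal", "categorical"),
                         mode = c("CAPI", "CASI"),
                         qtype = c("behavior", "opinion"),
                         binary_reduction = NULL, cut = 3) {
  scale <- match.arg(scale)
  if (scale == "categorical" && is.null(binary_reduction))
    stop("outcome_meta: categorical outcomes must declare a binary_reduction")
  structure(list(name = name, scale = scale, mode = match.arg(mode),
                 qtype = match.arg(qtype),
                 binary_reduction = binary_reduction, cut = cut),
            class = "outcome_meta")
}

#' Collapse a categorical outcome to binary
#'
#' @param values Vector of categories.
#' @param reduction Named vector/list mapping every category to 0 or 1.
#' @return Integer 0/1 vector.
#' @export
reduce_categorical <- function(values, reduction) {
  reduction <- unlist(reduction)
  if (!all(reduction %in% 0:1))
    stop("reduce_categorical: reduction must map to 0/1")
  out <- reduction[as.character(values)]
  if (anyNA(out))
    stop(sprintf("reduce_categorical: category '%s' not covered by the reduction",
                 as.character(values)[which(is.na(out))[1]]))
  as.integer(unname(out))
}

#' Absolute odds ratio
#'
#' Direction-free distance of an odds ratio from 1: ORs below 1 are
#' inverted, so e.g. 0.5 is treated as 2.0.
#'
#' @param or_value Positive odds ratio(s).
#' @return `max(OR, 1/OR)`, elementwise.
#' @export
abs_or <- function(or_value) {
  if (any(!is.finite(or_value)) || any(or_value <= 0))
    stop("abs_or: odds ratios must be positive and finite")
  pmax(or_value, 1 / or_value)
}

or_result_row <- function(name, mode, qtype, or, se_log, method,
                          conf_level = 0.95) {
  z <- log(or) / se_log
  q <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(outcome = name, mode = mode, qtype = qtype,
             or = or,
             ci_low = exp(log(or) - q * se_log),
             ci_high = exp(log(or) + q * se_log),
             p_value = 2 * pnorm(-abs(z)),
             abs_or = abs_or(or),
             method = method, stringsAsFactors = FALSE)
}

#' Odds ratio of a weighted survey proportion against a fixed benchmark
#'
#' The benchmark proportion is treated as a known constant; the variance of
#' the log odds ratio comes from the survey side only, by the delta method
#' with the effective sample size: `var(log OR) = 1 / (n_eff p (1-p))`.
#'
#' @param weighted_prop Survey weighted proportion (strictly inside (0,1)
#'   unless `continuity = TRUE`).
#' @param n_eff Effective sample size (see [kish_neff()]).
#' @param bench_prop Benchmark proportion in (0,1).
#' @param meta Optional [outcome_meta()] for labeling.
#' @param conf_level Confidence level for the Wald interval.
#' @param continuity If `TRUE`, a boundary survey proportion is handled by
#'   adding 0.5 to each implied cell of the survey's 2x1 table.
#' @return One-row data.frame: or, ci_low, ci_high, p_value, abs_or, method.
#' @export
or_vs_aggregate_benchmark <- function(weighted_prop, n_eff, bench_prop,
                                      meta = NULL, conf_level = 0.95,
                                      continuity = FALSE) {
  if (any(bench_prop <= 0 | bench_prop >= 1))
    stop("or_vs_aggregate_benchmark: benchmark proportion must be inside (0,1)")
  p <- weighted_prop
  boundary <- p <= 0 | p >= 1
  if (any(boundary)) {
    if (!continuity)
      stop("or_vs_aggregate_benchmark: boundary survey proportion; set continuity = TRUE")
    p[boundary] <- (p[boundary] * n_eff + 0.5) / (n_eff + 1)
  }
  or <- (p / (1 - p)) / (bench_prop / (1 - bench_prop))
  se <- sqrt(1 / (n_eff * p * (1 - p)))
  or_result_row(if (is.null(meta)) NA_character_ else meta$name,
                if (is.null(meta)) NA_character_ else meta$mode,
                if (is.null(meta)) NA_character_ else meta$qtype,
                or, se, "aggregate-benchmark", conf_level)
}

## Robust vcov: V %*% crossprod(estfun) %*% V (HC0; optionally clustered).
robust_vcov <- function(fit, cluster = NULL) {
  V <- vcov(fit)
  ef <- sandwich::estfun(fit)
  if (!is.null(cluster)) ef <- rowsum(ef, cluster)
  V %*% crossprod(ef) %*% V
}

outcome_values <- function(df, meta) {
  v <- df[[meta$name]]
  if (is.null(v))
    stop(sprintf("outcome '%s' not found in sample", meta$name))
  if (meta$scale == "categorical") {
    reduce_categorical(v, meta$binary_reduction)
  } else if (meta$scale == "binary" && !is.null(meta$binary_reduction)) {
    reduce_categorical(v, meta$binary_reduction)
  } else v
}

#' Odds ratio of a survey against a microdata benchmark
#'
#' Stacks the survey with the benchmark sample (benchmark as the reference
#' level of a membership indicator) and estimates the indicator's OR by
#' weighted binary logistic regression, or by a weighted proportional-odds
#' cumulative-logit model for 5-point ordinal outcomes (one OR per
#' outcome). Variance is robust (sandwich). If the proportional-odds fit
#' fails, the outcome is reduced to binary at its declared cut with a
#' warning.
#'
#' @param sample The survey under assessment (`weight` column used).
#' @param benchmark_sample The reference sample (e.g. the probability
#'   survey), weighted.
#' @param meta An [outcome_meta()].
#' @param conf_level Confidence level.
#' @return One-row data.frame as in [or_vs_aggregate_benchmark()].
#' @export
or_vs_microdata_benchmark <- function(sample, benchmark_sample, meta,
                                      conf_level = 0.95) {
  y1 <- outcome_values(sample, meta)
  y0 <- outcome_values(benchmark_sample, meta)
  w1 <- if ("weight" %in% names(sample)) sample$weight else rep(1, length(y1))
  w0 <- if ("weight" %in% names(benchmark_sample)) benchmark_sample$weight else
    rep(1, length(y0))
  if (length(unique(y1)) < 2 || length(unique(y0)) < 2)
    stop(sprintf("or_vs_microdata_benchmark: outcome '%s' constant in one sample",
                 meta$name))
  member <- c(rep(0, length(y0)), rep(1, length(y1)))
  y <- c(y0, y1)
  w <- c(w0, w1)
  ordinal <- meta$scale == "ordinal"
  if (ordinal) {
    fit <- tryCatch(
      suppressWarnings(
        MASS::polr(factor(y, ordered = TRUE) ~ member, weights = w,
                   Hess = TRUE)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)[["member"]])) {
      warning(sprintf("proportional-odds fit failed for '%s'; falling back to binary cut at %d",
                      meta$name, meta$cut))
      ordinal <- FALSE
      y <- as.integer(y > meta$cut)
    }
  }
  if (ordinal) {
    b <- coef(fit)[["member"]]
    se <- sqrt(robust_vcov(fit)["member", "member"])
    method <- "microdata-ordinal"
  } else {
    fit <- suppressWarnings(glm(y ~ member, family = quasibinomial(),
                                weights = w))
    b <- coef(fit)[["member"]]
    se <- sqrt(robust_vcov(fit)["member", "member"])
    method <- "microdata-logistic"
  }
  or_result_row(meta$name, meta$mode, meta$qtype, exp(b), se, method,
                conf_level)
}

#' Odds ratios of every outcome in a battery
#'
#' Dispatches each outcome to the aggregate route (benchmark is a
#' `benchmark_set`: category proportions, binary / reduced outcomes with
#' the proportion of category `"1"` as the benchmark prevalence) or the
#' microdata route (benchmark is a sample data.frame).
#'
#' @param sample The survey under assessment.
#' @param benchmark A `benchmark_set` or a benchmark sample.
#' @param outcomes List of [outcome_meta()] objects.
#' @param conf_level Confidence level.
#' @return Data.frame of class `or_results`, one row per outcome.
#' @export
survey_vs_benchmarks <- function(sample, benchmark, outcomes,
                                 conf_level = 0.95) {
  if (inherits(benchmark, "benchmark_set")) {
    # batch path: every aggregate OR is closed-form, so compute the whole
    # battery vectorized (this is the bootstrap hot path)
    w <- if ("weight" %in% names(sample)) sample$weight else
      rep(1, nrow(sample))
    neff <- kish_neff(w)
    sw <- sum(w)
    ps <- bp <- numeric(length(outcomes))
    for (i in seq_along(outcomes)) {
      meta <- outcomes[[i]]
      y <- outcome_values(sample, meta)
      if (meta$scale == "ordinal") y <- as.integer(y > meta$cut)
      props <- benchmark[[meta$name]]
      if (is.null(props))
        stop(sprintf("survey_vs_benchmarks: no benchmark entry for '%s'", meta$name))
      bp[i] <- if (length(props) == 1) unname(props) else {
        if (!"1" %in% names(props))
          stop(sprintf("survey_vs_benchmarks: benchmark for '%s' lacks category '1'",
                       meta$name))
        unname(props[["1"]])
      }
      ps[i] <- sum(w * y) / sw
    }
    out <- or_vs_aggregate_benchmark(ps, neff, bp, conf_level = conf_level)
    out$outcome <- vapply(outcomes, `[[`, "", "name")
    out$mode <- vapply(outcomes, `[[`, "", "mode")
    out$qtype <- vapply(outcomes, `[[`, "", "qtype")
  } else {
    out <- do.call(rbind, lapply(outcomes, function(meta)
      or_vs_microdata_benchmark(sample, benchmark, meta, conf_level)))
  }
  rownames(out) <- NULL
  class(out) <- c("or_results", "data.frame")
  out
}

#' Absolute-OR summary blocks
#'
#' For the full battery ("All") and for every mode x question-type group
#' present: the unweighted mean and maximum of the absolute ORs, and the
#' count of outcomes significantly different from the benchmark at the 5%
#' level (no multiple-testing adjustment, by design).
#'
#' @param results An `or_results` data.frame.
#' @param alpha Significance level for the difference count.
#' @return Data.frame: group, avg_abs_or, largest_abs_or, n_sig, n_total.
#' @export
summarize_or_results <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) > 0)
  groups <- c(list(All = rep(TRUE, nrow(results))),
              {
                tags <- unique(results[c("qtype", "mode")])
                tags <- tags[complete.cases(tags), , drop = FALSE]
                g <- lapply(seq_len(nrow(tags)), function(i)
                  results$qtype == tags$qtype[i] & results$mode == tags$mode[i])
                names(g) <- paste(cap1(tags$qtype), tags$mode)
                g
              })
  rows <- lapply(names(groups), function(nm) {
    sel <- groups[[nm]] & !is.na(results$abs_or)
    if (!any(sel)) {
      warning(sprintf("summarize_or_results: group '%s' is empty; omitted", nm))
      return(NULL)
    }
    data.frame(group = nm,
               avg_abs_or = mean(results$abs_or[sel]),
               largest_abs_or = max(results$abs_or[sel]),
               n_sig = sum(results$p_value[sel] < alpha),
               n_total = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cap1 <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

#' Bootstrap standard error of the average absolute OR
#'
#' Resamples participants with replacement independently within each input
#' survey (sizes preserved), re-poststratifies each resample, recomputes
#' every OR and each group's average absolute OR. The standard error is
#' the standard deviation of the replicate values. An OR that cannot be
#' computed in a replicate is dropped from that replicate's average; a
#' group where more than 10% of replicates lost an OR is flagged
#' unreliable.
#'
#' @param samples A single survey or a list of surveys to pool (each keeps
#'   its own weights; pooled weights rescaled jointly to mean 1).
#' @param benchmark A `benchmark_set` or benchmark sample (held fixed).
#' @param outcomes List of [outcome_meta()] objects.
#' @param B Number of bootstrap replicates (the study default is 100).
#' @param margins,cells If given, every resample is re-poststratified to
#'   these margins before estimation.
#' @param seed Integer RNG seed.
#' @param alpha Significance level used in replicate summaries.
#' @return A `bootstrap_result`: `$B`, `$groups` (group, estimate, se,
#'   prop_degenerate, unreliable), `$replicates` (B x groups matrix),
#'   `$seed`.
#' @export
bootstrap_avg_abs_or <- function(samples, benchmark, outcomes, B = 100,
                                 margins = NULL, cells = NULL, seed = NULL,
                                 alpha = 0.05) {
  stopifnot(B >= 2)
  if (is.data.frame(samples)) samples <- list(samples)
  if (!is.null(seed)) set.seed(seed)
  # restrict to the columns estimation touches: resampling cost is
  # proportional to the number of columns carried through the replicates
  needed <- unique(c(vapply(outcomes, `[[`, "", "name"), "weight", cells))
  samples <- lapply(samples, function(s) {
    keep <- intersect(names(s), needed)
    out <- as.data.frame(s)[keep]
    attr(out, "provenance") <- attr(s, "provenance")
    class(out) <- class(s)
    out
  })

  estimate_groups <- function(smpls) {
    smpls <- lapply(smpls, function(s) {
      if (!is.null(margins)) s <- poststratify(s, margins, cells)
      s
    })
    pooled <- pool_samples(smpls)
    res <- survey_vs_benchmarks_safe(pooled, benchmark, outcomes)
    list(summary = summarize_or_results(res$results, alpha),
         n_failed = res$n_failed)
  }

  point <- estimate_groups(samples)
  group_names <- point$summary$group
  reps <- matrix(NA_real_, B, length(group_names),
                 dimnames = list(NULL, group_names))
  failed <- numeric(B)
  for (b in seq_len(B)) {
    re <- lapply(samples, function(s) {
      s[sample.int(nrow(s), nrow(s), replace = TRUE), , drop = FALSE]
    })
    est <- estimate_groups(re)
    reps[b, est$summary$group] <- est$summary$avg_abs_or
    failed[b] <- est$n_failed
  }
  se <- apply(reps, 2, sd, na.rm = TRUE)
  prop_deg <- mean(failed > 0)
  structure(list(
    B = B,
    groups = data.frame(group = group_names,
                        estimate = point$summary$avg_abs_or,
                        se = unname(se[group_names]),
                        prop_degenerate = prop_deg,
                        unreliable = prop_deg > 0.1,
                        stringsAsFactors = FALSE),
    replicates = reps, seed = seed),
    class = "bootstrap_result")
}

## Pool surveys: concatenate rows, rescale weights jointly to mean 1.
pool_samples <- function(smpls) {
  if (length(smpls) == 1) return(smpls[[1]])
  common <- Reduce(intersect, lapply(smpls, names))
  pooled <- do.call(rbind, lapply(smpls, function(s) as.data.frame(s)[common]))
  pooled$weight <- pooled$weight / mean(pooled$weight)
  new_survey_sample(pooled, "pooled")
}

## survey_vs_benchmarks with per-outcome failure tolerance (degenerate
## bootstrap replicates): failing outcomes dropped, count returned.
survey_vs_benchmarks_safe <- function(sample, benchmark, outcomes) {
  all_ok <- tryCatch(survey_vs_benchmarks(sample, benchmark, outcomes),
                     error = function(e) NULL)
  if (!is.null(all_ok)) return(list(results = all_ok, n_failed = 0L))
  rows <- list(); n_failed <- 0L
  for (meta in outcomes) {
    r <- tryCatch(survey_vs_benchmarks(sample, benchmark, list(meta)),
                  error = function(e) NULL)
    if (is.null(r)) n_failed <- n_failed + 1L else rows[[length(rows) + 1]] <- r
  }
  if (!length(rows)) stop("no outcome could be compared to the benchmark")
  out <- do.call(rbind, rows)
  class(out) <- c("or_results", "data.frame")
  list(results = out, n_failed = n_failed)
}

#' Normal-approximation test for a difference in average absolute ORs
#'
#' `z = (a - b) / sqrt(se_a^2 + se_b^2)` with a two-sided normal p-value;
#' the standard errors come from independent surveys' bootstrap
#' distributions.
#'
#' @param a,b Each a list or numeric vector with elements `avg` (or first
#'   element) and `se` (or second element).
#' @return List with `z`, `p`, and the difference `diff`.
#' @export
compare_avg_abs_or <- function(a, b) {
  get2 <- function(x) {
    if (is.list(x)) c(x$avg %||% x$estimate, x$se) else x[1:2]
  }
  a <- get2(a); b <- get2(b)
  d <- a[1] - b[1]
  s <- sqrt(a[2]^2 + b[2]^2)
  if (s == 0) {
    if (d == 0) return(list(z = 0, p = 1, diff = 0))
    warning("compare_avg_abs_or: zero standard errors with unequal averages")
    return(list(z = sign(d) * Inf, p = 0, diff = d))
  }
  z <- d / s
  list(z = unname(z), p = unname(2 * pnorm(-abs(z))), diff = unname(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average absolute OR of two pooled surveys
#'
#' Pools two surveys into one (each keeping its own weights, jointly
#' rescaled to mean 1), computes every OR against the benchmark on the
#' pooled sample and summarizes. `method = "average"` instead averages the
#' two surveys' per-outcome absolute ORs before summarizing (the
#' alternative reading of "the two basic surveys combined").
#'
#' @param sampleA,sampleB The two surveys.
#' @param benchmark A `benchmark_set` or benchmark sample.
#' @param outcomes List of [outcome_meta()].
#' @param method `"pool"` (primary) or `"average"`.
#' @param alpha Significance level.
#' @return Summary data.frame as from [summarize_or_results()].
#' @export
combined_basic_avg <- function(sampleA, sampleB, benchmark, outcomes,
                               method = c("pool", "average"), alpha = 0.05) {
  method <- match.arg(method)
  shared <- Filter(function(m) {
    ok <- m$name %in% names(sampleA) && m$name %in% names(sampleB)
    if (!ok) message(sprintf("combined_basic_avg: outcome '%s' missing in one survey; excluded",
                             m$name))
    ok
  }, outcomes)
  if (method == "pool") {
    pooled <- pool_samples(list(sampleA, sampleB))
    summarize_or_results(survey_vs_benchmarks(pooled, benchmark, shared), alpha)
  } else {
    ra <- survey_vs_benchmarks(sampleA, benchmark, shared)
    rb <- survey_vs_benchmarks(sampleB, benchmark, shared)
    avg <- ra
    avg$abs_or <- (ra$abs_or + rb$abs_or) / 2
    avg$p_value <- pmin(ra$p_value, rb$p_value) # for counting only
    summarize_or_results(avg, alpha)
  }
}

#' Weighted share of neutral responses
#'
#' The satisficing indicator: the weighted proportion of an opinion item's
#' responses falling in any designated neutral category (e.g. "neither
#' agree nor disagree", the middle of a 5-point scale).
#'
#' @param sample A weighted survey sample.
#' @param meta An [outcome_meta()] for an ordinal or categorical outcome.
#' @param neutral_categories Nonempty set of categories counted as neutral.
#' @return Weighted proportion in \[0, 1\].
#' @export
neutral_share <- function(sample, meta, neutral_categories) {
  if (length(neutral_categories) == 0)
    stop("neutral_share: neutral_categories must be nonempty")
  if (meta$scale == "binary")
    stop("neutral_share: outcome must be ordinal or categorical")
  v <- sample[[meta$name]]
  w <- if ("weight" %in% names(sample)) sample$weight else rep(1, length(v))
  weighted_prop(v %in% neutral_categories, w)
}
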