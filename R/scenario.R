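## End-to-end study replica: generate a population, recruit volunteer
## panels, run four quota surveys (two basic, two with modified quotas
## chosen by the two selection procedures), draw and weight a probability
## sample, and compare all five samples against the known truth.

#' Weighted benchmark distributions from a sample
#'
#' Weighted tabulation of sample variables in `benchmark_set` form; used
#' to set modified-quota targets so their distributions match the
#' reference survey.
#'
#' @param sample A weighted sample.
#' @param variables List of variable names / character vectors to cross.
#' @return A `benchmark_set`.
#' @export
sample_benchmarks <- function(sample, variables) {
  if (is.character(variables)) variables <- as.list(variables)
  w <- if ("weight" %in% names(sample)) sample$weight else rep(1, nrow(sample))
  out <- list()
  for (vs in variables) {
    lab <- cell_labels(sample, vs)
    tot <- tapply(w, lab, sum)
    out[[bench_key(vs)]] <- setNames(as.vector(tot) / sum(w), names(tot))
  }
  structure(out, class = "benchmark_set")
}

#' Default outcome battery
#'
#' A battery shaped like the study questionnaire: binary behavior items
#' split between interviewer-administered (CAPI) and self-completed (CASI)
#' sections, and 5-point opinion items, with covariate-dependent
#' prevalences. One rare CASI behavior (`samesex_partner_5y`, marginal
#' prevalence near 3%) anchors the rare-outcome end of the battery.
#'
#' @param n_behavior_capi,n_behavior_casi,n_opinion_capi,n_opinion_casi
#'   Battery sizes (study shape: 9, 18, 5, 3).
#' @return Named list of [outcome_spec()] objects.
#' @export
default_outcomes <- function(n_behavior_capi = 9, n_behavior_casi = 18,
                             n_opinion_capi = 5, n_opinion_casi = 3) {
  specs <- list()
  intercepts <- c(-1.8, -0.9, -0.3, 0.2, -1.2, -0.6, 0.5, -1.5, 0)
  coef_sets <- list(
    list(drink = c("weekly+" = 0.6)),
    list(educ_age = c("<=16" = -0.5, ">=19" = 0.5)),
    list(att_samesex = c("4" = 0.4, "5" = 0.8)),
    list(under18s = c(yes = -0.4), sex = c(male = 0.2)),
    list(hh_size = c("1" = 0.5), partnership = c(other = 0.4)),
    list(age_group = c("18-24" = 0.6, "35-44" = -0.3))
  )
  add <- function(prefix, n, mode, qtype, scale) {
    for (i in seq_len(n)) {
      nm <- sprintf("%s_%02d", prefix, i)
      cf <- coef_sets[[1 + (i - 1) %% length(coef_sets)]]
      if (scale == "binary") {
        specs[[nm]] <<- outcome_spec("binary", mode, qtype,
          intercept = intercepts[1 + (i - 1) %% length(intercepts)],
          coef = cf)
      } else {
        specs[[nm]] <<- outcome_spec("ordinal", mode, qtype,
          thresholds = c(-2, -0.7, 0.7, 2) + 0.15 * ((i %% 3) - 1),
          coef = cf)
      }
    }
  }
  add("beh_capi", n_behavior_capi, "CAPI", "behavior", "binary")
  if (n_behavior_casi > 0) {
    add("beh_casi", n_behavior_casi - 1, "CASI", "behavior", "binary")
    specs[["samesex_partner_5y"]] <- outcome_spec(
      "binary", "CASI", "behavior", intercept = -3.476,
      coef = list(att_samesex = c("5" = 0.4)))
  }
  add("op_capi", n_opinion_capi, "CAPI", "opinion", "ordinal")
  add("op_casi", n_opinion_casi, "CASI", "opinion", "ordinal")
  specs
}

#' Default population configuration
#'
#' The study conditions: a British-adult-like covariate mix for ages
#' 18-44 (sex; three age bands; partnership status; London vs rest;
#' age finished full-time education; under-18s in household; household
#' size; drinking frequency; a 5-point attitude item), the
#' [default_outcomes()] battery, a mild covariate-dependent response
#' mechanism for the probability survey, and a volunteer-joining mechanism
#' that over-represents the well-educated, frequent drinkers, the
#' tolerant-attitude categories and (non-ignorably) people reporting the
#' rare CASI behavior, while under-representing young adults.
#'
#' @param n Population size.
#' @param outcomes Outcome battery (default [default_outcomes()]).
#' @param join_outcome_coef Non-ignorable joining coefficient on the rare
#'   CASI behavior (log-odds scale).
#' @param latent_sd Shared person-level logit offset SD (within-person
#'   outcome correlation knob; default 0).
#' @param joining_model Optional [selection_model()] replacing the default
#'   biased joining mechanism (e.g. a constant-propensity model for
#'   zero-bias calibration studies).
#' @return A [population_config()].
#' @export
default_population <- function(n = 100000, outcomes = default_outcomes(),
                               join_outcome_coef = 0.8, latent_sd = 0,
                               joining_model = NULL) {
  covariates <- list(
    sex = list(categories = c("male", "female"), probs = c(0.5, 0.5)),
    age_group = list(categories = c("18-24", "25-34", "35-44"),
                     probs = c(0.267, 0.366, 0.367)),
    partnership = list(categories = c("married-cohab", "other"),
                       probs = c(0.45, 0.55)),
    region = list(categories = c("London", "rest"), probs = c(0.135, 0.865)),
    educ_age = list(categories = c("<=16", "17-18", ">=19"),
                    probs = c(0.25, 0.35, 0.40)),
    under18s = list(categories = c("yes", "no"), probs = c(0.35, 0.65)),
    hh_size = list(categories = c("1", "2", "3", "4+"),
                   probs = c(0.15, 0.30, 0.25, 0.30)),
    drink = list(categories = c("<weekly", "weekly+"), probs = c(0.45, 0.55)),
    att_samesex = list(categories = as.character(1:5),
                       probs = c(0.08, 0.12, 0.20, 0.30, 0.30)))
  response_model <- selection_model(
    intercept = 0,
    coef = list(age_group = c("18-24" = -0.3), under18s = c(yes = 0.2)))
  outcome_coef <- numeric(0)
  if ("samesex_partner_5y" %in% names(outcomes) && join_outcome_coef != 0)
    outcome_coef <- c(samesex_partner_5y = join_outcome_coef)
  if (is.null(joining_model)) joining_model <- selection_model(
    intercept = -2,
    coef = list(educ_age = c(">=19" = 0.7, "<=16" = -0.5),
                drink = c("weekly+" = 0.4),
                att_samesex = c("4" = 0.3, "5" = 0.8),
                age_group = c("18-24" = -0.5)),
    outcome_coef = outcome_coef)
  population_config(n, covariates, outcomes, response_model, joining_model,
                    latent_sd = latent_sd)
}

#' Scenario configuration for the end-to-end replica
#'
#' @param population A [population_config()].
#' @param prob_n Probability-sample target size (study: 8969).
#' @param quota_target Completed interviews per quota survey (study: 2000).
#' @param basic_groupings Basic quota groupings (age within sex,
#'   partnership within sex, region).
#' @param m1_candidates Candidate variables for the stepwise modified-quota
#'   selection.
#' @param m2_omnibus_vars Variables collected on the omnibus pre-screen.
#' @param m2_screen_target Omnibus pre-screen size (study: 9176).
#' @param B Bootstrap replicates (study: 100).
#' @param alpha Significance level.
#' @param seed Master seed; per-stage seeds are derived as fixed offsets.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(population = default_population(),
                            prob_n = 8969, quota_target = 2000,
                            basic_groupings = list(c("sex", "age_group"),
                                                   c("sex", "partnership"),
                                                   "region"),
                            m1_candidates = c("educ_age", "under18s", "hh_size"),
                            m2_omnibus_vars = c("drink", "educ_age",
                                                "att_samesex", "hh_size"),
                            m2_screen_target = 9176,
                            B = 100, alpha = 0.05, seed = 1) {
  stopifnot(inherits(population, "population_config"),
            prob_n <= population$n, quota_target >= 1, B >= 2)
  structure(list(population = population, prob_n = prob_n,
                 quota_target = quota_target,
                 basic_groupings = basic_groupings,
                 m1_candidates = m1_candidates,
                 m2_omnibus_vars = m2_omnibus_vars,
                 m2_screen_target = m2_screen_target,
                 B = B, alpha = alpha, seed = seed),
            class = "scenario_config")
}

## Fixed per-stage seed offsets so any stage can be rerun in isolation.
stage_seed <- function(master, stage) {
  offsets <- c(population = 11L, prob = 23L, panelA = 31L, panelB = 37L,
               panelC = 41L, b1 = 53L, b2 = 59L, m1 = 67L, m2 = 71L,
               omnibus = 79L, boot = 83L)
  (as.integer(master) * 101L + offsets[[stage]]) %% 2000000011L
}

#' Run the full study replica
#'
#' Generates the population, draws and rakes the probability sample, runs
#' the two basic and two modified quota surveys (modified quota variables
#' chosen by stepwise membership selection and by the omnibus two-stage
#' screen respectively), poststratifies everything to the census analog,
#' and emits: a participant-characteristics summary against exact
#' population benchmarks (per sex), an outcome summary against the
#' probability-sample microdata (per sex), bootstrap comparisons of the
#' combined basic surveys with each modified survey, and the cross-panel
#' consistency test. Deterministic given the master seed.
#'
#' @param config A [scenario_config()].
#' @param out_dir If non-`NULL`, CSV/JSON outputs are written there.
#' @return The report bundle (list), invisibly if `out_dir` is given.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed
  pc <- config$population
  outcomes_meta <- scenario_outcome_meta(pc)

  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  note("stage population: n=%d, digest pending", pc$n)
  pop <- generate_population(pc, seed = stage_seed(seed, "population"))
  note("population generated, digest %s", pop$digest)

  bench_vars <- c(config$basic_groupings,
                  as.list(setdiff(names(pc$covariates),
                                  unlist(config$basic_groupings))))
  census <- true_benchmarks(pop, bench_vars)

  prob <- draw_probability_sample(pop, config$prob_n,
                                  seed = stage_seed(seed, "prob"))
  prob <- rake(prob, census, list(c("sex", "age_group"), "region"))
  note("probability sample: %d participants (target %d)", nrow(prob),
       config$prob_n)

  panels <- list(A = recruit_panel(pop, stage_seed(seed, "panelA")),
                 B = recruit_panel(pop, stage_seed(seed, "panelB")),
                 C = recruit_panel(pop, stage_seed(seed, "panelC")))
  note("panels recruited: A=%d B=%d C=%d members", nrow(panels$A$data),
       nrow(panels$B$data), nrow(panels$C$data))

  basic_spec <- build_quota_spec(census, config$basic_groupings,
                                 config$quota_target)
  ws_b1 <- run_quota_survey(panels$A, basic_spec, stage_seed(seed, "b1"))
  ws_b2 <- run_quota_survey(panels$B, basic_spec, stage_seed(seed, "b2"))
  note("basic quota surveys: WS-B1 n=%d (%d relaxations), WS-B2 n=%d (%d relaxations)",
       nrow(ws_b1$sample), nrow(ws_b1$log), nrow(ws_b2$sample), nrow(ws_b2$log))

  # WS-M1: stepwise selection on probability sample vs WS-B2
  m1_sel <- stepwise_membership_selection(prob, ws_b2$sample,
                                          config$m1_candidates,
                                          alpha = config$alpha)
  m1_vars <- m1_sel$selected$variable
  note("WS-M1 selection: %s", if (length(m1_vars))
    paste(m1_vars, collapse = ", ") else "(none)")
  m1_margins <- c(census, sample_benchmarks(prob, as.list(m1_vars)))
  class(m1_margins) <- "benchmark_set"
  m1_spec <- build_quota_spec(m1_margins,
                              c(config$basic_groupings, as.list(m1_vars)),
                              config$quota_target)
  ws_m1 <- run_quota_survey(panels$B, m1_spec, stage_seed(seed, "m1"))
  note("WS-M1: n=%d (%d relaxations)", nrow(ws_m1$sample), nrow(ws_m1$log))

  # WS-M2: omnibus pre-screen + stepwise selection on the omnibus subsample
  panelC <- omnibus_prescreen(panels$C, config$m2_omnibus_vars,
                              min(config$m2_screen_target, nrow(panels$C$data)),
                              seed = stage_seed(seed, "omnibus"))
  omnibus_sample <- new_survey_sample(
    panelC$data[panelC$data$.screened,
                setdiff(names(panelC$data), c("p_respond", "p_join", ".screened")),
                drop = FALSE], "panel-omnibus")
  m2_sel <- omnibus_membership_selection(prob, omnibus_sample,
                                         config$m2_omnibus_vars,
                                         alpha = config$alpha)
  m2_vars <- m2_sel$selected$variable
  note("WS-M2 selection: %s", if (length(m2_vars))
    paste(m2_vars, collapse = ", ") else "(none)")
  m2_margins <- c(census, sample_benchmarks(prob, as.list(m2_vars)))
  class(m2_margins) <- "benchmark_set"
  m2_spec <- build_quota_spec(m2_margins,
                              c(config$basic_groupings, as.list(m2_vars)),
                              config$quota_target)
  ws_m2 <- run_quota_survey(panelC, m2_spec, stage_seed(seed, "m2"))
  note("WS-M2: n=%d (%d relaxations)", nrow(ws_m2$sample), nrow(ws_m2$log))

  # poststratify everything to the census analog (age within sex)
  ps <- function(s) poststratify(s, census, c("sex", "age_group"))
  surveys <- list("WS-B1" = ps(ws_b1$sample), "WS-B2" = ps(ws_b2$sample),
                  "WS-M1" = ps(ws_m1$sample), "WS-M2" = ps(ws_m2$sample),
                  "Probability" = prob)

  # participant characteristics vs exact population benchmarks, per sex
  quota_vars <- unique(unlist(c(config$basic_groupings, m1_vars, m2_vars)))
  socio_vars <- setdiff(names(pc$covariates), c(quota_vars, "sex"))
  socio_meta <- lapply(socio_vars, function(v) {
    cats <- pc$covariates[[v]]$categories
    red <- setNames(c(1, rep(0, length(cats) - 1)), cats)
    outcome_meta(v, "categorical", binary_reduction = red)
  })
  table2 <- summarize_by_sex(surveys, pop, census, socio_meta,
                             config$alpha, socio = TRUE)

  # outcomes vs probability-sample microdata, per sex
  table3 <- summarize_by_sex(surveys[names(surveys) != "Probability"],
                             pop, prob, outcomes_meta, config$alpha,
                             socio = FALSE)

  # combined basic vs each modified survey, bootstrap SEs, per sex
  table4 <- compare_modified(surveys, prob, outcomes_meta, config,
                             stage_seed(seed, "boot"))

  # cross-panel consistency of the two basic surveys
  stack <- stack_for_gee(surveys[["WS-B1"]], surveys[["WS-B2"]],
                         outcomes_meta, labels = c("WS-B1", "WS-B2"))
  gee <- gee_consistency_test(stack)
  note("consistency joint Wald: stat=%.2f df=%d p=%.3g", gee$joint$stat,
       gee$joint$df, gee$joint$p)

  bundle <- list(
    digest = pop$digest, seed = seed,
    samples = surveys,
    fill_rates = list("WS-B1" = fill_rate(ws_b1$spec),
                      "WS-B2" = fill_rate(ws_b2$spec),
                      "WS-M1" = fill_rate(ws_m1$spec),
                      "WS-M2" = fill_rate(ws_m2$spec)),
    relaxation = list("WS-B1" = ws_b1$log, "WS-B2" = ws_b2$log,
                      "WS-M1" = ws_m1$log, "WS-M2" = ws_m2$log),
    selection = list(m1 = m1_sel, m2 = m2_sel),
    table2 = table2, table3 = table3, table4 = table4,
    gee = gee, log = log_lines)
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

scenario_outcome_meta <- function(pc) {
  lapply(names(pc$outcomes), function(nm) {
    sp <- pc$outcomes[[nm]]
    outcome_meta(nm, sp$scale, sp$mode, sp$qtype,
                 cut = if (sp$scale == "ordinal") sp$cut else 3)
  })
}

summarize_by_sex <- function(surveys, pop, benchmark, metas, alpha, socio) {
  rows <- list()
  for (sex in c("male", "female")) {
    bm <- if (inherits(benchmark, "benchmark_set")) benchmark else {
      b <- benchmark[benchmark$sex == sex, , drop = FALSE]
      b$weight <- b$weight / mean(b$weight)
      b
    }
    if (socio) {
      sub <- pop$data[pop$data$sex == sex, , drop = FALSE]
      bm <- structure(lapply(metas, function(m) {
        p <- mean(reduce_categorical(sub[[m$name]], m$binary_reduction))
        setNames(c(1 - p, p), c("0", "1"))
      }), names = vapply(metas, `[[`, "", "name"), class = "benchmark_set")
    }
    for (nm in names(surveys)) {
      s <- surveys[[nm]]
      s <- s[s$sex == sex, , drop = FALSE]
      s$weight <- s$weight / mean(s$weight)
      sm <- summarize_or_results(survey_vs_benchmarks(s, bm, metas), alpha)
      sm <- cbind(survey = nm, sex = sex, sm)
      rows[[length(rows) + 1]] <- sm
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

compare_modified <- function(surveys, prob, metas, config, boot_seed) {
  rows <- list()
  for (sex in c("male", "female")) {
    bm <- prob[prob$sex == sex, , drop = FALSE]
    bm$weight <- bm$weight / mean(bm$weight)
    sub <- lapply(surveys, function(s) {
      s <- s[s$sex == sex, , drop = FALSE]
      s$weight <- s$weight / mean(s$weight)
      s
    })
    boot <- list(
      basic = bootstrap_avg_abs_or(list(sub[["WS-B1"]], sub[["WS-B2"]]),
                                   bm, metas, B = config$B,
                                   seed = boot_seed, alpha = config$alpha),
      "WS-M1" = bootstrap_avg_abs_or(sub[["WS-M1"]], bm, metas,
                                     B = config$B, seed = boot_seed + 1,
                                     alpha = config$alpha),
      "WS-M2" = bootstrap_avg_abs_or(sub[["WS-M2"]], bm, metas,
                                     B = config$B, seed = boot_seed + 2,
                                     alpha = config$alpha))
    for (mod in c("WS-M1", "WS-M2")) {
      gb <- boot$basic$groups
      gm <- boot[[mod]]$groups
      for (g in gb$group) {
        if (!g %in% gm$group) next
        a <- gb[gb$group == g, ]
        b <- gm[gm$group == g, ]
        cmp <- compare_avg_abs_or(list(avg = a$estimate, se = a$se),
                                  list(avg = b$estimate, se = b$se))
        rows[[length(rows) + 1]] <- data.frame(
          sex = sex, group = g, modified = mod,
          basic_avg = a$estimate, basic_se = a$se,
          modified_avg = b$estimate, modified_se = b$se,
          z = cmp$z, p = cmp$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$samples))
    write_sample(bundle$samples[[nm]],
                 file.path(out_dir, paste0(gsub("\\W", "_", nm), ".csv")),
                 seed = bundle$seed)
  for (nm in names(bundle$fill_rates))
    write.csv(bundle$fill_rates[[nm]],
              file.path(out_dir, paste0("fill_", gsub("\\W", "_", nm), ".csv")),
              row.names = FALSE)
  write.csv(bundle$table2, file.path(out_dir, "table2_characteristics.csv"),
            row.names = FALSE)
  write.csv(bundle$table3, file.path(out_dir, "table3_outcomes.csv"),
            row.names = FALSE)
  write.csv(bundle$table4, file.path(out_dir, "table4_modified_vs_basic.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(digest = bundle$digest, seed = bundle$seed,
         selection = lapply(bundle$selection, function(s)
           list(selected = s$selected, dropped = s$dropped_for_collinearity)),
         gee = bundle$gee[c("per_question", "common", "joint")],
         log = bundle$log),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}
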