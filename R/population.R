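## Synthetic finite population with known selection mechanisms.
##
## Covariates are defined on an explicit joint cell grid so that marginal
## and conditional quantities have exact enumeration counterparts; outcomes
## are binary-logistic or proportional-odds given the covariates; the
## probability-survey response mechanism and the volunteer-panel joining
## mechanism are logistic in covariates (and, for the panel, optionally in
## outcomes, which plants non-ignorable selection bias).

#' Declare an outcome's generating model
#'
#' @param scale `"binary"` or `"ordinal"`. Ordinal outcomes are generated
#'   from a proportional-odds (cumulative logit) model.
#' @param mode Administration mode tag in the reference survey, `"CAPI"`
#'   (interviewer-administered) or `"CASI"` (self-completed). A label only;
#'   no mode-specific measurement error is generated.
#' @param qtype Question type tag, `"behavior"` or `"opinion"`.
#' @param intercept Logit-scale intercept (binary outcomes).
#' @param thresholds Strictly increasing cutpoints on the logit scale
#'   (ordinal outcomes); `length(thresholds) + 1` categories. The default
#'   5-point scale designates category 3 as the neutral point
#'   ("neither agree nor disagree").
#' @param coef Named list mapping covariate name to a named numeric vector
#'   of per-category logit effects (categories absent from the vector get 0).
#' @param cut For ordinal outcomes, the category above which the default
#'   binary reduction codes 1 (used when a single odds ratio is needed and
#'   the proportional-odds fit is unavailable).
#' @return An `outcome_spec` object.
#' @export
outcome_spec <- function(scale = c("binary", "ordinal"),
                         mode = c("CAPI", "CASI"),
                         qtype = c("behavior", "opinion"),
                         intercept = 0,
                         thresholds = NULL,
                         coef = list(),
                         cut = NULL) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  qtype <- match.arg(qtype)
  if (scale == "ordinal") {
    if (is.null(thresholds)) thresholds <- c(-2, -0.7, 0.7, 2)
    if (any(diff(thresholds) <= 0))
      stop("outcome_spec: 'thresholds' must be strictly increasing")
    if (is.null(cut)) cut <- ceiling((length(thresholds) + 1) / 2)
  }
  stopifnot(is.list(coef))
  structure(list(scale = scale, mode = mode, qtype = qtype,
                 intercept = intercept, thresholds = thresholds,
                 coef = coef, cut = cut),
            class = "outcome_spec")
}

#' Declare a logistic selection mechanism
#'
#' Used both for probability-survey response propensity and for volunteer
#' panel joining propensity. The linear predictor is
#' `intercept + covariate effects + outcome effects`; outcome effects
#' multiply the numeric outcome value (0/1 for binary, 1..K for ordinal),
#' so a nonzero `outcome_coef` plants non-ignorable selection bias.
#'
#' @param intercept Logit intercept.
#' @param coef Named list: covariate name -> named numeric vector of
#'   per-category effects.
#' @param outcome_coef Named numeric vector: outcome name -> slope.
#' @return A `selection_model` object.
#' @export
selection_model <- function(intercept = 0, coef = list(),
                            outcome_coef = numeric(0)) {
  stopifnot(is.list(coef), is.numeric(outcome_coef) || length(outcome_coef) == 0)
  structure(list(intercept = intercept, coef = coef,
                 outcome_coef = outcome_coef),
            class = "selection_model")
}

#' Configure a synthetic population
#'
#' @param n Number of individuals in the finite population.
#' @param covariates Named list; each element is
#'   `list(categories = <character>, probs = <numeric>)`. Covariates are
#'   independent unless `joint` is given.
#' @param outcomes Named list of [outcome_spec()] objects.
#' @param response_model [selection_model()] for probability-survey
#'   response propensity (default: constant).
#' @param joining_model [selection_model()] for volunteer-panel joining
#'   propensity, or `NULL` if no panel is to be recruited.
#' @param joint Optional data.frame giving the joint covariate distribution
#'   explicitly: one column per covariate plus a `prob` column summing to 1.
#'   Overrides independence of the marginals.
#' @param latent_sd Standard deviation of an optional shared person-level
#'   logit offset added to every outcome's linear predictor; induces
#'   within-person correlation across outcomes. Default 0 (outcomes
#'   independent given covariates).
#' @return A `population_config` object.
#' @export
population_config <- function(n, covariates, outcomes,
                              response_model = selection_model(),
                              joining_model = NULL,
                              joint = NULL,
                              latent_sd = 0) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("population_config: 'n' must be a positive integer")
  if (!is.list(covariates) || is.null(names(covariates)) ||
      any(names(covariates) == ""))
    stop("population_config: 'covariates' must be a named list")
  for (v in names(covariates)) {
    cv <- covariates[[v]]
    if (is.null(cv$categories) || length(cv$categories) == 0)
      stop(sprintf("population_config: covariate '%s' has no categories", v))
    if (is.null(joint)) {
      p <- cv$probs
      if (length(p) != length(cv$categories) || any(p < 0) || any(p > 1))
        stop(sprintf("population_config: covariate '%s' probs invalid", v))
      if (abs(sum(p) - 1) > 1e-8)
        stop(sprintf("population_config: covariate '%s' probs must sum to 1", v))
    }
  }
  if (!is.list(outcomes) || is.null(names(outcomes)))
    stop("population_config: 'outcomes' must be a named list")
  for (o in names(outcomes)) {
    if (!inherits(outcomes[[o]], "outcome_spec"))
      stop(sprintf("population_config: outcome '%s' is not an outcome_spec", o))
    bad <- setdiff(names(outcomes[[o]]$coef), names(covariates))
    if (length(bad))
      stop(sprintf("population_config: outcome '%s' references unknown covariate '%s'",
                   o, bad[1]))
  }
  for (nm in c("response_model", "joining_model")) {
    m <- get(nm)
    if (is.null(m)) next
    if (!inherits(m, "selection_model"))
      stop(sprintf("population_config: '%s' must be a selection_model", nm))
    bad <- setdiff(names(m$coef), names(covariates))
    if (length(bad))
      stop(sprintf("population_config: %s references unknown covariate '%s'",
                   nm, bad[1]))
    bad <- setdiff(names(m$outcome_coef), names(outcomes))
    if (length(bad))
      stop(sprintf("population_config: %s references unknown outcome '%s'",
                   nm, bad[1]))
  }
  if (!is.null(joint)) {
    if (!is.data.frame(joint) || !"prob" %in% names(joint))
      stop("population_config: 'joint' must be a data.frame with a 'prob' column")
    if (!setequal(setdiff(names(joint), "prob"), names(covariates)))
      stop("population_config: 'joint' columns must match covariate names")
    if (abs(sum(joint$prob) - 1) > 1e-8 || any(joint$prob < 0))
      stop("population_config: 'joint' probs must be nonnegative and sum to 1")
  }
  structure(list(n = as.integer(n), covariates = covariates,
                 outcomes = outcomes, response_model = response_model,
                 joining_model = joining_model, joint = joint,
                 latent_sd = latent_sd),
            class = "population_config")
}

## Joint covariate-cell grid: one row per cell, prob column.
covariate_grid <- function(config) {
  if (!is.null(config$joint)) {
    g <- config$joint[c(names(config$covariates), "prob")]
    rownames(g) <- NULL
    return(g)
  }
  cats <- lapply(config$covariates, function(cv) cv$categories)
  g <- expand.grid(cats, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- rep(1, nrow(g))
  for (v in names(config$covariates)) {
    pv <- setNames(config$covariates[[v]]$probs,
                   config$covariates[[v]]$categories)
    p <- p * pv[g[[v]]]
  }
  g$prob <- unname(p)
  g
}

## Linear predictor from per-category covariate effects.
lp_from_coef <- function(df, intercept, coef) {
  eta <- rep(intercept, nrow(df))
  for (v in names(coef)) {
    cv <- coef[[v]]
    add <- cv[as.character(df[[v]])]
    add[is.na(add)] <- 0
    eta <- eta + unname(add)
  }
  eta
}

lp_selection <- function(df, model, outcomes) {
  eta <- lp_from_coef(df, model$intercept, model$coef)
  for (o in names(model$outcome_coef))
    eta <- eta + model$outcome_coef[[o]] * as.numeric(df[[o]])
  eta
}

draw_outcome <- function(spec, eta, n) {
  if (spec$scale == "binary") {
    rbinom(n, 1L, plogis(eta))
  } else {
    u <- runif(n)
    y <- rep(1L, n)
    for (th in spec$thresholds) y <- y + (u > plogis(th - eta))
    y
  }
}

## Short stable digest of a config (polynomial rolling hash over its JSON
## serialization; collision resistance adequate for provenance checks).
config_digest <- function(config) {
  s <- jsonlite::toJSON(unclass_rec(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 1000000007
    h2 <- (h2 * 137 + b) %% 998244353
  }
  sprintf("%08x%08x", h1, h2)
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else unclass(x)
}

#' Generate a finite synthetic population
#'
#' Draws `config$n` individuals: covariates from the joint cell grid,
#' each outcome from its link model given the covariates, and response /
#' joining propensities from the declared selection models.
#'
#' @param config A [population_config()].
#' @param seed Integer RNG seed; the same config and seed reproduce the
#'   population exactly.
#' @return A `population` object: `$data` (one row per person), `$config`,
#'   `$digest`.
#' @export
generate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  grid <- covariate_grid(config)
  idx <- sample.int(nrow(grid), n, replace = TRUE, prob = grid$prob)
  df <- grid[idx, setdiff(names(grid), "prob"), drop = FALSE]
  rownames(df) <- NULL
  df <- cbind(person_id = seq_len(n), df)
  latent <- if (config$latent_sd > 0) stats::rnorm(n, 0, config$latent_sd) else 0
  for (o in names(config$outcomes)) {
    spec <- config$outcomes[[o]]
    eta <- lp_from_coef(df, spec$intercept, spec$coef) + latent
    df[[o]] <- draw_outcome(spec, eta, n)
  }
  df$p_respond <- plogis(lp_selection(df, config$response_model, config$outcomes))
  df$p_join <- if (is.null(config$joining_model)) NA_real_ else
    plogis(lp_selection(df, config$joining_model, config$outcomes))
  structure(list(data = df, config = config, digest = config_digest(config)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d persons, %d covariates, %d outcomes, digest %s\n",
              nrow(x$data), length(x$config$covariates),
              length(x$config$outcomes), x$digest))
  invisible(x)
}

new_survey_sample <- function(df, provenance) {
  if (!"weight" %in% names(df)) df$weight <- 1
  attr(df, "provenance") <- provenance
  class(df) <- c("survey_sample", "data.frame")
  df
}

#' Draw a probability sample from a population
#'
#' Independent (Poisson) sampling: each person is included with probability
#' proportional to their response propensity `p_respond`, scaled so the
#' expected sample size is `target_n`. Clustering and stratification of real
#' field designs are not simulated.
#'
#' @param pop A `population`.
#' @param target_n Expected number of participants; must not exceed the
#'   population size.
#' @param seed Integer RNG seed.
#' @return A `survey_sample` (data.frame with `weight = 1` and provenance
#'   `"probability"`).
#' @export
draw_probability_sample <- function(pop, target_n, seed = NULL) {
  stopifnot(inherits(pop, "population"))
  n <- nrow(pop$data)
  if (target_n > n)
    stop("draw_probability_sample: target_n exceeds population size")
  if (!is.null(seed)) set.seed(seed)
  pr <- pop$data$p_respond
  p_incl <- pmin(1, pr * target_n / sum(pr))
  keep <- runif(n) < p_incl
  df <- pop$data[keep, setdiff(names(pop$data), c("p_respond", "p_join")),
                 drop = FALSE]
  rownames(df) <- NULL
  new_survey_sample(df, "probability")
}

#' Recruit a volunteer web panel
#'
#' Each person joins independently with probability `p_join` from the
#' configured joining model. The returned subpopulation is the volunteer
#' panel from which quota surveys recruit.
#'
#' @param pop A `population` whose config declares a joining model.
#' @param seed Integer RNG seed.
#' @return A `population` restricted to panel members.
#' @export
recruit_panel <- function(pop, seed = NULL) {
  stopifnot(inherits(pop, "population"))
  if (is.null(pop$config$joining_model))
    stop("recruit_panel: no joining_model declared in the config")
  if (!is.null(seed)) set.seed(seed)
  keep <- runif(nrow(pop$data)) < pop$data$p_join
  out <- pop
  out$data <- pop$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  attr(out, "panel") <- TRUE
  out
}

bench_key <- function(vars) paste(vars, collapse = ":")

cell_labels <- function(df, vars) {
  if (length(vars) == 1) as.character(df[[vars]])
  else do.call(paste, c(unname(df[vars]), sep = "|"))
}

#' Exact finite-population benchmark distributions
#'
#' Tabulates the full population: the synthetic analog of an external
#' census benchmark. Crossed variables (e.g. age group within sex) are
#' requested as character vectors and keyed `"sex:age_group"` with
#' categories `"male|18-24"` etc.
#'
#' @param pop A `population`.
#' @param variables List of variable names or character vectors of names to
#'   cross; single names may be given as a plain character vector.
#' @return A `benchmark_set`: named list, variable key -> named vector of
#'   proportions summing to 1.
#' @export
true_benchmarks <- function(pop, variables) {
  stopifnot(inherits(pop, "population"))
  if (is.character(variables)) variables <- as.list(variables)
  out <- list()
  for (vs in variables) {
    miss <- setdiff(vs, names(pop$data))
    if (length(miss))
      stop(sprintf("true_benchmarks: unknown variable '%s'", miss[1]))
    tab <- table(cell_labels(pop$data, vs))
    out[[bench_key(vs)]] <- setNames(as.vector(tab) / nrow(pop$data), names(tab))
  }
  structure(out, class = "benchmark_set")
}

#' Exact marginal outcome prevalence by enumeration
#'
#' Integrates a binary outcome's logistic model over the covariate cell
#' grid: the exact super-population prevalence, useful as an analytic
#' benchmark for calibration studies.
#'
#' @param config A [population_config()].
#' @param outcome Outcome name (must be binary).
#' @return The exact marginal prevalence.
#' @export
enumerate_prevalence <- function(config, outcome) {
  spec <- config$outcomes[[outcome]]
  if (is.null(spec)) stop("enumerate_prevalence: unknown outcome")
  if (spec$scale != "binary")
    stop("enumerate_prevalence: only binary outcomes supported")
  if (config$latent_sd > 0)
    stop("enumerate_prevalence: exact enumeration requires latent_sd = 0")
  grid <- covariate_grid(config)
  eta <- lp_from_coef(grid, spec$intercept, spec$coef)
  sum(grid$prob * plogis(eta))
}
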