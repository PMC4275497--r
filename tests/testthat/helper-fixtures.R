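# Small configuration builders shared across tests. All fixtures are
# generated in code; nothing is read from disk.

# Minimal two-covariate config: sex (50/50) and a binary factor x with
# prevalence px; `outcomes` defaults to one null binary outcome.
tiny_config <- function(n, px = 0.5, outcomes = NULL,
                        response_model = selection_model(),
                        joining_model = NULL, latent_sd = 0) {
  if (is.null(outcomes))
    outcomes <- list(y = outcome_spec("binary", "CASI", "behavior"))
  population_config(
    n,
    covariates = list(
      sex = list(categories = c("male", "female"), probs = c(0.5, 0.5)),
      x = list(categories = c("0", "1"), probs = c(1 - px, px))),
    outcomes = outcomes,
    response_model = response_model,
    joining_model = joining_model,
    latent_sd = latent_sd)
}

# A battery of k intercept-only binary outcomes with given prevalences.
null_battery <- function(prev) {
  out <- lapply(prev, function(p)
    outcome_spec("binary", "CASI", "behavior", intercept = qlogis(p)))
  names(out) <- sprintf("y%02d", seq_along(prev))
  out
}

meta_for <- function(config) {
  lapply(names(config$outcomes), function(nm) {
    sp <- config$outcomes[[nm]]
    outcome_meta(nm, sp$scale, sp$mode, sp$qtype,
                 cut = if (sp$scale == "ordinal") sp$cut else 3)
  })
}

# Analytic benchmark set for intercept-only binary outcomes.
analytic_benchmarks <- function(config) {
  out <- lapply(names(config$outcomes), function(nm) {
    p <- enumerate_prevalence(config, nm)
    setNames(c(1 - p, p), c("0", "1"))
  })
  names(out) <- names(config$outcomes)
  structure(out, class = "benchmark_set")
}

# Build a survey_sample directly from a data.frame (unit weights).
as_sample <- function(df, provenance = "test") {
  df$weight <- if ("weight" %in% names(df)) df$weight else 1
  attr(df, "provenance") <- provenance
  class(df) <- c("survey_sample", "data.frame")
  df
}
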