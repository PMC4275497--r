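## Cross-panel consistency: do two panel surveys give the same response
## distributions over a shared question battery?
##
## Responses are stacked in long format (one row per person x question)
## and a marginal logistic model with question fixed effects and survey
## terms is estimated by ordinary ML with an independence working
## correlation; inference uses a sandwich variance clustered on person,
## which keeps the test valid under arbitrary within-person correlation
## across questions. No small-sample cluster adjustment is applied, so
## with singleton clusters the variance reduces exactly to the
## heteroskedasticity-robust (HC0) form.

#' Stack two surveys' responses for the consistency test
#'
#' @param sampleA,sampleB The two surveys.
#' @param outcomes List of [outcome_meta()] shared by both surveys; ordinal
#'   and categorical outcomes are reduced to binary via their declared
#'   reduction / cut.
#' @param labels Length-2 character vector naming the surveys.
#' @return A `stacked_responses` data.frame: person_id, survey, question, y.
#' @export
stack_for_gee <- function(sampleA, sampleB, outcomes,
                          labels = c("A", "B")) {
  shared <- Filter(function(m) m$name %in% names(sampleA) &&
                     m$name %in% names(sampleB), outcomes)
  if (length(shared) == 0)
    stop("stack_for_gee: no shared outcomes between the two surveys")
  one <- function(s, lab) {
    do.call(rbind, lapply(shared, function(meta) {
      y <- outcome_values(s, meta)
      if (meta$scale == "ordinal") y <- as.integer(y > meta$cut)
      data.frame(person_id = paste0(lab, ":", s$person_id),
                 survey = lab, question = meta$name, y = as.integer(y),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one(sampleA, labels[1]), one(sampleB, labels[2]))
  rownames(out) <- NULL
  class(out) <- c("stacked_responses", "data.frame")
  out
}

#' Consistency test between two panel surveys
#'
#' Fits logit-link marginal models to the stacked responses with a
#' sandwich variance clustered on person:
#' \itemize{
#'   \item per-question survey effects (log odds ratios survey B vs A)
#'     from the model with question fixed effects and question-specific
#'     survey terms;
#'   \item a common-effect test from the model with a single survey main
#'     effect;
#'   \item a joint Wald test that all survey terms are zero (the primary
#'     "are the panels consistent" statistic).
#' }
#' Questions constant across both surveys are dropped with a warning.
#'
#' @param stack A `stacked_responses` from [stack_for_gee()].
#' @return List: `per_question` (question, est, se, z, p), `common`
#'   (est, se, z, p), `joint` (stat, df, p), `dropped_questions`.
#' @export
gee_consistency_test <- function(stack) {
  stopifnot(inherits(stack, "stacked_responses"))
  qs <- unique(stack$question)
  if (length(qs) < 2)
    stop("gee_consistency_test: at least 2 questions required")
  if (length(unique(stack$survey)) != 2)
    stop("gee_consistency_test: both surveys must be represented")
  const <- qs[vapply(qs, function(q)
    length(unique(stack$y[stack$question == q])) < 2, logical(1))]
  if (length(const)) {
    warning(sprintf("dropping constant question(s): %s",
                    paste(const, collapse = ", ")))
    stack <- stack[!stack$question %in% const, , drop = FALSE]
    qs <- setdiff(qs, const)
  }
  stack$question <- factor(stack$question, levels = qs)
  stack$survey <- factor(stack$survey)

  # per-question survey effects: question FE + question-specific survey terms
  fit1 <- glm(y ~ question + question:survey, family = binomial(),
              data = stack)
  if (!fit1$converged)
    stop(sprintf("gee_consistency_test: model did not converge (questions: %s)",
                 paste(qs, collapse = ", ")))
  V1 <- robust_vcov(fit1, cluster = stack$person_id)
  cf <- coef(fit1)
  surv_terms <- grep(":survey", names(cf), fixed = TRUE)
  est <- cf[surv_terms]
  se <- sqrt(diag(V1)[surv_terms])
  zq <- est / se
  per_question <- data.frame(
    question = qs,
    est = unname(est), se = unname(se), z = unname(zq),
    p = unname(2 * pnorm(-abs(zq))), stringsAsFactors = FALSE)

  # joint Wald: all survey terms zero
  Vs <- V1[surv_terms, surv_terms, drop = FALSE]
  stat <- drop(t(est) %*% solve(Vs, est))
  joint <- list(stat = unname(stat), df = length(est),
                p = unname(pchisq(stat, length(est), lower.tail = FALSE)))

  # common survey effect
  fit2 <- glm(y ~ question + survey, family = binomial(), data = stack)
  V2 <- robust_vcov(fit2, cluster = stack$person_id)
  i <- grep("^survey", names(coef(fit2)))
  e2 <- coef(fit2)[i]; s2 <- sqrt(V2[i, i])
  common <- list(est = unname(e2), se = unname(s2), z = unname(e2 / s2),
                 p = unname(2 * pnorm(-abs(e2 / s2))))

  list(per_question = per_question, common = common, joint = joint,
       dropped_questions = const)
}
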