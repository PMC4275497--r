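## Variable selection for modified quota schemes.
##
## Two procedures: (1) forward stepwise logistic regression on a stacked
## probability-sample / web-sample dataset with sample membership as the
## outcome, entry by likelihood-ratio p-value below alpha, followed by a
## collinearity pruning rule; (2) a bivariate screen ranking candidate
## variables by how many key outcomes they are associated with, both
## crudely and after adjusting for the basic quota variables.

#' Forward stepwise selection of membership predictors
#'
#' Stacks the probability sample and the web sample with a binary
#' membership indicator and runs forward stepwise logistic regression: at
#' each step the candidate with the smallest likelihood-ratio p-value
#' below `alpha` (given variables already entered) enters; the process
#' stops when none qualifies. Categorical candidates enter as full dummy
#' blocks (the block LRT governs entry). Afterwards, among entered
#' variables any pair with Cramer's V above `collinearity_v` loses its
#' less significant member (larger entry p-value).
#'
#' @param prob_sample,web_sample The two (nonoverlapping) samples.
#' @param candidates Character vector of candidate variable names observed
#'   in both samples.
#' @param alpha Entry significance level (the study process uses 0.05).
#' @param collinearity_v Cramer's V threshold for the pruning rule.
#' @param forced Variables conditioned on from the start (never candidates
#'   for entry or pruning); empty by default, i.e. the stepwise model is
#'   not conditioned on the basic quota variables.
#' @return A `selection_result`: `$selected` (data.frame: variable, entry
#'   p-value, step), `$dropped_for_collinearity` (data.frame: dropped,
#'   retained, cramers_v), `$candidate_pool`.
#' @export
stepwise_membership_selection <- function(prob_sample, web_sample, candidates,
                                          alpha = 0.05,
                                          collinearity_v = 0.5,
                                          forced = character(0)) {
  df <- stack_membership(prob_sample, web_sample,
                         unique(c(candidates, forced)))
  in_model <- character(0)
  entry_p <- numeric(0)
  pool <- candidates
  skipped <- character(0)
  repeat {
    ps <- vapply(setdiff(pool, c(in_model, skipped)), function(v) {
      p <- tryCatch(lrt_add_p(df, c(forced, in_model), v),
                    error = function(e) NA_real_)
      if (is.na(p)) {
        warning(sprintf("candidate '%s' skipped (separation or fit failure)", v))
        skipped <<- c(skipped, v)
      }
      p
    }, 0)
    ps <- ps[!is.na(ps)]
    if (!length(ps) || min(ps) >= alpha) break
    best <- names(ps)[which.min(ps)]
    in_model <- c(in_model, best)
    entry_p <- c(entry_p, min(ps))
  }
  dropped <- data.frame(dropped = character(0), retained = character(0),
                        cramers_v = numeric(0), stringsAsFactors = FALSE)
  if (length(in_model) > 1) {
    keep <- rep(TRUE, length(in_model))
    for (i in seq_along(in_model)) for (j in seq_along(in_model)) {
      if (i >= j || !keep[i] || !keep[j]) next
      v <- cramers_v(df[[in_model[i]]], df[[in_model[j]]])
      if (v > collinearity_v) {
        loser <- if (entry_p[i] > entry_p[j]) i else j
        winner <- if (loser == i) j else i
        keep[loser] <- FALSE
        dropped <- rbind(dropped, data.frame(
          dropped = in_model[loser], retained = in_model[winner],
          cramers_v = v, stringsAsFactors = FALSE))
      }
    }
    entry_p <- entry_p[keep]
    in_model <- in_model[keep]
  }
  structure(list(
    selected = data.frame(variable = in_model, entry_p = entry_p,
                          step = seq_along(in_model), stringsAsFactors = FALSE),
    dropped_for_collinearity = dropped,
    candidate_pool = candidates,
    skipped = skipped, alpha = alpha),
    class = "selection_result")
}

#' Stepwise selection against an omnibus pre-screen sample
#'
#' Identical contract to [stepwise_membership_selection()] with the
#' omnibus subsample of the panel as the second stratum (the two-stage
#' modified-quota design's second stage).
#'
#' @inheritParams stepwise_membership_selection
#' @param omnibus_sample Sample of panel members with the omnibus
#'   variables observed.
#' @export
omnibus_membership_selection <- function(prob_sample, omnibus_sample,
                                         candidates, alpha = 0.05,
                                         collinearity_v = 0.5) {
  stepwise_membership_selection(prob_sample, omnibus_sample, candidates,
                                alpha, collinearity_v)
}

stack_membership <- function(prob_sample, web_sample, candidates) {
  for (v in candidates) {
    if (!v %in% names(prob_sample) || !v %in% names(web_sample))
      stop(sprintf("candidate '%s' not observed in both samples", v))
  }
  a <- as.data.frame(prob_sample)[candidates]
  b <- as.data.frame(web_sample)[candidates]
  df <- rbind(a, b)
  df$.member <- c(rep(0L, nrow(a)), rep(1L, nrow(b)))
  for (v in candidates) if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  df
}

## Block likelihood-ratio p-value for adding `v` to the variables `base`.
lrt_add_p <- function(df, base, v, outcome = ".member") {
  rhs0 <- if (length(base)) paste(base, collapse = " + ") else "1"
  f0 <- as.formula(paste(outcome, "~", rhs0))
  f1 <- as.formula(paste(outcome, "~", paste(c(base, v), collapse = " + ")))
  m0 <- glm(f0, family = binomial(), data = df)
  m1 <- glm(f1, family = binomial(), data = df)
  if (!m1$converged || any(abs(coef(m1)) > 15, na.rm = TRUE))
    stop("separation")
  dev <- m0$deviance - m1$deviance
  dfree <- m0$df.residual - m1$df.residual
  if (dfree <= 0) stop("no degrees of freedom added")
  pchisq(dev, dfree, lower.tail = FALSE)
}

#' Cramer's V association between two categorical variables
#'
#' @param x,y Vectors (coerced to factors).
#' @return V in \[0, 1\].
#' @export
cramers_v <- function(x, y) {
  tab <- table(x, y)
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  n <- sum(tab)
  k <- min(nrow(tab), ncol(tab)) - 1
  if (k == 0) return(0)
  unname(sqrt(chi2 / (n * k)))
}

#' Bivariate association screen for candidate quota variables
#'
#' For each candidate, counts the key outcomes with which it is associated
#' at level `alpha` both crudely (outcome ~ candidate) and after adjusting
#' for the basic quota variables (outcome ~ candidate + adjusters), using
#' block likelihood-ratio tests from binary logistic models (ordinal
#' outcomes via proportional-odds models). Candidates are ranked by the
#' count.
#'
#' @param prob_sample The reference survey providing the associations.
#' @param key_outcomes List of [outcome_meta()] (nonempty).
#' @param candidates Character vector of candidate variables.
#' @param adjusters Adjustment variables (the basic quota variables:
#'   age group, partnership status, region by default).
#' @param alpha Significance level.
#' @return Data.frame ranked by `n_significant`: candidate, n_significant,
#'   n_outcomes.
#' @export
bivariate_screen <- function(prob_sample, key_outcomes, candidates,
                             adjusters = c("age_group", "partnership", "region"),
                             alpha = 0.05) {
  if (length(key_outcomes) == 0)
    stop("bivariate_screen: key_outcomes must be nonempty")
  df <- as.data.frame(prob_sample)
  for (v in c(candidates, adjusters))
    if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  counts <- vapply(candidates, function(cand) {
    sum(vapply(key_outcomes, function(meta) {
      p_crude <- outcome_assoc_p(df, meta, cand, character(0))
      if (is.na(p_crude) || p_crude >= alpha) return(FALSE)
      p_adj <- outcome_assoc_p(df, meta, cand, adjusters)
      !is.na(p_adj) && p_adj < alpha
    }, logical(1)))
  }, 0L)
  out <- data.frame(candidate = candidates, n_significant = counts,
                    n_outcomes = length(key_outcomes),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_significant), ]
  rownames(out) <- NULL
  out
}

## LRT p-value for the candidate block in outcome ~ candidate (+ adjusters).
outcome_assoc_p <- function(df, meta, cand, adjusters) {
  y <- outcome_values(df, meta)
  d <- df[c(cand, adjusters)]
  tryCatch({
    if (meta$scale == "ordinal") {
      d$.y <- factor(y, ordered = TRUE)
      rhs0 <- if (length(adjusters)) paste(adjusters, collapse = " + ") else "1"
      m0 <- MASS::polr(as.formula(paste(".y ~", rhs0)), data = d, Hess = FALSE)
      m1 <- MASS::polr(as.formula(paste(".y ~", paste(c(adjusters, cand), collapse = " + "))),
                       data = d, Hess = FALSE)
      dev <- m0$deviance - m1$deviance
      dfree <- m1$edf - m0$edf
      pchisq(dev, dfree, lower.tail = FALSE)
    } else {
      d$.y <- y
      lrt_add_p(d, adjusters, cand, outcome = ".y")
    }
  }, error = function(e) NA_real_)
}
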