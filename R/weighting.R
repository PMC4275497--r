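## Poststratification and raking.
##
## Poststratification to the full cross of the declared variables gives
## exact agreement with the target margins; raking (iterative proportional
## fitting) is available when two margins (e.g. age-sex cells and region)
## must hold simultaneously without a joint benchmark.

#' Poststratify a sample to external margins
#'
#' Each person's weight is multiplied by target proportion / (current
#' weighted sample proportion) of their poststratification cell, then
#' rescaled to mean 1. Cells are the full cross of `cells`; an empty cell
#' with a nonzero target is a hard error (no automatic collapsing).
#'
#' @param sample A `survey_sample` (existing `weight` column respected,
#'   default 1).
#' @param margins A `benchmark_set` holding the target distribution for the
#'   crossed cells (entry `"sex:age_group"` for `cells = c("sex","age_group")`).
#' @param cells Character vector of variables whose cross defines the
#'   poststratification cells.
#' @return The sample with updated weights (mean exactly 1) and attribute
#'   `margin_spec`.
#' @export
poststratify <- function(sample, margins, cells) {
  stopifnot(is.data.frame(sample), inherits(margins, "benchmark_set"))
  key <- bench_key(cells)
  target <- margins[[key]]
  if (is.null(target))
    stop(sprintf("poststratify: margins have no entry '%s'", key))
  w <- if ("weight" %in% names(sample)) sample$weight else rep(1, nrow(sample))
  lab <- cell_labels(sample, cells)
  bad <- setdiff(unique(lab), names(target))
  if (length(bad))
    stop(sprintf("poststratify: sample cell '%s' missing from margins", bad[1]))
  cur <- vapply(names(target), function(cl) sum(w[lab == cl]), 0) / sum(w)
  empty <- names(target)[cur == 0 & target > 0]
  if (length(empty))
    stop(sprintf("poststratify: cell '%s' is empty in the sample but has nonzero target",
                 empty[1]))
  fac <- ifelse(cur > 0, target / cur, 0)
  w <- w * fac[lab]
  sample$weight <- unname(w / mean(w))
  attr(sample, "margin_spec") <- list(cells = cells, targets = target)
  sample
}

#' Rake a sample to several margins
#'
#' Iterative proportional fitting over the listed groupings (each a
#' variable or cross present in `margins`), cycling until the maximum
#' relative weight change in a full cycle is below `tol`.
#'
#' @param sample A `survey_sample`.
#' @param margins A `benchmark_set` with an entry per grouping.
#' @param groupings List of variable names / character vectors to cross.
#' @param max_iter,tol Convergence controls.
#' @return The sample with raked weights (mean 1) and attribute `margin_spec`.
#' @export
rake <- function(sample, margins, groupings, max_iter = 200, tol = 1e-10) {
  stopifnot(is.data.frame(sample), inherits(margins, "benchmark_set"))
  if (is.character(groupings)) groupings <- as.list(groupings)
  for (it in seq_len(max_iter)) {
    w_before <- if ("weight" %in% names(sample)) sample$weight else rep(1, nrow(sample))
    for (vs in groupings) sample <- poststratify(sample, margins, vs)
    rel <- max(abs(sample$weight - w_before) / pmax(w_before, .Machine$double.eps))
    if (rel < tol) break
  }
  if (rel >= tol)
    warning("rake: did not converge to tolerance within max_iter cycles")
  attr(sample, "margin_spec") <- list(groupings = groupings)
  sample
}

#' Kish effective sample size
#'
#' `(sum w)^2 / sum(w^2)`: the conventional approximation to the effective
#' number of observations behind a weighted proportion.
#'
#' @param w Positive weights.
#' @return Effective sample size.
#' @export
kish_neff <- function(w) {
  stopifnot(all(w > 0))
  sum(w)^2 / sum(w^2)
}

#' Weighted proportion
#'
#' @param x 0/1 (or logical) vector.
#' @param w Weights (default uniform).
#' @return Weighted mean of `x`.
#' @export
weighted_prop <- function(x, w = rep(1, length(x))) {
  sum(w * as.numeric(x)) / sum(w)
}
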