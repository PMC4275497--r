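## Quota-controlled recruitment from a volunteer panel.
##
## A quota spec holds cells for one or more groupings (a grouping is a
## single variable or a cross such as age group within sex). Panel members
## are streamed in seeded random order and accepted iff every cell they
## fall into is still open; when the stream exhausts before the total
## target is met, quota caps are relaxed one cell at a time (largest
## absolute shortfall first) and streaming restarts over the remaining
## members — a deterministic, auditable stand-in for the re-invitation
## waves agencies use when quotas prove hard to fill.

#' Build a quota specification from benchmark margins
#'
#' Cell targets are `total_target` times the benchmark proportion, rounded
#' by the largest-remainder method so targets sum exactly to
#' `total_target` within every grouping.
#'
#' @param benchmarks A `benchmark_set` containing an entry for every
#'   grouping (crossed groupings under their `"a:b"` key).
#' @param groupings List of variable names / character vectors to cross,
#'   e.g. `list(c("sex","age_group"), c("sex","partnership"), "region")`.
#' @param total_target Intended number of completed interviews.
#' @return A `quota_spec`: data.frame of cells (grouping, cell, target,
#'   achieved, relaxed) with attribute `total_target`.
#' @export
build_quota_spec <- function(benchmarks, groupings, total_target) {
  stopifnot(inherits(benchmarks, "benchmark_set"),
            is.numeric(total_target), total_target >= 1)
  if (is.character(groupings)) groupings <- as.list(groupings)
  cells <- list()
  for (vs in groupings) {
    key <- bench_key(vs)
    props <- benchmarks[[key]]
    if (is.null(props))
      stop(sprintf("build_quota_spec: no benchmark entry for grouping '%s'", key))
    tg <- largest_remainder(props, total_target)
    if (any(tg == 0 & props == 0))
      warning(sprintf("build_quota_spec: zero-probability categories in '%s' get target 0", key))
    cells[[key]] <- data.frame(grouping = key, cell = names(props),
                               target = tg, achieved = 0L, relaxed = FALSE,
                               stringsAsFactors = FALSE)
  }
  spec <- do.call(rbind, unname(cells))
  rownames(spec) <- NULL
  attr(spec, "total_target") <- as.integer(total_target)
  attr(spec, "groupings") <- groupings
  class(spec) <- c("quota_spec", "data.frame")
  spec
}

## Largest-remainder (Hamilton) apportionment of `total` over proportions.
largest_remainder <- function(props, total) {
  raw <- props * total
  base <- floor(raw)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Pre-screen a panel through an omnibus survey
#'
#' Marks a seeded random subset of at most `screen_target` panel members as
#' having the extra quota variables already observed (collected on a
#' regular multipurpose web survey); the rest are only observed at survey
#' entry. Purely a bookkeeping flag: the synthetic panel carries all
#' variables, the flag records when they became visible to the sampler.
#'
#' @param panel A `population` (the volunteer panel).
#' @param extra_vars Variables collected on the omnibus; must exist.
#' @param screen_target Number of members to pre-screen. If it exceeds the
#'   panel size the whole panel is flagged with a warning.
#' @param seed Integer RNG seed.
#' @return The panel with a logical `.screened` column in `$data`.
#' @export
omnibus_prescreen <- function(panel, extra_vars, screen_target, seed = NULL) {
  stopifnot(inherits(panel, "population"))
  miss <- setdiff(extra_vars, names(panel$data))
  if (length(miss))
    stop(sprintf("omnibus_prescreen: variable '%s' not in panel", miss[1]))
  n <- nrow(panel$data)
  if (!is.null(seed)) set.seed(seed)
  if (screen_target > n) {
    warning("omnibus_prescreen: screen_target exceeds panel size; whole panel flagged")
    screen_target <- n
  }
  flagged <- sample.int(n, screen_target)
  panel$data$.screened <- FALSE
  panel$data$.screened[flagged] <- TRUE
  attr(panel, "omnibus_vars") <- extra_vars
  panel
}

#' Run a quota survey on a volunteer panel
#'
#' Streams panel members in seeded uniform random order; a member is
#' accepted iff every quota cell they fall into is open (achieved < target,
#' or cap relaxed). Recruitment stops at the total target; if the stream
#' exhausts first, the cap of the unfilled cell with the largest absolute
#' shortfall is released and streaming restarts over the remaining members
#' (fresh seeded shuffle), repeating until the target is met or the panel
#' is exhausted, in which case a partial sample is returned and the
#' shortfall logged.
#'
#' @param panel A `population` (the volunteer panel).
#' @param spec A `quota_spec`.
#' @param seed Integer RNG seed for the stream order.
#' @param questionnaire Optional character vector of outcome names to keep
#'   in the sample (all columns kept if `NULL`).
#' @return A list: `sample` (a `survey_sample`, provenance
#'   `"panel-quota"`), `spec` (with achieved counts and relaxation flags),
#'   `log` (a `relaxation_log` data.frame; zero rows if nothing relaxed).
#' @export
run_quota_survey <- function(panel, spec, seed = NULL, questionnaire = NULL) {
  stopifnot(inherits(panel, "population"), inherits(spec, "quota_spec"))
  df <- panel$data
  if (nrow(df) == 0) stop("run_quota_survey: panel is empty")
  if (!is.null(seed)) set.seed(seed)
  total_target <- attr(spec, "total_target")
  groupings <- attr(spec, "groupings")
  spec_key <- paste(spec$grouping, spec$cell)

  # n x G matrix of quota-cell row indices for each member
  G <- length(groupings)
  cell_idx <- matrix(NA_integer_, nrow(df), G)
  for (g in seq_len(G)) {
    key <- bench_key(groupings[[g]])
    cell_idx[, g] <- match(paste(key, cell_labels(df, groupings[[g]])), spec_key)
  }
  if (anyNA(cell_idx))
    stop("run_quota_survey: panel contains categories absent from the quota spec")

  target <- spec$target
  achieved <- integer(nrow(spec))
  relaxed <- logical(nrow(spec))
  accepted <- logical(nrow(df))
  n_accepted <- 0L
  log_rows <- list()
  event <- 0L

  repeat {
    stream <- sample(which(!accepted))
    for (i in stream) {
      cells_i <- cell_idx[i, ]
      if (all(relaxed[cells_i] | achieved[cells_i] < target[cells_i])) {
        achieved[cells_i] <- achieved[cells_i] + 1L
        accepted[i] <- TRUE
        n_accepted <- n_accepted + 1L
        if (n_accepted >= total_target) break
      }
    }
    if (n_accepted >= total_target) break
    if (all(accepted) || all(relaxed)) break
    # stream exhausted: relax the unfilled cell with the largest shortfall;
    # if every unfilled cell is already relaxed, the remaining members are
    # blocked by exactly-filled cells in other groupings, so release the
    # unrelaxed cell blocking the most remaining members
    shortfall <- ifelse(relaxed, -Inf, target - achieved)
    if (max(shortfall) > 0) {
      release <- which.max(shortfall)
    } else {
      blocked <- tabulate(cell_idx[!accepted, , drop = FALSE],
                          nbins = nrow(spec))
      blocked[relaxed] <- -1L
      if (max(blocked) <= 0) break
      release <- which.max(blocked)
    }
    relaxed[release] <- TRUE
    event <- event + 1L
    log_rows[[event]] <- data.frame(
      event = event, grouping = spec$grouping[release],
      cell = spec$cell[release],
      shortfall = as.integer(shortfall[release]),
      accepted_so_far = n_accepted, action = "cap released",
      stringsAsFactors = FALSE)
  }

  if (n_accepted < total_target) {
    event <- event + 1L
    log_rows[[event]] <- data.frame(
      event = event, grouping = "(total)", cell = "(total)",
      shortfall = as.integer(total_target - n_accepted),
      accepted_so_far = n_accepted, action = "panel exhausted: partial sample",
      stringsAsFactors = FALSE)
  }

  spec$achieved <- achieved
  spec$relaxed <- relaxed
  out <- df[accepted, , drop = FALSE]
  drop_cols <- intersect(c("p_respond", "p_join", ".screened"), names(out))
  if (!is.null(questionnaire)) {
    keep <- c("person_id", names(panel$config$covariates),
              intersect(questionnaire, names(out)))
    out <- out[, keep, drop = FALSE]
  } else if (length(drop_cols)) {
    out <- out[, setdiff(names(out), drop_cols), drop = FALSE]
  }
  rownames(out) <- NULL
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(event = integer(0), grouping = character(0),
               cell = character(0), shortfall = integer(0),
               accepted_so_far = integer(0), action = character(0))
  class(log) <- c("relaxation_log", "data.frame")
  list(sample = new_survey_sample(out, "panel-quota"), spec = spec, log = log)
}

#' Quota fill-rate report
#'
#' @param spec A `quota_spec` after [run_quota_survey()].
#' @return Data.frame with one row per cell: achieved, target and percent
#'   filled (one decimal; `NA` for cells with target 0).
#' @export
fill_rate <- function(spec) {
  stopifnot(inherits(spec, "quota_spec"))
  pct <- ifelse(spec$target > 0, round(100 * spec$achieved / spec$target, 1),
                NA_real_)
  data.frame(grouping = spec$grouping, cell = spec$cell,
             achieved = spec$achieved, target = spec$target,
             percent = pct, relaxed = spec$relaxed, stringsAsFactors = FALSE)
}
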