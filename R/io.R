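## Plain-text interchange: samples as CSV (with JSON sidecar), benchmark
## sets as JSON or YAML, quota specs as YAML.

#' Write a survey sample (or population) to CSV with a JSON sidecar
#'
#' @param x A `survey_sample` data.frame or a `population`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json` (provenance, digest, seed if recorded).
#' @param seed Optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_sample <- function(x, path, seed = NULL) {
  if (inherits(x, "population")) {
    df <- x$data
    meta <- list(kind = "population", digest = x$digest,
                 n = nrow(df), seed = seed)
  } else {
    df <- as.data.frame(x)
    meta <- list(kind = "survey_sample",
                 provenance = attr(x, "provenance"),
                 n = nrow(df), seed = seed)
  }
  if (anyNA(df)) stop("write_sample: missing values are not permitted")
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a survey sample from CSV
#'
#' @param path CSV path written by [write_sample()] (sidecar optional).
#' @return A `survey_sample`.
#' @export
read_sample <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  prov <- "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$provenance)) prov <- meta$provenance
  }
  new_survey_sample(df, prov)
}

#' Write / read a benchmark set (JSON or YAML by extension)
#'
#' @param benchmarks A `benchmark_set`.
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return `path` invisibly; `read_benchmarks()` returns a `benchmark_set`.
#' @export
write_benchmarks <- function(benchmarks, path) {
  x <- lapply(benchmarks, as.list)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_benchmarks
#' @export
read_benchmarks <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else
    yaml::read_yaml(path)
  out <- lapply(x, function(v) unlist(v))
  for (key in names(out)) {
    s <- sum(out[[key]])
    if (abs(s - 1) > 1e-6)
      warning(sprintf("read_benchmarks: '%s' proportions sum to %.6f", key, s))
  }
  structure(out, class = "benchmark_set")
}

#' Write a quota spec (with fill state) to YAML
#'
#' @param spec A `quota_spec`.
#' @param path YAML path.
#' @export
write_quota_spec <- function(spec, path) {
  yaml::write_yaml(list(
    total_target = attr(spec, "total_target"),
    groupings = lapply(attr(spec, "groupings"), as.list),
    cells = lapply(seq_len(nrow(spec)), function(i) as.list(spec[i, ]))),
    path)
  invisible(path)
}
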