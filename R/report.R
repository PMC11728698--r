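#' Summarize a per-sample evaluation for one tool
#'
#' Collapses a [evaluate_sample_set()] result to per-metric medians
#' across samples, tagged with the tool, scenario and common feature
#' space it describes. Undefined (`NA`) per-sample values are excluded
#' from the medians and counted.
#'
#' @param eval_result A `profiler_eval` from [evaluate_sample_set()], or
#'   its `per_sample` data frame.
#' @param tool,scenario,space Labels for the summary row.
#' @return A `tool_summary`: list with `tool`, `scenario`, `space`,
#'   `medians` (named numeric), `n_missing` (named integer) and
#'   `n_samples`.
#' @export
summarize_tool <- function(eval_result, tool = "tool",
                           scenario = "scenario", space = "space") {
  per_sample <- if (inherits(eval_result, "profiler_eval"))
    eval_result$per_sample else eval_result
  if (!is.data.frame(per_sample) || nrow(per_sample) == 0L)
    stop("empty metric list")
  metric_cols <- setdiff(names(per_sample),
                         c("sample_id", "tp", "fp", "fn"))
  medians <- vapply(per_sample[metric_cols], stats::median, numeric(1L),
                    na.rm = TRUE)
  n_missing <- vapply(per_sample[metric_cols], function(x) sum(is.na(x)),
                      integer(1L))
  structure(list(tool = tool, scenario = scenario, space = space,
                 medians = medians, n_missing = n_missing,
                 n_samples = nrow(per_sample)),
            class = "tool_summary")
}

#' @export
print.tool_summary <- function(x, ...) {
  cat(sprintf("Tool summary: %s (%s, %s), %d samples\n",
              x$tool, x$scenario, x$space, x$n_samples))
  print(round(x$medians, 4), ...)
  invisible(x)
}

#' Transform summary medians to bounded similarities
#'
#' Puts heterogeneous metrics on a common 0-to-1 "higher is better"
#' scale for radar-style comparison: richness and Shannon diversity are
#' compared to the truth with the Bray-Curtis-style similarity
#' `1 - |u - v| / (u + v)`; Bray-Curtis and weighted UniFrac distances
#' become `1 - d`; FPRA becomes the true-positive relative abundance
#' `TPRA = 1 - FPRA`; sensitivity and precision, already in \[0, 1\]
#' with higher better, pass through unchanged.
#'
#' @param summary A `tool_summary` from [summarize_tool()].
#' @param richness_truth,shannon_truth Reference medians to compare the
#'   estimated richness and Shannon medians against (must be positive).
#'   Defaults are taken from the summary's own `richness_ref` /
#'   `shannon_ref` medians.
#' @return Named numeric vector of similarities in \[0, 1\] with
#'   elements `richness`, `shannon`, `bray_curtis`, `unifrac`, `tpra`,
#'   `sensitivity`, `precision`.
#' @export
to_similarities <- function(summary, richness_truth = NULL,
                            shannon_truth = NULL) {
  stopifnot(inherits(summary, "tool_summary"))
  m <- summary$medians
  if (is.null(richness_truth)) richness_truth <- m[["richness_ref"]]
  if (is.null(shannon_truth)) shannon_truth <- m[["shannon_ref"]]
  if (!isTRUE(richness_truth > 0) || !isTRUE(shannon_truth > 0))
    stop("truth values must be positive")
  bc_sim <- function(u, v) if (u + v == 0) NA_real_ else 1 - abs(u - v) / (u + v)
  rich_est <- richness_truth + m[["richness_diff"]]
  shan_est <- shannon_truth + m[["shannon_diff"]]
  c(richness = bc_sim(richness_truth, rich_est),
    shannon = bc_sim(shannon_truth, shan_est),
    bray_curtis = 1 - m[["bray_curtis"]],
    unifrac = if (is.na(m[["unifrac"]])) NA_real_ else 1 - m[["unifrac"]],
    tpra = 1 - m[["fpra"]],
    sensitivity = m[["sensitivity"]],
    precision = m[["precision"]])
}

#' Rank tools per metric from their similarity profiles
#'
#' For every similarity axis, tools are ranked best-first (higher
#' similarity is better); ties share a rank. No composite score is
#' computed: the ranking is strictly per metric.
#'
#' @param summaries A list of `tool_summary` objects (at least 2).
#' @param ... Passed to [to_similarities()] (e.g. shared truth medians).
#' @return A `rank_report`: list with `similarities` (tools x metrics
#'   matrix) and `ranks` (integer matrix, 1 = best). Row order follows
#'   alphabetical tool order, so the report is invariant under input
#'   permutation.
#' @export
rank_report <- function(summaries, ...) {
  if (length(summaries) < 2L) stop("need at least 2 tool summaries")
  tools <- vapply(summaries, function(s) s$tool, character(1L))
  if (anyDuplicated(tools)) stop("duplicate tool labels")
  ord <- order(tools)
  summaries <- summaries[ord]
  tools <- tools[ord]
  sims <- t(vapply(summaries, to_similarities, numeric(7L), ...))
  rownames(sims) <- tools
  ranks <- apply(sims, 2L, function(col) {
    r <- rep(NA_integer_, length(col))
    ok <- !is.na(col)
    r[ok] <- rank(-col[ok], ties.method = "min")
    r
  })
  rownames(ranks) <- tools
  structure(list(similarities = sims, ranks = ranks),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat("Per-metric similarities (1 = perfect agreement with truth):\n")
  print(round(x$similarities, 4))
  cat("\nPer-metric ranks (1 = best):\n")
  print(x$ranks)
  invisible(x)
}

#' Write a rank report to TSV and JSON
#'
#' @param report A `rank_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the report.
#' @export
write_rank_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "rank_report"))
  if (!is.null(tsv_path)) {
    df <- data.frame(tool = rownames(report$similarities),
                     report$similarities, check.names = FALSE)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(similarities = as.data.frame(report$similarities),
           ranks = as.data.frame(report$ranks)),
      json_path, dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(report)
}
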