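#' Project an abundance table into a common feature space
#'
#' Converts a table from a profiler's native feature space to a common
#' feature space through a weighted [feature_mapping()], applying four
#' rules: (1) native features sharing a common target are summed;
#' (2) a native feature with several weighted targets is split
#' proportionally; (3) unmapped native features (and, under the
#' species-rank filter, features whose target is not resolved at species
#' rank) are omitted, their abundance accruing to the per-sample loss
#' account; (4) the converted columns are renormalized to sum 1.
#' A sample that loses all its abundance is left all-zero and flagged
#' rather than renormalized.
#'
#' Mass is conserved: for every sample, the pre-normalization projected
#' column sum plus the lost abundance equals the input column sum
#' (within 1e-9).
#'
#' @param table An [abundance_table()] (features x samples).
#' @param mapping A [feature_mapping()] from the table's native space to
#'   the common space.
#' @param species_only Logical; drop common-space targets whose rank
#'   label is present and differs from `"species"`. Features without a
#'   rank label pass through.
#' @param common_ranks Optional named character vector of rank labels for
#'   common-space features; defaults to the mapping's `common_ranks`
#'   attribute (e.g. from a `rank` column in the mapping TSV).
#' @return A `projection_result`: list with elements
#'   \describe{
#'     \item{projected}{normalized common-space [abundance_table()]}
#'     \item{lost_abundance}{named per-sample abundance mass dropped}
#'     \item{lost_features}{named per-sample count of dropped native
#'       features with nonzero abundance in that sample}
#'     \item{dropped_feature_ids}{native ids with no (surviving)
#'       correspondence}
#'     \item{projected_mass}{pre-normalization projected column sums}
#'     \item{all_zero_samples}{ids of samples that lost everything}
#'   }
#' @examples
#' tab <- abundance_table(matrix(c(0.9, 0.1), 2,
#'          dimnames = list(c("A", "D"), "s1")), normalized = TRUE)
#' project(tab, feature_mapping("A", "X", 1))  # D unmapped: lost 0.1
#' @export
project <- function(table, mapping, species_only = FALSE,
                    common_ranks = NULL) {
  stopifnot(is.matrix(table), is.numeric(table))
  if (!inherits(mapping, "feature_mapping"))
    stop("`mapping` must be a feature_mapping")
  feats <- rownames(table)
  samples <- colnames(table)
  if (is.null(common_ranks)) common_ranks <- attr(mapping, "common_ranks")

  m <- mapping[mapping$native_id %in% feats, , drop = FALSE]
  if (nrow(m) == 0L)
    stop("empty projection: table and mapping feature-id sets are disjoint")
  if (species_only && !is.null(common_ranks)) {
    labelled <- m$common_id %in% names(common_ranks)
    keep <- !labelled | common_ranks[m$common_id] == "species"
    keep[is.na(keep)] <- TRUE
    m <- m[keep, , drop = FALSE]
  }

  # surviving weight per native feature; 0 = fully dropped
  w_kept <- stats::setNames(numeric(length(feats)), feats)
  if (nrow(m) > 0L) {
    s <- tapply(m$weight, m$native_id, sum)
    w_kept[names(s)] <- as.numeric(s)
  }
  dropped <- feats[w_kept == 0]

  commons <- unique(m$common_id)
  if (length(commons) == 0L)
    stop("empty projection: every feature was dropped by the rank filter")
  W <- matrix(0, nrow = length(feats), ncol = length(commons),
              dimnames = list(feats, commons))
  W[cbind(match(m$native_id, feats), match(m$common_id, commons))] <- m$weight

  pre <- crossprod(W, table)            # split then sum
  colnames(pre) <- samples
  lost_ab <- as.numeric(colSums(table * (1 - w_kept)))
  names(lost_ab) <- samples
  lost_ft <- if (length(dropped) > 0L) {
    as.integer(colSums(table[dropped, , drop = FALSE] > 0))
  } else rep(0L, length(samples))
  names(lost_ft) <- samples

  mass <- colSums(pre)
  zero_cols <- mass == 0
  proj <- pre
  if (any(!zero_cols))
    proj[, !zero_cols] <- sweep(pre[, !zero_cols, drop = FALSE], 2L,
                                mass[!zero_cols], "/")
  if (any(zero_cols))
    warning("sample(s) lost all abundance in projection: ",
            paste(samples[zero_cols], collapse = ", "))

  structure(list(
    projected = abundance_table(proj, normalized = !any(zero_cols)),
    lost_abundance = lost_ab,
    lost_features = lost_ft,
    dropped_feature_ids = dropped,
    projected_mass = stats::setNames(as.numeric(mass), samples),
    all_zero_samples = samples[zero_cols]
  ), class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Projection: %d features x %d samples in common space\n",
              nrow(x$projected), ncol(x$projected)))
  cat(sprintf("  median lost abundance: %.4f   median lost features: %d\n",
              stats::median(x$lost_abundance),
              as.integer(stats::median(x$lost_features))))
  cat(sprintf("  dropped native features: %d\n",
              length(x$dropped_feature_ids)))
  if (length(x$all_zero_samples) > 0L)
    cat("  all-zero samples:", paste(x$all_zero_samples, collapse = ", "),
        "\n")
  invisible(x)
}

#' Summarize projection losses across tools
#'
#' Medians across samples of the abundance and feature counts lost in
#' projection, one row per projection result.
#'
#' @param results A list of `projection_result` objects (optionally
#'   named by tool).
#' @return Data frame with columns `tool`, `median_lost_abundance`,
#'   `median_lost_features`. Even-length medians are midpoints of the
#'   two central order statistics.
#' @export
loss_summary <- function(results) {
  if (inherits(results, "projection_result")) results <- list(results)
  if (length(results) == 0L) stop("empty result list")
  tools <- names(results)
  if (is.null(tools)) tools <- paste0("tool", seq_along(results))
  data.frame(
    tool = tools,
    median_lost_abundance = vapply(results, function(r)
      stats::median(r$lost_abundance), numeric(1L)),
    median_lost_features = vapply(results, function(r)
      stats::median(r$lost_features), numeric(1L)),
    row.names = NULL
  )
}
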