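#' Samples where a feature pair is simultaneously FN and FP
#'
#' For a candidate confused pair, only samples where the putative source
#' (`fn_feature`) is a clean false negative (present in the reference,
#' absent from the estimate) and the putative sink (`fp_feature`) a
#' clean false positive (absent from the reference, present in the
#' estimate) are informative: in samples where both features appear on
#' the same side, neither can be attributed to the other.
#'
#' @param ref,est Abundance tables sharing sample ids (features may
#'   differ; absent features count as zero).
#' @param fn_feature,fp_feature Feature ids.
#' @return Character vector of eligible sample ids.
#' @export
eligible_samples <- function(ref, est, fn_feature, fp_feature) {
  samples <- intersect(colnames(ref), colnames(est))
  if (length(samples) == 0L) stop("no shared samples")
  known <- union(rownames(ref), rownames(est))
  for (f in c(fn_feature, fp_feature))
    if (!f %in% known) stop("unknown feature id: ", f)
  g <- function(tab, f) if (f %in% rownames(tab))
    unclass(tab)[f, samples] else stats::setNames(numeric(length(samples)), samples)
  ok <- g(ref, fn_feature) > 0 & g(est, fn_feature) == 0 &
        g(ref, fp_feature) == 0 & g(est, fp_feature) > 0
  samples[ok]
}

#' Candidate confused-feature pairs
#'
#' Enumerates (FN candidate, FP candidate) feature pairs worth testing:
#' pairs for which at least one sample satisfies the eligibility rule of
#' [eligible_samples()]. Incidence is indexed per sample, avoiding the
#' full all-pairs scan over features that never co-occur as FN and FP.
#'
#' @param ref,est Abundance tables sharing sample ids.
#' @return Data frame with columns `fn_feature`, `fp_feature`,
#'   `n_eligible` (count of eligible samples), one row per candidate
#'   pair, in deterministic order.
#' @export
candidate_pairs <- function(ref, est) {
  samples <- intersect(colnames(ref), colnames(est))
  if (length(samples) == 0L) stop("no shared samples")
  feats <- union(rownames(ref), rownames(est))
  R <- matrix(0, length(feats), length(samples),
              dimnames = list(feats, samples))
  E <- R
  R[rownames(ref), ] <- unclass(ref)[, samples]
  E[rownames(est), ] <- unclass(est)[, samples]
  fn_mat <- (R > 0) & (E == 0)   # feature is a clean FN in sample
  fp_mat <- (R == 0) & (E > 0)   # feature is a clean FP in sample
  fn_any <- rowSums(fn_mat) > 0
  fp_any <- rowSums(fp_mat) > 0
  if (!any(fn_any) || !any(fp_any))
    return(data.frame(fn_feature = character(), fp_feature = character(),
                      n_eligible = integer()))
  # co-incidence counts: pairs eligible in >= 1 common sample
  counts <- fn_mat[fn_any, , drop = FALSE] %*%
    t(fp_mat[fp_any, , drop = FALSE])
  idx <- which(counts > 0, arr.ind = TRUE)
  out <- data.frame(fn_feature = rownames(counts)[idx[, 1L]],
                    fp_feature = colnames(counts)[idx[, 2L]],
                    n_eligible = as.integer(counts[idx]),
                    stringsAsFactors = FALSE)
  out <- out[out$fn_feature != out$fp_feature, , drop = FALSE]
  out[order(out$fn_feature, out$fp_feature), , drop = FALSE]
}

#' Detect systematically confused feature pairs
#'
#' A profiler that cannot distinguish two closely related species
#' reports the abundance of the one it misses (the false negative) under
#' the identity of the other (the false positive). Such pairs are found
#' by correlating, across the eligible samples of [eligible_samples()],
#' the reference abundance of the FN feature with the estimated
#' abundance of the FP feature. A pair is reported when it has at least
#' `min_samples` eligible samples and the Pearson correlation strictly
#' exceeds `r_threshold`.
#'
#' @param ref,est Abundance tables sharing sample ids.
#' @param min_samples Minimum number of eligible samples (default 25).
#' @param r_threshold Pearson correlation threshold, strict (default
#'   0.5; use 0.9 for a high-confidence list).
#' @return Data frame with columns `fn_feature`, `fp_feature`,
#'   `n_eligible`, `pearson_r`, sorted by descending correlation. Pairs
#'   whose series have fewer than 3 distinct values (undefined or
#'   degenerate correlation) are skipped.
#' @export
find_confused_pairs <- function(ref, est, min_samples = 25,
                                r_threshold = 0.5) {
  if (min_samples < 3) stop("min_samples must be at least 3")
  cand <- candidate_pairs(ref, est)
  cand <- cand[cand$n_eligible >= min_samples, , drop = FALSE]
  empty <- data.frame(fn_feature = character(), fp_feature = character(),
                      n_eligible = integer(), pearson_r = numeric())
  if (nrow(cand) == 0L) return(empty)
  samples <- intersect(colnames(ref), colnames(est))
  rows <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    fn <- cand$fn_feature[k]; fp <- cand$fp_feature[k]
    elig <- eligible_samples(ref, est, fn, fp)
    x <- unclass(ref)[fn, elig]
    y <- unclass(est)[fp, elig]
    if (length(unique(x)) < 3L || length(unique(y)) < 3L) next
    r <- stats::cor(x, y)
    if (is.na(r) || r <= r_threshold) next
    rows[[k]] <- data.frame(fn_feature = fn, fp_feature = fp,
                            n_eligible = length(elig), pearson_r = r,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$pearson_r, out$fn_feature, out$fp_feature), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
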