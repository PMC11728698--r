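#' Presence/absence confusion counts for one sample
#'
#' Features with nonzero abundance in both reference and estimate are
#' true positives; nonzero only in the estimate, false positives; nonzero
#' only in the reference, false negatives. "Zero" means exactly 0: the
#' projection step emits exact zeros and no detection threshold is
#' applied.
#'
#' @param ref_col,est_col Numeric abundance vectors over the same feature
#'   index. If both are named, the name sets must agree (the estimate is
#'   realigned to the reference order).
#' @return A list with integer components `tp`, `fp`, `fn`.
#' @examples
#' confusion_counts(c(0.5, 0.5, 0), c(0.4, 0, 0.6))  # tp 1, fp 1, fn 1
#' @export
confusion_counts <- function(ref_col, est_col) {
  est_col <- align_features(ref_col, est_col)
  list(tp = sum(ref_col > 0 & est_col > 0),
       fp = sum(ref_col == 0 & est_col > 0),
       fn = sum(ref_col > 0 & est_col == 0))
}

# realign est to ref's feature order; error on mismatched indices
align_features <- function(ref_col, est_col) {
  if (length(ref_col) != length(est_col))
    stop("abundance vectors differ in length")
  if (!is.null(names(ref_col)) && !is.null(names(est_col))) {
    if (!setequal(names(ref_col), names(est_col)))
      stop("abundance vectors have mismatched feature indices")
    est_col <- est_col[names(ref_col)]
  }
  est_col
}

#' Sensitivity and precision from confusion counts
#'
#' Sensitivity = TP / (TP + FN); precision = TP / (TP + FP). A zero
#' denominator yields `NA` (undefined, excluded from medians downstream),
#' not an error.
#'
#' @param counts A list with components `tp`, `fp`, `fn` (as returned by
#'   [confusion_counts()]).
#' @return Named numeric vector `c(sensitivity =, precision =)`.
#' @export
sensitivity_precision <- function(counts) {
  sens <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_
  prec <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else NA_real_
  c(sensitivity = sens, precision = prec)
}

#' False-positive and false-negative relative abundance
#'
#' FPRA is the summed estimated abundance over false-positive features;
#' FNRA the summed reference abundance over false negatives. The
#' true-positive relative abundance is the complement, TPRA = 1 - FPRA.
#'
#' @param ref_col,est_col Normalized abundance vectors (column sums 1
#'   within 1e-6) over the same feature index.
#' @return Named numeric vector `c(fpra =, fnra =)`.
#' @export
fpra_fnra <- function(ref_col, est_col) {
  est_col <- align_features(ref_col, est_col)
  if (abs(sum(ref_col) - 1) > 1e-6 || abs(sum(est_col) - 1) > 1e-6)
    stop("fpra_fnra requires normalized abundance vectors")
  c(fpra = sum(est_col[ref_col == 0]),
    fnra = sum(ref_col[est_col == 0]))
}

# Shannon entropy in nats of a proportion vector (zeros contribute 0)
shannon_entropy <- function(x) {
  x <- x[x > 0]
  -sum(x * log(x))
}

#' Species richness and Shannon diversity of one sample
#'
#' Richness is the count of features with nonzero abundance; Shannon
#' diversity is the entropy of the abundance vector in natural-log units
#' (nats).
#'
#' @param col Normalized abundance vector.
#' @return Named numeric vector `c(richness =, shannon =)`.
#' @examples
#' richness_shannon(rep(0.25, 4))  # richness 4, shannon log(4)
#' @export
richness_shannon <- function(col) {
  c(richness = sum(col > 0), shannon = shannon_entropy(col))
}

#' Bray-Curtis distance
#'
#' `d_BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i)`: 0 for identical
#' vectors, 1 for disjoint supports.
#'
#' @param u,v Nonnegative abundance vectors over the same feature index.
#' @return The distance, or `NA` if both vectors are all-zero.
#' @export
bray_curtis <- function(u, v) {
  v <- align_features(u, v)
  denom <- sum(u + v)
  if (denom == 0) return(NA_real_)
  sum(abs(u - v)) / denom
}

# postorder edge traversal data reused across samples
unifrac_prep <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length))
    stop("weighted UniFrac needs a tree with branch lengths")
  tree <- validate_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  list(tip_label = tree$tip.label, n_tip = length(tree$tip.label),
       n_node = tree$Nnode, edge = po$edge, edge_len = po$edge.length)
}

# per-edge subtree abundance masses, x named over (a subset of) tips
unifrac_edge_mass <- function(prep, x) {
  mass <- numeric(prep$n_tip + prep$n_node)
  idx <- match(names(x), prep$tip_label)
  mass[idx] <- x
  e <- prep$edge
  for (k in seq_len(nrow(e)))
    mass[e[k, 1L]] <- mass[e[k, 1L]] + mass[e[k, 2L]]
  mass[e[, 2L]]
}

#' Weighted UniFrac distance
#'
#' Phylogeny-aware dissimilarity: for each branch of the tree, the
#' abundance descending from it is totalled for each profile, and the
#' branch-length-weighted differences are normalized by the weighted
#' sums, `d_WUF = sum b_i |u_i - v_i| / sum b_i (u_i + v_i)`. The result
#' lies in \[0, 1\].
#'
#' @param u,v Normalized named abundance vectors; every nonzero feature
#'   should be a leaf of `tree`.
#' @param tree A rooted `phylo` tree with branch lengths whose leaves are
#'   feature ids.
#' @param strict Logical; if `TRUE`, features carrying abundance but
#'   absent from the tree are an error. The default drops them from both
#'   vectors, renormalizes, and warns.
#' @return The distance, or `NA` when both profiles are empty.
#' @export
weighted_unifrac <- function(u, v, tree, strict = FALSE) {
  if (is.null(names(u)) || is.null(names(v)))
    stop("weighted_unifrac needs named abundance vectors")
  v <- align_features(u, v)
  prep <- if (inherits(tree, "unifrac_prep")) tree else
    structure(unifrac_prep(tree), class = "unifrac_prep")
  missing <- setdiff(names(u)[u > 0 | v > 0], prep$tip_label)
  if (length(missing) > 0L) {
    if (strict)
      stop("feature(s) absent from tree: ", paste(missing, collapse = ", "))
    warning(length(missing),
            " feature(s) absent from tree dropped and vectors renormalized")
    keep <- setdiff(names(u), missing)
    u <- u[keep]; v <- v[keep]
    if (sum(u) > 0) u <- u / sum(u)
    if (sum(v) > 0) v <- v / sum(v)
  }
  mu <- unifrac_edge_mass(prep, u)
  mv <- unifrac_edge_mass(prep, v)
  denom <- sum(prep$edge_len * (mu + mv))
  if (denom == 0) return(NA_real_)
  sum(prep$edge_len * abs(mu - mv)) / denom
}

# multiplicative zero replacement preserving unit sum
multiplicative_replacement <- function(x, delta) {
  z <- sum(x == 0)
  if (z == 0L) return(x)
  if (delta * z >= 1)
    stop("replacement exceeds unit mass (delta * #zeros >= 1)")
  out <- x * (1 - z * delta)
  out[x == 0] <- delta
  out
}

# centered log-ratio transform of a strictly positive composition
clr <- function(x) log(x) - mean(log(x))

#' Aitchison distance
#'
#' Euclidean distance between centered-log-ratio (clr) transformed
#' compositions. Zeros are first replaced with a multiplicative strategy:
#' each zero becomes `delta` and the nonzero entries are rescaled by
#' `1 - z * delta` (z = number of zeros), preserving the unit sum.
#' Inputs are closed (renormalized to sum 1) before replacement, so the
#' distance is scale-invariant.
#'
#' @param u,v Abundance vectors over the same feature index.
#' @param delta Zero-replacement value; defaults to `1 / D^2` with `D`
#'   the number of features.
#' @return Nonnegative distance.
#' @export
aitchison <- function(u, v, delta = NULL) {
  v <- align_features(u, v)
  if (sum(u) == 0 || sum(v) == 0)
    stop("aitchison distance undefined for an all-zero profile")
  u <- u / sum(u)
  v <- v / sum(v)
  if (is.null(delta)) delta <- 1 / length(u)^2
  if (delta <= 0) stop("delta must be positive")
  cu <- clr(multiplicative_replacement(u, delta))
  cv <- clr(multiplicative_replacement(v, delta))
  sqrt(sum((cu - cv)^2))
}

#' Evaluate a profiler against a reference, sample by sample
#'
#' Computes the full per-sample metric suite between a reference
#' (ground-truth) table and an estimated table sharing a feature space:
#' richness and Shannon-diversity differences (estimate minus reference),
#' Bray-Curtis, weighted UniFrac and Aitchison distances to the truth,
#' sensitivity, precision, and false-positive / false-negative relative
#' abundance. Features present in only one table are imputed as zero in
#' the other; metrics are computed over the shared samples.
#'
#' @param ref,est Normalized [abundance_table()] objects with a common
#'   sample-id set.
#' @param tree Optional `phylo` tree for weighted UniFrac (skipped with
#'   `NA` results when absent).
#' @param delta Zero-replacement value for the Aitchison distance
#'   (default `1/D^2`, `D` = number of unioned features).
#' @param strict_tree Passed to [weighted_unifrac()] for features absent
#'   from the tree.
#' @return A `profiler_eval` object: list with `per_sample` (data frame,
#'   one row per sample), `medians` (per-metric medians across samples,
#'   `NA` values excluded), and `n_missing` (count of excluded undefined
#'   values per metric).
#' @export
evaluate_sample_set <- function(ref, est, tree = NULL, delta = NULL,
                                strict_tree = FALSE) {
  samples <- intersect(colnames(ref), colnames(est))
  if (length(samples) == 0L) stop("no shared samples between tables")
  feats <- union(rownames(ref), rownames(est))
  R <- matrix(0, length(feats), length(samples),
              dimnames = list(feats, samples))
  E <- R
  R[rownames(ref), ] <- unclass(ref)[, samples]
  E[rownames(est), ] <- unclass(est)[, samples]
  if (is.null(delta)) delta <- 1 / length(feats)^2
  prep <- if (!is.null(tree))
    structure(unifrac_prep(tree), class = "unifrac_prep") else NULL

  rows <- lapply(samples, function(s) {
    u <- R[, s]; v <- E[, s]
    cc <- confusion_counts(u, v)
    sp <- sensitivity_precision(cc)
    ff <- fpra_fnra(u, v)
    rs_u <- richness_shannon(u)
    rs_v <- richness_shannon(v)
    wuf <- if (is.null(prep)) NA_real_ else
      weighted_unifrac(u, v, prep, strict = strict_tree)
    data.frame(
      sample_id = s,
      richness_ref = unname(rs_u["richness"]),
      richness_est = unname(rs_v["richness"]),
      richness_diff = unname(rs_v["richness"] - rs_u["richness"]),
      shannon_ref = unname(rs_u["shannon"]),
      shannon_est = unname(rs_v["shannon"]),
      shannon_diff = unname(rs_v["shannon"] - rs_u["shannon"]),
      tp = cc$tp, fp = cc$fp, fn = cc$fn,
      sensitivity = unname(sp["sensitivity"]),
      precision = unname(sp["precision"]),
      fpra = unname(ff["fpra"]),
      fnra = unname(ff["fnra"]),
      bray_curtis = bray_curtis(u, v),
      unifrac = wuf,
      aitchison = aitchison(u, v, delta = delta),
      stringsAsFactors = FALSE
    )
  })
  per_sample <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_sample),
                         c("sample_id", "tp", "fp", "fn"))
  medians <- vapply(per_sample[metric_cols], stats::median,
                    numeric(1L), na.rm = TRUE)
  n_missing <- vapply(per_sample[metric_cols], function(x)
    sum(is.na(x)), integer(1L))
  structure(list(per_sample = per_sample, medians = medians,
                 n_missing = n_missing, n_samples = length(samples)),
            class = "profiler_eval")
}

#' @export
print.profiler_eval <- function(x, ...) {
  cat(sprintf("Profiler evaluation over %d sample(s)\n", x$n_samples))
  cat("Medians across samples:\n")
  show <- c("richness_diff", "shannon_diff", "bray_curtis", "unifrac",
            "aitchison", "sensitivity", "precision", "fpra", "fnra")
  m <- x$medians[show]
  for (k in show)
    cat(sprintf("  %-14s %s\n", k,
                if (is.na(m[k])) sprintf("NA (undefined in %d samples)",
                                         x$n_missing[k])
                else format(m[k], digits = 5)))
  invisible(x)
}
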