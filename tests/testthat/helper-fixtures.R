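# Fixture builders used across test files. Tests set their own seeds.

# small abundance table from a named list of per-sample named vectors
make_table <- function(..., normalized = TRUE) {
  cols <- list(...)
  feats <- unique(unlist(lapply(cols, names)))
  m <- matrix(0, length(feats), length(cols),
              dimnames = list(feats, names(cols)))
  for (s in names(cols)) m[names(cols[[s]]), s] <- cols[[s]]
  abundance_table(m, normalized = normalized)
}

# random sparse normalized table
rand_table <- function(n_feat, n_samp, p_zero = 0.5,
                       prefix = "sp") {
  m <- matrix(stats::rexp(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_feat)),
                              sprintf("s%03d", seq_len(n_samp))))
  m[matrix(stats::runif(length(m)) < p_zero, n_feat, n_samp)] <- 0
  # keep at least one feature per sample
  empty <- colSums(m) == 0
  m[1, empty] <- 1
  sweep(m, 2, colSums(m), "/")
}

# random mapping over feature ids: mixes 1->1, 1->2 split, and unmapped
rand_mapping <- function(feature_ids, p_unmapped = 0.2, p_split = 0.3) {
  native <- character(0); common <- character(0); weight <- numeric(0)
  for (f in feature_ids) {
    r <- stats::runif(1)
    if (r < p_unmapped) next
    if (r < p_unmapped + p_split) {
      w <- stats::runif(1, 0.1, 0.9)
      tg <- sample(sprintf("c%03d", 1:40), 2)
      native <- c(native, f, f); common <- c(common, tg)
      weight <- c(weight, w, 1 - w)
    } else {
      native <- c(native, f)
      common <- c(common, sample(sprintf("c%03d", 1:40), 1))
      weight <- c(weight, 1)
    }
  }
  if (length(native) == 0)
    return(identity_mapping(feature_ids[1]))
  # drop accidental duplicate (native, common) pairs from splits
  dup <- duplicated(paste(native, common))
  if (any(dup)) {
    keep <- !native %in% native[dup]
    native <- native[keep]; common <- common[keep]; weight <- weight[keep]
    if (length(native) == 0) return(identity_mapping(feature_ids[1]))
  }
  feature_mapping(native, common, weight)
}

rand_tree <- function(n_tips, labels = sprintf("sp%03d", seq_len(n_tips))) {
  ape::rtree(n_tips, rooted = TRUE, tip.label = labels,
             br = function(k) stats::runif(k, 0.01, 1))
}

# random normalized abundance pair over a tree's tips
rand_profile <- function(labels, p_zero = 0.3) {
  x <- stats::rexp(length(labels))
  x[stats::runif(length(x)) < p_zero] <- 0
  if (sum(x) == 0) x[1] <- 1
  stats::setNames(x / sum(x), labels)
}
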