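#' Pairwise distance matrix between all samples of a table
#'
#' Builds the symmetric sample-by-sample distance matrix under one of
#' the evaluation metrics, for comparing community structure between a
#' reference and an estimation (see [jensen_shannon()]).
#'
#' @param table A normalized [abundance_table()].
#' @param metric One of `"bray_curtis"`, `"weighted_unifrac"`,
#'   `"aitchison"`.
#' @param tree A `phylo` tree; required iff `metric` is
#'   `"weighted_unifrac"`.
#' @param delta Zero-replacement value for `"aitchison"` (default
#'   `1/D^2`).
#' @return A `dist_matrix`: symmetric numeric matrix with zero diagonal,
#'   sample ids as dimnames, and a `metric` attribute.
#' @export
pairwise_distances <- function(table,
                               metric = c("bray_curtis",
                                          "weighted_unifrac",
                                          "aitchison"),
                               tree = NULL, delta = NULL) {
  metric <- match.arg(metric)
  n <- ncol(table)
  samples <- colnames(table)
  if (metric == "weighted_unifrac") {
    if (is.null(tree)) stop("weighted_unifrac requires a tree")
    tree <- structure(unifrac_prep(tree), class = "unifrac_prep")
  }
  if (metric == "aitchison" && is.null(delta)) delta <- 1 / nrow(table)^2
  fun <- switch(metric,
    bray_curtis = function(u, v) bray_curtis(u, v),
    weighted_unifrac = function(u, v) weighted_unifrac(u, v, tree),
    aitchison = function(u, v) aitchison(u, v, delta = delta))
  D <- matrix(0, n, n, dimnames = list(samples, samples))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      u <- unclass(table)[, i]
      for (j in seq(i + 1L, n)) {
        d <- fun(u, unclass(table)[, j])
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  structure(D, class = c("dist_matrix", class(D)), metric = metric)
}

# normalized upper-triangle weights of a distance matrix
upper_triangle_weights <- function(m) {
  p <- m[upper.tri(m)]
  if (any(p < 0)) stop("negative distance entries")
  s <- sum(p)
  if (s == 0) stop("all-zero distance matrix")
  p / s
}

#' Jensen-Shannon divergence between two distance matrices (or weight
#' vectors)
#'
#' Quantifies how similarly two pairwise distance matrices organize the
#' same samples: the upper triangles are normalized to unit sum, forming
#' discrete weight vectors p and q, and
#' `JSD(p, q) = (D(p || m) + D(q || m)) / 2` with `m = (p + q)/2` and
#' `D` the Kullback-Leibler divergence in natural log. The result lies
#' in `[0, log(2)]`; lower values mean the estimation preserves the
#' reference community structure better.
#'
#' @param p,q Two `dist_matrix` objects over the same ordered sample set,
#'   or two nonnegative numeric vectors (normalized internally).
#' @param kl_denominator `"mixture"` (the Jensen-Shannon construction,
#'   default) or `"printed"` (a compatibility variant taking the KL
#'   denominator as the other distribution, which yields plain
#'   `KL(p || q)` averaged with `KL(q || p)` and is unbounded).
#' @return The divergence (nats).
#' @examples
#' jensen_shannon(c(1, 0), c(0, 1))  # log(2)
#' @export
jensen_shannon <- function(p, q, kl_denominator = c("mixture", "printed")) {
  kl_denominator <- match.arg(kl_denominator)
  if (is.matrix(p) || is.matrix(q)) {
    if (!is.matrix(p) || !is.matrix(q))
      stop("p and q must both be matrices or both vectors")
    if (nrow(p) != nrow(q) ||
        !identical(rownames(p), rownames(q)))
      stop("distance matrices have mismatched sample sets")
    p <- upper_triangle_weights(p)
    q <- upper_triangle_weights(q)
  } else {
    if (length(p) != length(q)) stop("p and q differ in length")
    if (any(p < 0) || any(q < 0)) stop("negative weights")
    if (sum(p) == 0 || sum(q) == 0) stop("all-zero weight vector")
    p <- p / sum(p)
    q <- q / sum(q)
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  if (kl_denominator == "printed")
    (kl_finite(p, q) + kl_finite(q, p)) / 2
  else
    (kl(p, m) + kl(q, m)) / 2
}

# KL(p || q) with 0*log(0) = 0; infinite when q = 0 where p > 0
kl_finite <- function(p, q) {
  i <- p > 0
  if (any(q[i] == 0)) return(Inf)
  sum(p[i] * log(p[i] / q[i]))
}

#' Rank tools by Jensen-Shannon divergence from the reference
#'
#' @param jsd_by_tool Named numeric vector or list of per-tool JSD
#'   values.
#' @return Data frame ordered by ascending JSD with columns `tool`,
#'   `jsd`, `rank` (ties share a rank) and `best` (flag for the
#'   minimal-JSD tool or tools).
#' @export
rank_tools <- function(jsd_by_tool) {
  x <- unlist(jsd_by_tool)
  if (length(x) == 0L) stop("empty tool map")
  ord <- order(x, names(x))
  out <- data.frame(tool = names(x)[ord], jsd = unname(x[ord]),
                    rank = rank(x, ties.method = "min")[ord],
                    row.names = NULL)
  out$best <- out$rank == 1L
  out
}
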