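#' Construct a feature mapping
#'
#' A feature mapping is a weighted many-to-many correspondence from the
#' native feature space of a profiler to a common feature space. Each
#' native feature's weights sum to 1: projecting splits its abundance
#' across its common-space targets in those proportions. Native features
#' absent from the mapping are unmapped and will be dropped (with loss
#' accounting) during projection.
#'
#' @param native_id,common_id Character vectors of equal length.
#' @param weight Numeric split weights in (0, 1]; per native id they must
#'   sum to 1 within 1e-6.
#' @param common_ranks Optional named character vector of taxonomic rank
#'   labels for common-space features (used by the species-rank filter).
#' @return A `feature_mapping`: a data frame with columns `native_id`,
#'   `common_id`, `weight`.
#' @examples
#' # two native features merging into one common feature
#' feature_mapping(c("A", "B"), c("X", "X"), c(1, 1))
#' # one native feature split equally across two common features
#' feature_mapping(c("C", "C"), c("Y", "Z"), c(0.5, 0.5))
#' @export
feature_mapping <- function(native_id, common_id, weight = NULL,
                            common_ranks = NULL) {
  native_id <- as.character(native_id)
  common_id <- as.character(common_id)
  if (length(native_id) != length(common_id))
    stop("native_id and common_id must have equal length")
  if (is.null(weight)) {
    # equal-split convenience: weight 1/k for a native id's k entries
    k <- table(native_id)
    weight <- 1 / as.numeric(k[native_id])
  }
  weight <- as.numeric(weight)
  if (length(weight) != length(native_id))
    stop("weight must match native_id in length")
  if (any(is.na(weight)) || any(weight <= 0) || any(weight > 1))
    stop("weights must lie in (0, 1]")
  pair <- paste(native_id, common_id, sep = "\r")
  if (anyDuplicated(pair))
    stop("duplicate (native_id, common_id) pair: ",
         gsub("\r", " -> ", pair[duplicated(pair)][1L]))
  sums <- tapply(weight, native_id, sum)
  off <- abs(sums - 1) > 1e-6
  if (any(off))
    stop("weights for native id '", names(sums)[off][1L],
         "' sum to ", format(sums[off][1L]), ", not 1")
  m <- data.frame(native_id = native_id, common_id = common_id,
                  weight = weight, stringsAsFactors = FALSE)
  structure(m, class = c("feature_mapping", "data.frame"),
            common_ranks = common_ranks)
}

#' @export
print.feature_mapping <- function(x, ...) {
  cat(sprintf("Feature mapping: %d native -> %d common features (%d entries)\n",
              length(unique(x$native_id)), length(unique(x$common_id)),
              nrow(x)))
  print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more entries)\n", sep = "")
  invisible(x)
}

#' Read a feature mapping from TSV
#'
#' Canonical dialect: header `native_id<TAB>common_id<TAB>weight`. A
#' weightless two-column dialect is also accepted; it assigns weight
#' `1/k` to each of a native id's `k` rows (equal splitting). An optional
#' `rank` column attaches rank labels to common-space features.
#'
#' @param path Path to the TSV file.
#' @return A [feature_mapping()].
#' @export
read_mapping <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           comment.char = "",
                           colClasses = "character")
  need <- c("native_id", "common_id")
  if (!all(need %in% names(raw)))
    stop("mapping file must have columns native_id and common_id")
  weight <- NULL
  if ("weight" %in% names(raw)) {
    weight <- suppressWarnings(as.numeric(raw$weight))
    if (anyNA(weight)) stop("non-numeric weight in ", path)
  }
  common_ranks <- NULL
  if ("rank" %in% names(raw)) {
    cr <- tapply(raw$rank, raw$common_id, function(r) unique(r))
    if (any(lengths(cr) > 1L))
      stop("conflicting rank labels for common id '",
           names(cr)[lengths(cr) > 1L][1L], "'")
    common_ranks <- vapply(cr, `[[`, character(1L), 1L)
  }
  feature_mapping(raw$native_id, raw$common_id, weight,
                  common_ranks = common_ranks)
}

#' Write a feature mapping to TSV
#'
#' @param mapping A [feature_mapping()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "feature_mapping"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("native_id\tcommon_id\tweight", con)
  writeLines(paste(mapping$native_id, mapping$common_id,
                   sprintf("%.12g", mapping$weight), sep = "\t"),
             con)
  invisible(path)
}

#' Identity mapping over a feature set
#'
#' Convenience constructor: every feature maps to itself with weight 1.
#' Projecting through an identity mapping is the identity transformation.
#'
#' @param feature_ids Character vector of feature ids.
#' @return A [feature_mapping()].
#' @export
identity_mapping <- function(feature_ids) {
  feature_mapping(feature_ids, feature_ids, rep(1, length(feature_ids)))
}
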