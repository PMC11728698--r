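#' Construct an abundance table
#'
#' An abundance table holds relative abundances of taxonomic features
#' (rows) across samples (columns). Values are proportions in \[0, 1\],
#' never percentages. A table flagged as normalized has every column
#' summing to 1 (within 1e-9); all-zero columns are disallowed in
#' normalized tables.
#'
#' @param values Numeric matrix, features in rows and samples in columns,
#'   with row and column names set to the feature and sample identifiers.
#' @param rank_labels Optional character vector of taxonomic rank tags
#'   (e.g. `"species"`), one per feature, named by feature id.
#' @param normalized Logical; assert that every column sums to 1.
#' @return An object of class `abund_table` (a numeric matrix with
#'   attributes `rank_labels` and `normalized`).
#' @examples
#' m <- matrix(c(0.6, 0.4, 0.5, 0.5), nrow = 2,
#'             dimnames = list(c("sp1", "sp2"), c("s1", "s2")))
#' abundance_table(m, normalized = TRUE)
#' @export
abundance_table <- function(values, rank_labels = NULL, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (anyNA(values)) stop("abundance values must not be NA")
  if (any(values < 0)) stop("abundance values must be nonnegative")
  if (!is.null(rank_labels)) {
    if (is.null(names(rank_labels)))
      names(rank_labels) <- rownames(values)
    if (!all(rownames(values) %in% names(rank_labels)))
      stop("`rank_labels` must cover every feature id")
    rank_labels <- rank_labels[rownames(values)]
  }
  if (normalized) {
    cs <- colSums(values)
    if (any(cs == 0))
      stop("normalized table contains an all-zero sample column: ",
           colnames(values)[cs == 0][1L])
    if (any(abs(cs - 1) > 1e-9))
      stop("column sums deviate from 1 beyond 1e-9 (max deviation ",
           format(max(abs(cs - 1))), ")")
  }
  structure(values, class = c("abund_table", class(values)),
            rank_labels = rank_labels, normalized = normalized)
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d features x %d samples%s\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  show <- unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                     drop = FALSE]
  print(show, ...)
  if (nrow(x) > 6L || ncol(x) > 6L)
    cat(sprintf("... (%d more features, %d more samples)\n",
                max(0L, nrow(x) - 6L), max(0L, ncol(x) - 6L)))
  invisible(x)
}

#' @export
summary.abund_table <- function(object, ...) {
  cs <- colSums(object)
  data.frame(sample_id = colnames(object),
             richness = colSums(object > 0),
             shannon = apply(object, 2L, function(x) shannon_entropy(x / max(sum(x), .Machine$double.xmin))),
             total = cs,
             row.names = NULL)
}

# internal: is x an abund_table whose columns sum to 1?
is_normalized <- function(x, tol = 1e-9) {
  all(abs(colSums(x) - 1) <= tol)
}

#' Read an abundance table from TSV
#'
#' Canonical dialect: UTF-8 tab-separated text, `.` decimal separator,
#' first column = feature id, header row = sample ids.
#'
#' @param path Path to the TSV file.
#' @param normalized_expected Logical; verify that each column sums to 1
#'   within 1e-6 and rescale residual drift so sums are exactly 1.
#' @param percent Logical; divide all values by 100 (for tables exported
#'   as percentages). Without this flag, column sums above `1 + 1e-6`
#'   are rejected.
#' @param rank_column Optional name of a column carrying per-feature rank
#'   labels (removed from the numeric matrix and stored as `rank_labels`).
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, normalized_expected = FALSE,
                                 percent = FALSE, rank_column = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("abundance table needs a feature column and at least one sample column")
  feature_ids <- raw[[1L]]
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id in ", path, ": ",
         feature_ids[duplicated(feature_ids)][1L])
  body <- raw[-1L]
  rank_labels <- NULL
  if (!is.null(rank_column)) {
    if (!rank_column %in% names(body))
      stop("rank column '", rank_column, "' not found")
    rank_labels <- stats::setNames(body[[rank_column]], feature_ids)
    body[[rank_column]] <- NULL
  }
  vals <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)))
  )
  if (nrow(body) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(body)))
  bad <- which(is.na(vals) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at feature '%s', sample '%s': '%s'",
                 feature_ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
                 as.matrix(body)[bad[1L, , drop = FALSE]]))
  if (anyNA(vals)) stop("missing value in abundance table ", path)
  rownames(vals) <- feature_ids
  if (any(vals < 0))
    stop("negative abundance value in ", path)
  if (percent) vals <- vals / 100
  cs <- colSums(vals)
  if (any(cs > 1 + 1e-6))
    stop("column sums exceed 1 (max ", format(max(cs)),
         "); use percent = TRUE for percentage tables")
  if (normalized_expected) {
    if (any(abs(cs - 1) > 1e-6))
      stop("column sums deviate from 1 beyond 1e-6 (max deviation ",
           format(max(abs(cs - 1))), ")")
    vals <- sweep(vals, 2L, cs, "/")
  }
  abundance_table(vals, rank_labels = rank_labels,
                  normalized = normalized_expected)
}

#' Write an abundance table to TSV
#'
#' Values are written with 12 significant digits, so a written table
#' re-read with [read_abundance_table()] reproduces the original within
#' 1e-12. Row and column order are preserved; the output is byte-stable.
#'
#' @param table An [abundance_table()] (or bare named numeric matrix).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(table, path) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("`table` must be a numeric matrix")
  if (is.null(colnames(table)) || ncol(table) == 0L)
    stop("refusing to write a table without sample columns")
  if (is.null(rownames(table)))
    stop("refusing to write a table without feature ids")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(table)), collapse = "\t"), con)
  cells <- matrix(sprintf("%.12g", table), nrow = nrow(table))
  writeLines(paste(rownames(table),
                   apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"),
             con)
  invisible(path)
}
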