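#' Read a phylogenetic tree from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the evaluation pipeline
#' needs: leaf labels must be unique (they are matched against feature
#' ids) and every edge must carry a nonnegative branch length. Edges with
#' missing branch lengths default to 0 with a warning. The outermost
#' Newick node is taken as the root; basal polytomies (star trees) are
#' accepted.
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick file ",
                                            path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("cannot parse Newick file ", path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected a single tree in ", path)
    tree <- tree[[1L]]
  }
  validate_tree(tree)
}

# shared validation for trees read from file or built in memory
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length in tree")
  tree
}

#' Write a phylogenetic tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
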