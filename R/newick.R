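# Newick I/O and internal-node numbering.
#
# Trees are ape "phylo" objects throughout.  Internal nodes carry integer
# labels in tree$node.label following the PAML convention: tips are numbered
# 1..N in input order and internal nodes N+1, N+2, ... starting at the root
# and descending depth-first, so that in an N-tip analysis the root is node
# N+1 (the convention behind node labels like "128" in a 127-sequence study).

#' Assign internal node labels
#'
#' Numbers internal nodes `N+1, N+2, ...` from the root, depth-first
#' (PAML's convention).  The labelling is a pure function of topology and
#' tip order.
#'
#' @param tree An ape `phylo` object.
#' @param overwrite Replace existing `node.label`s (default `TRUE`).
#' @return The tree with `node.label` set to the assigned numbers (as
#'   character).
#' @export
set_node_labels <- function(tree, overwrite = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!overwrite && !is.null(tree$node.label)) return(tree)
  n <- length(tree$tip.label)
  cw <- ape::reorder.phylo(tree, "cladewise")
  ord <- unique(cw$edge[, 1])            # internal nodes, root first
  lab <- integer(tree$Nnode)
  lab[ord - n] <- seq(n + 1L, n + tree$Nnode)
  tree$node.label <- as.character(lab)
  tree
}

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] and validates the result: branch lengths must be
#' present and non-negative.  Internal labels are preserved if present in
#' the file, otherwise assigned by [set_node_labels()].
#'
#' @param path Path to a Newick file (ignored when `text` is given).
#' @param text Optional Newick string.
#' @return An ape `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    tr <- ape::read.tree(file = path)
  } else {
    tr <- ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo"))
    stop("expected a single tree, found several")
  if (is.null(tr$edge.length))
    stop("Newick input has no branch lengths")
  if (anyNA(tr$edge.length))
    stop("Newick input has missing branch lengths")
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    child <- tr$edge[neg[1], 2]
    what <- if (child <= length(tr$tip.label)) tr$tip.label[child]
            else sprintf("internal node %d", child)
    stop(sprintf("negative branch length %g on the edge to %s",
                 tr$edge.length[neg[1]], what))
  }
  has_labels <- !is.null(tr$node.label) && all(nzchar(tr$node.label))
  if (!has_labels) tr <- set_node_labels(tr)
  tr
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 12 significant digits so a write/read
#' round trip preserves them.
#'
#' @param tree An ape `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# Label -> ape node index map for internal nodes.
.internal_map <- function(tree) {
  if (is.null(tree$node.label)) tree <- set_node_labels(tree)
  n <- length(tree$tip.label)
  setNames(seq(n + 1L, n + tree$Nnode), tree$node.label)
}

# Children of every node, from the edge matrix.
.children_of <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1],
                               levels = seq_len(length(tree$tip.label) +
                                                tree$Nnode)))
}

.root_node <- function(tree) {
  n <- length(tree$tip.label)
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
}
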