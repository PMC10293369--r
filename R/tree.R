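#' Read a rooted bifurcating tree with node supports
#'
#' Reads a Newick tree whose numeric internal-node labels are interpreted as
#' node support. Support scale is auto-detected: if any numeric label
#' exceeds 1 the labels are taken to be percentages (e.g. bootstrap) and
#' normalized to \[0,1\]; otherwise they are taken to be on the unit scale
#' (e.g. posterior probability). Normalization is idempotent. Non-numeric
#' labels are preserved and treated as absent support.
#'
#' Polytomies are rejected by default because the downstream delimitation
#' methods require a binary tree; with `resolve_polytomies = TRUE` they are
#' resolved deterministically (left-branching in input order, zero-length
#' branches) and the new nodes carry absent support.
#'
#' @param path path to a Newick file (or `NULL` when `text` is given).
#' @param text Newick string, as an alternative to `path`.
#' @param resolve_polytomies resolve polytomies instead of rejecting them.
#' @return an ape `phylo` object with normalized support in `node.label`
#'   and a `support_scale` attribute (`"unit"`, `"percent"` or `"none"`).
#' @export
read_tree <- function(path = NULL, text = NULL, resolve_polytomies = FALSE) {
  tr <- if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    ape::read.tree(path)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("could not parse Newick tree")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf name: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  }
  if (!ape::is.binary.phylo(tr) || !ape::is.rooted(tr)) {
    if (!resolve_polytomies) {
      stop("tree contains polytomies (or is unrooted); a rooted binary tree ",
           "is required. Use resolve_polytomies = TRUE for deterministic ",
           "resolution in input order.")
    }
    tr <- ape::multi2di(tr, random = FALSE)
  }
  if (!ape::is.rooted(tr) || !ape::is.binary.phylo(tr)) {
    stop("tree could not be reduced to a rooted binary tree")
  }
  labs <- tr$node.label
  if (is.null(labs)) labs <- rep("", tr$Nnode)
  labs[is.na(labs)] <- ""
  sup <- suppressWarnings(as.numeric(labs))
  scale <- if (all(is.na(sup))) {
    "none"
  } else if (any(sup > 1, na.rm = TRUE)) {
    "percent"
  } else {
    "unit"
  }
  if (scale == "percent") sup <- sup / 100
  if (any(sup > 1 | sup < 0, na.rm = TRUE)) {
    stop("node support out of range after normalization")
  }
  tr$node.label <- ifelse(is.na(sup), labs, as.character(sup))
  attr(tr, "support_scale") <- scale
  tr
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Node support values of a tree
#'
#' @param tree a `phylo` object as returned by [read_tree()].
#' @return numeric vector of length `tree$Nnode`, `NA` where support is
#'   absent; index i corresponds to node `Ntip + i`.
#' @export
node_support <- function(tree) {
  labs <- tree$node.label
  if (is.null(labs)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(labs))
}

# support of an internal node id; absent support counts as 0 in threshold
# comparisons (a node without support must not pass a support test)
#' @noRd
support_at <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(NA_real_)
  node_support(tree)[node - ntip]
}

#' @noRd
root_node <- function(tree) length(tree$tip.label) + 1L

#' @noRd
parent_of <- function(tree, node) {
  i <- match(node, tree$edge[, 2L])
  if (is.na(i)) NA_integer_ else tree$edge[i, 1L]
}

# tip labels descending from a node (the node itself when it is a tip)
#' @noRd
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  idx <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
  tree$tip.label[idx]
}

# all nodes (tips + internals) in the subtree rooted at `node`, inclusive
#' @noRd
nodes_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- phangorn::Descendants(tree, node, type = "all")
  c(node, kids)
}

# node spanning a set of tip labels (the tip itself for a single label)
#' @noRd
span_node <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("tip(s) not in tree: ", paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) idx else ape::getMRCA(tree, idx)
}

# the other child of `node`'s parent; NA for the root
#' @noRd
sister_of <- function(tree, node) {
  p <- parent_of(tree, node)
  if (is.na(p)) return(NA_integer_)
  kids <- tree$edge[tree$edge[, 1L] == p, 2L]
  kids[kids != node]
}
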