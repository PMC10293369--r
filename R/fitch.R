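#' Optimize substitutions onto a fixed tree by Fitch parsimony
#'
#' Per site, a bottom-up Fitch pass assigns each internal node the
#' intersection of its children's state sets when non-empty, otherwise their
#' union; the number of unions is the site's Fitch length. A deterministic
#' top-down pass then resolves states: the root takes the alphabetically
#' smallest member (A < C < G < T) of its set, and each child takes its
#' parent's state when that state is in the child's set, otherwise the
#' alphabetically smallest member of its own set, recording a substitution
#' event on that branch. The number of events per site equals the site's
#' Fitch length, and the total equals the tree's parsimony score.
#'
#' Gaps, `N` and other missing tip states contribute the full state set
#' \{A,C,G,T\} (no event is ever forced by missing data); IUPAC ambiguity
#' codes contribute their code's state set.
#'
#' @param tree a rooted binary `phylo`; tip labels must equal the alignment
#'   sample ids.
#' @param alignment a [dna_alignment] over the same samples.
#' @return a `substitution_map`: list with `events` (data.frame with
#'   columns `site`, `branch` = child-node id, `branch_label`, `from`,
#'   `to`), `site_lengths` (integer vector, per-site Fitch length), `score`
#'   (total parsimony score), and the `tree`.
#' @export
fitch_optimize <- function(tree, alignment) {
  stopifnot(inherits(alignment, "dna_alignment"))
  if (!setequal(tree$tip.label, rownames(alignment))) {
    stop("tree leaves and alignment ids differ")
  }
  if (!ape::is.binary.phylo(tree) || !ape::is.rooted(tree)) {
    stop("a rooted binary tree is required")
  }
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  L <- ncol(alignment)

  B <- matrix(0L, nn, L)
  for (i in seq_len(ntip)) {
    B[i, ] <- char_bits(unclass(alignment)[tree$tip.label[i], ])
  }

  E <- ape::reorder.phylo(tree, "postorder")$edge
  parents <- unique(E[, 1L])  # postorder: children always precede parents
  site_len <- integer(L)
  for (p in parents) {
    ch <- E[E[, 1L] == p, 2L]
    inter <- bitwAnd(B[ch[1L], ], B[ch[2L], ])
    un <- inter == 0L
    if (any(un)) {
      inter[un] <- bitwOr(B[ch[1L], ], B[ch[2L], ])[un]
      site_len <- site_len + un
    }
    B[p, ] <- inter
  }

  root <- ntip + 1L
  St <- matrix(0L, nn, L)
  St[root, ] <- lowest_bit(B[root, ])
  ev_site <- integer(0)
  ev_branch <- integer(0)
  ev_from <- integer(0)
  ev_to <- integer(0)
  for (k in rev(seq_len(nrow(E)))) {  # preorder
    p <- E[k, 1L]
    ch <- E[k, 2L]
    ps <- St[p, ]
    keep <- bitwAnd(ps, B[ch, ]) > 0L
    st <- ps
    if (!all(keep)) {
      st[!keep] <- lowest_bit(B[ch, !keep])
      w <- which(!keep)
      ev_site <- c(ev_site, w)
      ev_branch <- c(ev_branch, rep.int(ch, length(w)))
      ev_from <- c(ev_from, ps[w])
      ev_to <- c(ev_to, st[w])
    }
    St[ch, ] <- st
  }

  events <- data.frame(
    site = ev_site,
    branch = ev_branch,
    branch_label = branch_label(tree, ev_branch),
    from = bit_base(ev_from),
    to = bit_base(ev_to),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$site, events$branch), , drop = FALSE]
  rownames(events) <- NULL
  structure(
    list(events = events, site_lengths = site_len, score = sum(site_len),
         tree = tree),
    class = "substitution_map"
  )
}

#' @export
print.substitution_map <- function(x, ...) {
  cat("Substitution map:", nrow(x$events), "events,",
      sum(x$site_lengths > 0L), "variable sites, parsimony score",
      x$score, "\n")
  invisible(x)
}

#' @noRd
branch_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  ifelse(node <= ntip, tree$tip.label[node], paste0("node", node))
}

# weight (number of substitution events) per edge, indexed by child node id
#' @noRd
edge_weights <- function(map) {
  tree <- map$tree
  nn <- length(tree$tip.label) + tree$Nnode
  tabulate(map$events$branch, nbins = nn)
}
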