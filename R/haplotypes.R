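#' Collapse identical sequences into haplotypes
#'
#' Under the `strict` policy two sequences belong to the same haplotype iff
#' they are identical character-by-character (an equivalence relation).
#' Under `ignore-missing`, sites where either sequence carries `-` or `N`
#' are skipped in the comparison; because that relation is not transitive,
#' strict haplotypes are merged greedily in descending count order (a
#' haplotype compatible with more than one existing cluster is merged into
#' the largest, with a warning). Haplotypes are ordered by descending count,
#' then by first-member id.
#'
#' @param alignment a [dna_alignment].
#' @param policy `"strict"` (default) or `"ignore-missing"`.
#' @return a `haplotype_set`: list with `haplotypes` (each a list with
#'   `id`, `members`, `sequence`, `count`), `index` (named integer mapping
#'   sample id to haplotype number), `policy`, `n`.
#' @export
collapse_haplotypes <- function(alignment, policy = c("strict", "ignore-missing")) {
  policy <- match.arg(policy)
  stopifnot(inherits(alignment, "dna_alignment"), nrow(alignment) >= 1L)
  keys <- alignment_strings(alignment)
  groups <- split(rownames(alignment), factor(keys, levels = unique(keys)))

  if (policy == "ignore-missing") {
    ord <- order(-lengths(groups), vapply(groups, `[`, "", 1L))
    groups <- groups[ord]
    reps <- vapply(groups, `[`, "", 1L)
    clusters <- list()
    cl_reps <- list()  # representative strict sequences per cluster
    for (g in seq_along(groups)) {
      s <- unclass(alignment)[reps[g], ]
      compat <- vapply(cl_reps, function(rs) {
        all(vapply(rs, function(r) sequences_compatible(s, r), logical(1L)))
      }, logical(1L))
      hit <- which(compat)
      if (length(hit) == 0L) {
        clusters[[length(clusters) + 1L]] <- groups[[g]]
        cl_reps[[length(cl_reps) + 1L]] <- list(s)
      } else {
        if (length(hit) > 1L) {
          warning("ambiguous haplotype merge under ignore-missing policy; ",
                  "merged into the largest compatible cluster")
        }
        k <- hit[1L]
        clusters[[k]] <- c(clusters[[k]], groups[[g]])
        cl_reps[[k]] <- c(cl_reps[[k]], list(s))
      }
    }
    groups <- clusters
  }

  first <- vapply(groups, `[`, "", 1L)
  ord <- order(-lengths(groups), first)
  groups <- groups[ord]
  haps <- lapply(seq_along(groups), function(i) {
    list(id = paste0("H", i),
         members = groups[[i]],
         sequence = paste(unclass(alignment)[groups[[i]][1L], ], collapse = ""),
         count = length(groups[[i]]))
  })
  index <- integer(nrow(alignment))
  names(index) <- rownames(alignment)
  for (i in seq_along(haps)) index[haps[[i]]$members] <- i
  structure(list(haplotypes = haps, index = index, policy = policy,
                 n = nrow(alignment)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", length(x$haplotypes), "haplotypes over", x$n,
      "sequences (policy:", x$policy, ")\n")
  for (h in utils::head(x$haplotypes, 10L)) {
    cat(sprintf("  %-4s n=%-3d %s%s\n", h$id, h$count, h$members[1L],
                if (h$count > 1L) paste0(" +", h$count - 1L) else ""))
  }
  invisible(x)
}

#' @noRd
sequences_compatible <- function(a, b) {
  ok <- a != "-" & a != "N" & b != "-" & b != "N"
  all(a[ok] == b[ok])
}

#' Transform a bifurcating tree into a haplotype genealogy
#'
#' Builds a haplotype-network view of a rooted bifurcating tree: per-site
#' substitutions are optimized onto the tree with [fitch_optimize()] after
#' reducing the tree to one representative tip per haplotype; edges carrying
#' zero substitutions are contracted (merging haplotype tips with identical
#' internal nodes); internal nodes left without sampled members become
#' inferred nodes of size 0; and inferred nodes of degree 2 (including the
#' root, giving the genealogy unrooted semantics) are spliced out with their
#' edge weights summed. Node size is the number of sequence records; edge
#' weight is the number of substitutions on the contracted path.
#'
#' @param tree rooted binary `phylo` over all alignment samples.
#' @param alignment a [dna_alignment].
#' @param haplotypes optionally a precomputed [collapse_haplotypes()] result.
#' @param policy haplotype comparison policy when `haplotypes` is NULL.
#' @return a `haplotype_genealogy`: list with `nodes` (data.frame `id`,
#'   `size`), `members` (named list id -> sample ids), `edges` (data.frame
#'   `from`, `to`, `weight`), `n_sequences`, `policy`.
#' @export
build_genealogy <- function(tree, alignment, haplotypes = NULL,
                            policy = "strict") {
  stopifnot(inherits(alignment, "dna_alignment"))
  if (!setequal(tree$tip.label, rownames(alignment))) {
    stop("tree leaves and alignment ids differ")
  }
  haps <- haplotypes %||% collapse_haplotypes(alignment, policy)
  K <- length(haps$haplotypes)
  if (K == 1L) {
    return(new_genealogy(
      nodes = data.frame(id = "H1", size = haps$n, stringsAsFactors = FALSE),
      members = list(H1 = haps$haplotypes[[1L]]$members),
      edges = data.frame(from = character(0), to = character(0),
                         weight = integer(0), stringsAsFactors = FALSE),
      n_sequences = haps$n, policy = haps$policy
    ))
  }
  reps <- vapply(haps$haplotypes, function(h) h$members[1L], "")
  red <- if (K < length(tree$tip.label)) {
    ape::drop.tip(tree, setdiff(tree$tip.label, reps))
  } else {
    tree
  }
  map <- fitch_optimize(red, alignment[reps, , drop = FALSE])
  w <- edge_weights(map)
  ntip <- length(red$tip.label)
  nn <- ntip + red$Nnode

  # union-find contraction of zero-weight edges
  comp <- seq_len(nn)
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  for (k in seq_len(nrow(red$edge))) {
    ch <- red$edge[k, 2L]
    if (w[ch] == 0L) {
      a <- find(red$edge[k, 1L])
      b <- find(ch)
      if (a != b) comp[b] <- a
    }
  }
  grp <- vapply(seq_len(nn), find, 1L)
  members <- lapply(seq_len(nn), function(g) {
    tips <- which(grp == g & seq_len(nn) <= ntip)
    unlist(lapply(tips, function(i) {
      haps$haplotypes[[haps$index[red$tip.label[i]]]]$members
    }), use.names = FALSE) %||% character(0)
  })
  keep <- which(vapply(seq_len(nn), function(i) grp[i] == i, logical(1L)))
  e <- red$edge[w[red$edge[, 2L]] > 0L, , drop = FALSE]
  edges <- data.frame(a = vapply(e[, 1L], find, 1L),
                      b = vapply(e[, 2L], find, 1L),
                      weight = w[e[, 2L]])

  # splice degree-2 nodes without sampled members (root included)
  sizes <- lengths(members)
  repeat {
    deg <- tabulate(c(edges$a, edges$b), nbins = nn)
    cand <- intersect(keep[sizes[keep] == 0L & deg[keep] == 2L], unique(c(edges$a, edges$b)))
    if (length(cand) == 0L) break
    x <- cand[1L]
    inc <- which(edges$a == x | edges$b == x)
    ends <- setdiff(unique(c(edges$a[inc], edges$b[inc])), x)
    new_w <- sum(edges$weight[inc])
    edges <- edges[-inc, , drop = FALSE]
    edges <- rbind(edges, data.frame(a = ends[1L], b = ends[2L], weight = new_w))
    keep <- setdiff(keep, x)
  }
  used <- sort(unique(c(edges$a, edges$b, keep[sizes[keep] > 0L])))

  # name sampled nodes after their dominant haplotype, inferred nodes I1..
  node_id <- character(nn)
  inf_i <- 0L
  for (g in used) {
    if (sizes[g] > 0L) {
      hs <- sort(unique(haps$index[members[[g]]]))
      node_id[g] <- haps$haplotypes[[hs[1L]]]$id
    } else {
      inf_i <- inf_i + 1L
      node_id[g] <- paste0("I", inf_i)
    }
  }
  ord <- used[order(sizes[used] == 0L, node_id[used])]
  nodes <- data.frame(id = node_id[ord], size = sizes[ord],
                      stringsAsFactors = FALSE)
  mem <- stats::setNames(members[ord], node_id[ord])
  edges_out <- data.frame(from = node_id[edges$a], to = node_id[edges$b],
                          weight = as.integer(edges$weight),
                          stringsAsFactors = FALSE)
  new_genealogy(nodes = nodes, members = mem, edges = edges_out,
                n_sequences = haps$n, policy = haps$policy)
}

#' @noRd
new_genealogy <- function(nodes, members, edges, n_sequences, policy) {
  stopifnot(sum(nodes$size) == n_sequences, all(edges$weight >= 1L))
  # a genealogy derived from a tree is itself a tree: connected and acyclic
  if (nrow(nodes) > 1L && nrow(edges) != nrow(nodes) - 1L) {
    stop("internal error: genealogy is not tree-shaped")
  }
  structure(list(nodes = nodes, members = members, edges = edges,
                 n_sequences = n_sequences, policy = policy),
            class = "haplotype_genealogy")
}

#' @export
print.haplotype_genealogy <- function(x, ...) {
  cat("Haplotype genealogy:", nrow(x$nodes), "nodes (",
      sum(x$nodes$size > 0L), "sampled ),", nrow(x$edges), "edges,",
      x$n_sequences, "sequences\n")
  if (nrow(x$edges)) {
    for (i in seq_len(min(nrow(x$edges), 12L))) {
      cat(sprintf("  %s -- %s  [%d]\n", x$edges$from[i], x$edges$to[i],
                  x$edges$weight[i]))
    }
  }
  invisible(x)
}

#' Export a haplotype genealogy as DOT or JSON text
#'
#' DOT output renders nodes as circles whose area is proportional to the
#' number of sequence records, with edge labels giving substitution counts;
#' when a sample table is supplied, nodes are colored by the majority
#' `clade_label` of their members. JSON output is a full, round-trippable
#' serialization (see [import_genealogy()]).
#'
#' @param genealogy a `haplotype_genealogy`.
#' @param format `"dot"` or `"json"`.
#' @param samples optional sample table for DOT node coloring.
#' @return a single character string.
#' @export
export_genealogy <- function(genealogy, format = c("dot", "json"),
                             samples = NULL) {
  format <- match.arg(format)
  g <- genealogy
  if (format == "json") {
    obj <- list(
      nodes = lapply(seq_len(nrow(g$nodes)), function(i) {
        list(id = g$nodes$id[i], size = g$nodes$size[i],
             members = as.list(g$members[[g$nodes$id[i]]]))
      }),
      edges = lapply(seq_len(nrow(g$edges)), function(i) {
        list(from = g$edges$from[i], to = g$edges$to[i],
             weight = g$edges$weight[i])
      }),
      metadata = list(n_sequences = g$n_sequences, policy = g$policy)
    )
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)))
  }
  pal <- c("#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3", "#a6d854",
           "#ffd92f", "#e5c494", "#b3b3b3")
  col_of <- function(id) {
    if (is.null(samples)) return("#cccccc")
    cls <- samples$clade_label[match(g$members[[id]], samples$sample_id)]
    cls <- cls[!is.na(cls)]
    if (!length(cls)) return("#cccccc")
    maj <- names(sort(table(cls), decreasing = TRUE))[1L]
    pal[(match(maj, sort(unique(samples$clade_label))) - 1L) %% length(pal) + 1L]
  }
  lines <- c("graph haplotype_genealogy {",
             "  node [shape=circle, fixedsize=true, style=filled];")
  for (i in seq_len(nrow(g$nodes))) {
    id <- g$nodes$id[i]
    sz <- g$nodes$size[i]
    if (sz > 0L) {
      lines <- c(lines, sprintf(
        '  "%s" [width=%.3f, label="%s (%d)", fillcolor="%s"];',
        id, 0.4 * sqrt(sz) + 0.2, id, sz, col_of(id)))
    } else {
      lines <- c(lines, sprintf(
        '  "%s" [width=0.12, label="", fillcolor="black"];', id))
    }
  }
  for (i in seq_len(nrow(g$edges))) {
    lines <- c(lines, sprintf('  "%s" -- "%s" [label="%d"];',
                              g$edges$from[i], g$edges$to[i],
                              g$edges$weight[i]))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Import a haplotype genealogy from JSON
#'
#' @param text JSON text produced by [export_genealogy()] (or a file path).
#' @return a `haplotype_genealogy`.
#' @export
import_genealogy <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  nodes <- data.frame(
    id = vapply(obj$nodes, `[[`, "", "id"),
    size = vapply(obj$nodes, function(n) as.integer(n$size), 1L),
    stringsAsFactors = FALSE
  )
  members <- stats::setNames(
    lapply(obj$nodes, function(n) as.character(unlist(n$members))),
    nodes$id
  )
  edges <- if (length(obj$edges)) {
    data.frame(
      from = vapply(obj$edges, `[[`, "", "from"),
      to = vapply(obj$edges, `[[`, "", "to"),
      weight = vapply(obj$edges, function(e) as.integer(e$weight), 1L),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(from = character(0), to = character(0), weight = integer(0),
               stringsAsFactors = FALSE)
  }
  new_genealogy(nodes = nodes, members = members, edges = edges,
                n_sequences = obj$metadata$n_sequences,
                policy = obj$metadata$policy)
}
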