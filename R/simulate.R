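#' Clade specification for the structured simulator
#'
#' @param id unique identifier of this clade instance (a tip of the label
#'   topology given to [simulate_structured()]).
#' @param label a-priori species label (several instances may share one
#'   label, e.g. to plant an interdigitated synonym candidate).
#' @param n number of samples in the clade.
#' @param theta within-clade scaled mutation parameter (theta >= 0);
#'   within-clade branches receive Poisson(branch length x theta / 2)
#'   mutations.
#' @param stem number of diagnostic substitutions planted on the clade's
#'   stem branch.
#' @param tip_subs number of private substitutions planted on every tip's
#'   pendant branch (guarantees distinct haplotypes irrespective of theta).
#' @param support support value stamped on the clade's MRCA node.
#' @param clade_label named-clade assignment recorded in the sample table.
#' @param ingroup whether the clade belongs to the delimitation in-group.
#' @return a `clade_spec` list.
#' @export
clade_spec <- function(id, label = id, n = 1L, theta = 0, stem = 0L,
                       tip_subs = 0L, support = 1, clade_label = label,
                       ingroup = TRUE) {
  stopifnot(n >= 1L, theta >= 0, stem >= 0L, tip_subs >= 0L,
            support >= 0, support <= 1)
  structure(list(id = id, label = label, n = as.integer(n), theta = theta,
                 stem = as.integer(stem), tip_subs = as.integer(tip_subs),
                 support = support, clade_label = clade_label,
                 ingroup = ingroup),
            class = "clade_spec")
}

# neutral coalescent subtree as a Newick fragment (no trailing ";"):
# waiting time for k lineages ~ Exp(k(k-1)/2), joined pair chosen uniformly.
# Internal nodes are labelled "1" except the final (root) join, which gets
# `root_label`. For n = 1 returns a bare tip.
#' @noRd
coalescent_newick <- function(n, prefix, root_label = "1",
                              rate_change = NULL, inner_label = "1") {
  tips <- paste0(prefix, "_", seq_len(n))
  if (n == 1L) return(list(str = tips, tips = tips, height = 0))
  strs <- tips
  hts <- numeric(n)
  t <- 0
  k <- n
  while (k > 1L) {
    rate <- k * (k - 1) / 2
    if (is.null(rate_change)) {
      t <- t + stats::rexp(1L, rate)
    } else {
      # instantaneous size change looking back: coalescent rate is
      # multiplied by f for times older than t0
      t0 <- rate_change[["t"]]
      f <- rate_change[["f"]]
      if (t >= t0) {
        t <- t + stats::rexp(1L, rate * f)
      } else {
        dt <- stats::rexp(1L, rate)
        if (t + dt <= t0) {
          t <- t + dt
        } else {
          t <- t0 + stats::rexp(1L, rate * f)
        }
      }
    }
    pair <- sample.int(k, 2L)
    lab <- if (k == 2L) root_label else inner_label
    joined <- sprintf("(%s:%.10f,%s:%.10f)%s",
                      strs[pair[1L]], t - hts[pair[1L]],
                      strs[pair[2L]], t - hts[pair[2L]], lab)
    keep <- setdiff(seq_len(k), pair)
    strs <- c(strs[keep], joined)
    hts <- c(hts[keep], t)
    k <- k - 1L
  }
  list(str = strs, tips = tips, height = t)
}

#' Simulate a clade-structured alignment with planted diagnostics
#'
#' Emulates the data a single-locus delimitation study analyzes: a rooted
#' binary topology over clade instances, each clade expanded into a neutral
#' coalescent genealogy with within-clade mutations at rate theta/2 per
#' branch-length unit, plus exactly `stem` diagnostic substitutions planted
#' on each clade's stem branch (and optionally private substitutions on
#' every tip). In homoplasy-free mode (the default) every mutation occupies
#' its own alignment site with a derived state different from the root
#' state, so the simulation ledger exactly determines the expected
#' diagnostics, exclusivity labels and genealogy. Node supports are stamped
#' from the specs (clade MRCAs) and from `internal_supports` (named internal
#' nodes of the topology; unnamed internal nodes get 1).
#'
#' All randomness comes from one stream seeded with `seed`, drawn in a fixed
#' order: clade genealogies (spec order), root sequence, site permutation,
#' mutation counts/placements (spec order; within a clade: subtree edges by
#' child node id, then tip branches, then the stem), internal-clade stems,
#' then derived states in tree preorder.
#'
#' @param specs list of [clade_spec()] objects.
#' @param topology Newick string over the spec ids (rooted, binary);
#'   internal node labels name internal clades for `internal_supports` /
#'   `internal_stems`.
#' @param L alignment length in sites.
#' @param seed integer seed.
#' @param homoplasy_free when TRUE (default), mutations occupy distinct
#'   sites (infinite-sites); an error is raised when sites are exhausted.
#' @param internal_supports named numeric vector: support for named internal
#'   topology nodes (default 1 everywhere).
#' @param internal_stems named integer vector: diagnostic substitutions
#'   planted on the stem of named internal topology nodes.
#' @param default_support support stamped on unlabeled internal topology
#'   nodes and on within-clade coalescent nodes.
#' @param out_dir optional directory; when given, FASTA/Newick/TSV/ledger
#'   JSON are written there.
#' @return list with `alignment`, `tree` (supports normalized), `samples`,
#'   `ledger` (list: `tree`, `mutations` data.frame(site, branch, from,
#'   to), `partition`, `params`, `seed`).
#' @export
simulate_structured <- function(specs, topology, L, seed,
                                homoplasy_free = TRUE,
                                internal_supports = NULL,
                                internal_stems = NULL,
                                default_support = 1,
                                out_dir = NULL) {
  set.seed(seed)
  ids <- vapply(specs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate clade spec ids")
  names(specs) <- ids

  # 1. within-clade genealogies
  subs <- lapply(specs, function(sp) {
    coalescent_newick(sp$n, sp$id, root_label = as.character(sp$support),
                      inner_label = as.character(default_support))
  })

  # assemble the full Newick by replacing each topology tip with its clade
  if (length(specs) == 1L) {
    if (specs[[1L]]$n < 2L) stop("a single-clade simulation needs n >= 2")
    full_newick <- paste0(subs[[1L]]$str, ";")
  } else {
    topo <- ape::read.tree(text = topology)
    if (is.null(topo)) stop("could not parse label topology")
    if (!setequal(topo$tip.label, ids)) {
      stop("topology tips must equal the clade spec ids")
    }
    if (!ape::is.binary.phylo(topo) || !ape::is.rooted(topo)) {
      stop("label topology must be rooted and binary")
    }
    sup_of <- function(node) {
      lab <- if (is.null(topo$node.label)) "" else
        topo$node.label[node - length(topo$tip.label)]
      if (!is.null(internal_supports) && !is.na(lab) &&
          lab %in% names(internal_supports)) {
        return(internal_supports[[lab]])
      }
      v <- suppressWarnings(as.numeric(lab))
      if (!is.na(v)) v else default_support
    }
    emit <- function(node) {
      ntip <- length(topo$tip.label)
      if (node <= ntip) return(subs[[topo$tip.label[node]]]$str)
      kids <- topo$edge[topo$edge[, 1L] == node, 2L]
      inner <- paste(vapply(kids, function(k) paste0(emit(k), ":1"), ""),
                     collapse = ",")
      paste0("(", inner, ")", sup_of(node))
    }
    full_newick <- paste0(emit(length(topo$tip.label) + 1L), ";")
  }
  tree <- read_tree(text = full_newick)

  clade_tip_sets <- lapply(specs, function(sp) {
    paste0(sp$id, "_", seq_len(sp$n))
  })

  # 2. root sequence and site pool
  root_seq <- sample(BASES, L, replace = TRUE)
  pool <- if (homoplasy_free) sample.int(L) else NULL
  pool_pos <- 0L
  draw_sites <- function(m) {
    if (m == 0L) return(integer(0))
    if (homoplasy_free) {
      if (pool_pos + m > L) {
        stop("site exhaustion in homoplasy-free mode: need more than ", L,
             " sites")
      }
      out <- pool[pool_pos + seq_len(m)]
      pool_pos <<- pool_pos + m
      out
    } else {
      sample.int(L, m, replace = TRUE)
    }
  }

  ntip <- length(tree$tip.label)
  edge_len <- tree$edge.length
  child_of_edge <- tree$edge[, 2L]

  # 3. mutation placement: (branch, site) pairs
  mut_branch <- integer(0)
  mut_site <- integer(0)
  place <- function(branch_node, m) {
    if (m > 0L) {
      mut_branch <<- c(mut_branch, rep.int(branch_node, m))
      mut_site <<- c(mut_site, draw_sites(m))
    }
  }
  for (sp in specs) {
    tips <- clade_tip_sets[[sp$id]]
    node <- span_node(tree, tips)
    if (sp$n >= 2L && sp$theta > 0) {
      inner <- setdiff(nodes_below(tree, node), node)
      inner <- sort(inner)
      for (ch in inner) {
        len <- edge_len[match(ch, child_of_edge)]
        place(ch, stats::rpois(1L, len * sp$theta / 2))
      }
    }
    if (sp$tip_subs > 0L) {
      for (tp in sort(match(tips, tree$tip.label))) place(tp, sp$tip_subs)
    }
    if (sp$stem > 0L) {
      if (is.na(parent_of(tree, node))) {
        warning("clade '", sp$id, "' spans the whole tree; its stem ",
                "substitutions were skipped")
      } else {
        place(node, sp$stem)
      }
    }
  }
  if (!is.null(internal_stems)) {
    for (nm in names(internal_stems)) {
      members <- unlist(clade_tip_sets[named_clade_specs(specs, topology, nm)],
                        use.names = FALSE)
      node <- span_node(tree, members)
      place(node, internal_stems[[nm]])
    }
  }

  # 4. apply mutations root -> tips, drawing derived states in preorder
  seqs <- matrix("", ntip, L, dimnames = list(tree$tip.label, NULL))
  E <- ape::reorder.phylo(tree, "postorder")$edge
  mut_from <- character(length(mut_site))
  mut_to <- character(length(mut_site))
  state_env <- new.env(parent = emptyenv())
  assign(as.character(root_node(tree)), root_seq, envir = state_env)
  for (k in rev(seq_len(nrow(E)))) {  # preorder
    p <- E[k, 1L]
    ch <- E[k, 2L]
    s <- get(as.character(p), envir = state_env)
    hit <- which(mut_branch == ch)
    for (h in hit) {
      cur <- s[mut_site[h]]
      mut_from[h] <- cur
      mut_to[h] <- sample(setdiff(BASES, cur), 1L)
      s[mut_site[h]] <- mut_to[h]
    }
    if (ch <= ntip) {
      seqs[tree$tip.label[ch], ] <- s
    } else {
      assign(as.character(ch), s, envir = state_env)
    }
  }
  alignment <- dna_alignment(seqs)

  samples <- do.call(rbind, lapply(specs, function(sp) {
    data.frame(sample_id = clade_tip_sets[[sp$id]],
               species_label = sp$label, clade_label = sp$clade_label,
               ingroup = sp$ingroup, lat = NA_real_, lon = NA_real_,
               stringsAsFactors = FALSE)
  }))
  samples <- sample_table(samples[match(tree$tip.label, samples$sample_id), ])

  haps <- collapse_haplotypes(alignment)
  partition <- lapply(haps$haplotypes, `[[`, "members")

  ledger <- list(
    tree = tree,
    mutations = data.frame(site = mut_site, branch = mut_branch,
                           from = mut_from, to = mut_to,
                           stringsAsFactors = FALSE),
    partition = partition,
    params = list(specs = specs, topology = topology, L = L,
                  homoplasy_free = homoplasy_free,
                  internal_supports = as.list(internal_supports),
                  internal_stems = as.list(internal_stems)),
    seed = seed
  )
  out <- list(alignment = alignment, tree = tree, samples = samples,
              ledger = ledger)
  if (!is.null(out_dir)) write_simulation(out, out_dir)
  out
}

# spec ids descending from a named internal node of the label topology
#' @noRd
named_clade_specs <- function(specs, topology, name) {
  topo <- ape::read.tree(text = topology)
  idx <- match(name, topo$node.label)
  if (is.na(idx)) stop("no internal topology node named '", name, "'")
  tips_below(topo, length(topo$tip.label) + idx)
}

#' @noRd
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(sim$alignment, file.path(out_dir, "alignment.fasta"))
  write_tree(sim$tree, file.path(out_dir, "tree.nwk"))
  write_samples(sim$samples, file.path(out_dir, "samples.tsv"))
  led <- sim$ledger
  led$tree <- ape::write.tree(led$tree)
  led$params$specs <- lapply(led$params$specs, unclass)
  led$partition <- lapply(led$partition, as.list)
  jsonlite::write_json(led, file.path(out_dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a single population under constant size or sudden expansion
#'
#' Standard neutral coalescent for `n` samples in coalescent units; with
#' `expansion = c(t = .., f = ..)` the coalescent rate is multiplied by `f`
#' for times older than `t` (an instantaneous size change looking back:
#' f > 1 means the population was f-fold smaller before the expansion).
#' Mutations are Poisson with mean (branch length x theta0 / 2) per branch,
#' placed on distinct sites (infinite sites over L sites; exceeding L is an
#' error).
#'
#' @param n number of samples (>= 2).
#' @param theta0 scaled mutation parameter of the present population.
#' @param expansion `NULL` for constant size, or `c(t = , f = )`.
#' @param L number of sites.
#' @param seed integer seed.
#' @return list with `alignment` and `ledger` (tree, mutations, params,
#'   seed).
#' @export
simulate_demographic <- function(n, theta0, expansion = NULL, L, seed) {
  stopifnot(n >= 2L, theta0 >= 0, L >= 1L)
  if (!is.null(expansion)) {
    stopifnot(expansion[["f"]] > 0, expansion[["t"]] >= 0)
  }
  set.seed(seed)
  cn <- coalescent_newick(n, "s", rate_change = expansion)
  tree <- ape::read.tree(text = paste0(cn$str, ";"))
  ntip <- length(tree$tip.label)

  root_seq <- sample(BASES, L, replace = TRUE)
  m_per_edge <- stats::rpois(nrow(tree$edge), tree$edge.length * theta0 / 2)
  m_tot <- sum(m_per_edge)
  if (m_tot > L) {
    stop("site exhaustion: ", m_tot, " mutations exceed L = ", L, " sites")
  }
  sites <- sample.int(L, m_tot)
  mut_branch <- rep.int(tree$edge[, 2L], m_per_edge)
  mut_to <- character(m_tot)
  mut_from <- root_seq[sites]
  for (h in seq_len(m_tot)) {
    mut_to[h] <- sample(setdiff(BASES, mut_from[h]), 1L)
  }

  seqs <- matrix("", ntip, L, dimnames = list(tree$tip.label, NULL))
  E <- ape::reorder.phylo(tree, "postorder")$edge
  state_env <- new.env(parent = emptyenv())
  assign(as.character(ntip + 1L), root_seq, envir = state_env)
  for (k in rev(seq_len(nrow(E)))) {
    p <- E[k, 1L]
    ch <- E[k, 2L]
    s <- get(as.character(p), envir = state_env)
    hit <- which(mut_branch == ch)
    if (length(hit)) s[sites[hit]] <- mut_to[hit]
    if (ch <= ntip) {
      seqs[tree$tip.label[ch], ] <- s
    } else {
      assign(as.character(ch), s, envir = state_env)
    }
  }
  list(
    alignment = dna_alignment(seqs),
    ledger = list(tree = tree,
                  mutations = data.frame(site = sites, branch = mut_branch,
                                         from = mut_from, to = mut_to,
                                         stringsAsFactors = FALSE),
                  params = list(n = n, theta0 = theta0,
                                expansion = as.list(expansion), L = L),
                  seed = seed)
  )
}

#' Canned study-shaped fixture
#'
#' A configuration shaped like a single-locus delimitation study of a small
#' species group: six in-group labels of which three are "good" species
#' with planted stem diagnostics of sizes 2, 5 and 5, three labels
#' interdigitated around them (synonym analogues), two out-group labels,
#' and three diagnostic substitutions planted on the in-group stem. All
#' supports are 1 except the first species' own node (0.7), whose sister
#' branch is well supported — so the full pipeline exercises the
#' sister-rescue rule, the single-haplotype rule (the second species is one
#' haplotype), and the consensus, yielding exactly 3 valid species and 3
#' synonym candidates.
#'
#' @param seed integer seed.
#' @param support_override when not NULL, a single value replacing every
#'   stamped support.
#' @param stem_override when not NULL, a single count replacing the three
#'   species' stem diagnostics (and the in-group stem).
#' @return a [simulate_structured()] result.
#' @export
make_paper_analogue <- function(seed = 1L, support_override = NULL,
                                stem_override = NULL) {
  sp_stem <- function(x) if (is.null(stem_override)) x else stem_override
  sup <- function(x) if (is.null(support_override)) x else support_override
  specs <- list(
    clade_spec("sp1", label = "species_A", n = 5L, theta = 0,
               stem = sp_stem(2L), tip_subs = 1L, support = sup(0.7),
               clade_label = "cladeA"),
    clade_spec("synDa", label = "species_D", n = 1L, stem = 1L,
               clade_label = "cladeA", support = sup(1)),
    clade_spec("synDb", label = "species_D", n = 1L, stem = 1L,
               clade_label = "cladeA", support = sup(1)),
    clade_spec("synEa", label = "species_E", n = 1L, stem = 1L,
               clade_label = "cladeA", support = sup(1)),
    clade_spec("synEb", label = "species_E", n = 1L, stem = 1L,
               clade_label = "cladeA", support = sup(1)),
    clade_spec("sp2", label = "species_B", n = 2L, theta = 0,
               stem = sp_stem(5L), support = sup(1), clade_label = "cladeB"),
    clade_spec("sp3", label = "species_C", n = 4L, theta = 0,
               stem = sp_stem(5L), tip_subs = 1L, support = sup(1),
               clade_label = "cladeB"),
    clade_spec("synFa", label = "species_F", n = 1L, stem = 1L,
               clade_label = "cladeB", support = sup(1)),
    clade_spec("synFb", label = "species_F", n = 1L, stem = 1L,
               clade_label = "cladeB", support = sup(1)),
    clade_spec("out1", label = "outgroup_A", n = 2L, stem = 2L,
               support = sup(1), clade_label = "outgroup", ingroup = FALSE),
    clade_spec("out2", label = "outgroup_B", n = 1L, stem = 2L,
               clade_label = "outgroup", ingroup = FALSE)
  )
  topology <- paste0(
    "(((synDa,((synEa,(sp1,synEb)),synDb))cladeA,",
    "(sp2,(synFa,(sp3,synFb)))cladeB)ingroup,(out1,out2)outs);"
  )
  simulate_structured(
    specs, topology, L = 1039L, seed = seed,
    default_support = sup(1),
    internal_supports = stats::setNames(
      rep(sup(1), 4L), c("cladeA", "cladeB", "ingroup", "outs")),
    internal_stems = c(ingroup = if (is.null(stem_override)) 3L
                       else as.integer(stem_override))
  )
}
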