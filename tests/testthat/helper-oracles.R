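# Independent oracles used to verify the package's implementations.
# These deliberately use brute-force / literal-formula code paths that share
# nothing with the implementations they check.

# --- brute-force pairwise difference recount (double loop over sites) -----
brute_pairwise <- function(aln, policy = "complete-deletion") {
  m <- unclass(aln)
  missing <- !(m %in% c("A", "C", "G", "T"))
  dim(missing) <- dim(m)
  n <- nrow(m)
  if (policy == "complete-deletion") {
    keep <- !apply(missing, 2, any)
    m <- m[, keep, drop = FALSE]
    missing <- missing[, keep, drop = FALSE]
  }
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- 0L
      for (s in seq_len(ncol(m))) {
        if (!missing[i, s] && !missing[j, s] && m[i, s] != m[j, s]) d <- d + 1L
      }
      D[i, j] <- d
    }
  }
  dimnames(D) <- list(rownames(unclass(aln)), rownames(unclass(aln)))
  D
}

# --- literal-formula evaluation of Tajima's D and R2 from raw loops ------
oracle_d_r2 <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  L <- ncol(m)
  # assumes pure ACGT input
  S <- 0L
  U <- integer(n)
  for (s in seq_len(L)) {
    col <- m[, s]
    if (length(unique(col)) > 1L) S <- S + 1L
    for (i in seq_len(n)) {
      if (!any(col[-i] == col[i])) U[i] <- U[i] + 1L
    }
  }
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + sum(m[i, ] != m[j, ])
      np <- np + 1
    }
  }
  kbar <- tot / np
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- if (S > 0 && n >= 4) (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)) else NA
  R2 <- if (S > 0) sqrt(sum((U - kbar / 2)^2) / n) / S else NA
  list(S = S, k_bar = kbar, D = D, R2 = R2, U = U)
}

# --- exhaustive minimal-assignment parsimony for one site ----------------
# enumerates every assignment of {A,C,G,T} to the internal nodes and takes
# the minimum number of state changes over the edges
exhaustive_site_length <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  code <- match(tip_states[tree$tip.label], c("A", "C", "G", "T"))
  A <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  total <- integer(nrow(A))
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    ch <- tree$edge[k, 2L]
    ps <- A[, p - ntip]
    cs <- if (ch <= ntip) rep(code[ch], nrow(A)) else A[, ch - ntip]
    total <- total + (ps != cs)
  }
  min(total)
}

# --- brute-force global Needleman-Wunsch with traceback ------------------
# match 1, mismatch -1, linear gap -2; N scores 0 against anything;
# returns the alignment-column -> reference-position map
nw_map_oracle <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(p)
  m <- length(s)
  sc <- function(a, b) if (a == "N" || b == "N") 0 else if (a == b) 1 else -1
  F <- matrix(-Inf, n + 1, m + 1)
  F[1, ] <- -2 * (0:m)
  F[, 1] <- -2 * (0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      F[i + 1, j + 1] <- max(F[i, j] + sc(p[i], s[j]),
                             F[i, j + 1] - 2, F[i + 1, j] - 2)
    }
  }
  map <- rep(NA_integer_, n)
  i <- n
  j <- m
  while (i > 0 && j > 0) {
    if (F[i + 1, j + 1] == F[i, j] + sc(p[i], s[j])) {
      map[i] <- j
      i <- i - 1
      j <- j - 1
    } else if (F[i + 1, j + 1] == F[i, j + 1] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  map
}

# --- canonical forms for genealogy comparison ----------------------------
# a tree-shaped genealogy is determined by (a) the partition of samples
# into sampled nodes and (b) the member bipartition + weight of every edge
canon_partition <- function(member_sets) {
  unname(sort(vapply(member_sets, function(x) paste(sort(x), collapse = ","), "")))
}

canon_genealogy <- function(g) {
  ids <- g$nodes$id
  adj <- lapply(ids, function(i) {
    c(g$edges$to[g$edges$from == i], g$edges$from[g$edges$to == i])
  })
  names(adj) <- ids
  side_members <- function(start, blocked_a, blocked_b) {
    seen <- start
    queue <- start
    while (length(queue)) {
      x <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[x]]) {
        if ((x == blocked_a && nb == blocked_b) ||
            (x == blocked_b && nb == blocked_a)) next
        if (!nb %in% seen) {
          seen <- c(seen, nb)
          queue <- c(queue, nb)
        }
      }
    }
    sort(unlist(g$members[seen], use.names = FALSE))
  }
  keys <- vapply(seq_len(nrow(g$edges)), function(k) {
    a <- side_members(g$edges$from[k], g$edges$from[k], g$edges$to[k])
    b <- side_members(g$edges$to[k], g$edges$from[k], g$edges$to[k])
    ka <- paste(a, collapse = ",")
    kb <- paste(b, collapse = ",")
    paste0(min(ka, kb), "#", g$edges$weight[k])
  }, "")
  list(partition = canon_partition(g$members[g$nodes$size > 0]),
       edges = sort(keys))
}

# expected genealogy canonical form straight from a simulation ledger:
# contract true-tree edges by true mutation counts
canon_from_ledger <- function(ledger) {
  tree <- ledger$tree
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  w <- tabulate(ledger$mutations$branch, nbins = nn)
  all_ids <- tree$tip.label
  agg <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2L]
    if (w[ch] == 0L) next
    below <- if (ch <= ntip) {
      tree$tip.label[ch]
    } else {
      tree$tip.label[phangorn::Descendants(tree, ch, "tips")[[1]]]
    }
    ka <- paste(sort(below), collapse = ",")
    kb <- paste(sort(setdiff(all_ids, below)), collapse = ",")
    key <- min(ka, kb)
    assign(key, (if (exists(key, agg)) get(key, agg) else 0L) + w[ch], agg)
  }
  edges <- unname(sort(vapply(ls(agg), function(k) paste0(k, "#", get(k, agg)), "")))
  list(partition = canon_partition(ledger$partition), edges = edges)
}

# random polymorphic test alignment via the coalescent simulator
random_fixture <- function(n, L, theta = 3, seed = 1) {
  repeat {
    sim <- simulate_demographic(n = n, theta0 = theta, L = L, seed = seed)
    gs <- group_stats(sim$alignment)
    if (!is.na(gs$D)) return(sim$alignment)
    seed <- seed + 1000L
  }
}
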