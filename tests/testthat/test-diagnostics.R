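consensus_of <- function(aln) {
  m <- unclass(aln)
  paste(apply(m, 2, function(col) names(which.max(table(col)))),
        collapse = "")
}

# a structured homoplasy-free simulation used across several tests
diag_sim <- function(seed = 101) {
  simulate_structured(
    list(clade_spec("sp1", label = "alpha", n = 4L, theta = 0, stem = 2L,
                    tip_subs = 1L, clade_label = "north"),
         clade_spec("sp2", label = "beta", n = 3L, theta = 0, stem = 5L,
                    tip_subs = 1L, clade_label = "north"),
         clade_spec("sp3", label = "gamma", n = 3L, theta = 0, stem = 5L,
                    tip_subs = 1L, clade_label = "south"),
         clade_spec("og", label = "out", n = 2L, theta = 0, stem = 2L,
                    clade_label = "outgroup", ingroup = FALSE)),
    "(((sp1,sp2)north,sp3)ingroup,og);", L = 300, seed = seed,
    internal_stems = c(north = 2L, ingroup = 3L))
}

test_that("planted stem diagnostics are recovered and retained", {
  sim <- diag_sim()
  map <- fitch_optimize(sim$tree, sim$alignment)
  tips <- sim$samples$sample_id[sim$samples$species_label == "beta"]
  d <- stem_diagnostics(map, sim$tree, tips, sim$alignment)
  expect_equal(nrow(d), 5L)
  expect_true(all(d$retained))
  planted <- sim$ledger$mutations
  stem_node <- attr(d, "clade_node")
  expect_setequal(d$site, planted$site[planted$branch == stem_node])
})

test_that("the two root-adjacent branches behave as one unrooted edge", {
  sim <- simulate_structured(
    list(clade_spec("a", n = 3L, theta = 0, stem = 0L, tip_subs = 1L),
         clade_spec("b", n = 3L, theta = 0, stem = 3L)),
    "(a,b);", L = 100, seed = 3)
  map <- fitch_optimize(sim$tree, sim$alignment)
  # clade a's stem is the shared root edge: clade b's three substitutions
  # are seen from a's side in reverse orientation (rooting cannot polarize
  # the root edge), at the same sites
  d_a <- stem_diagnostics(map, sim$tree, paste0("a_", 1:3), sim$alignment)
  d_b <- stem_diagnostics(map, sim$tree, paste0("b_", 1:3), sim$alignment)
  planted <- sim$ledger$mutations
  b_stem_sites <- planted$site[planted$branch ==
                               attr(d_b, "clade_node")]
  expect_setequal(d_a$site, b_stem_sites)
  expect_setequal(d_b$site, b_stem_sites)
  expect_equal(d_a$from[order(d_a$site)], d_b$to[order(d_b$site)])
  expect_equal(d_a$to[order(d_a$site)], d_b$from[order(d_b$site)])
})

test_that("non-monophyletic tip sets are rejected with guidance", {
  sim <- diag_sim()
  mixed <- c(paste0("sp1_", 1:2), "sp2_1")
  map <- fitch_optimize(sim$tree, sim$alignment)
  expect_error(stem_diagnostics(map, sim$tree, mixed, sim$alignment),
               "monophyletic")
  expect_error(stem_diagnostics(map, sim$tree, sim$tree$tip.label,
                                sim$alignment), "no stem branch")
})

test_that("exclusivity is classified globally, within-ingroup, and demoted by homoplasy", {
  sim <- diag_sim()
  m <- unclass(sim$alignment)
  ing <- sim$samples$sample_id[sim$samples$ingroup]
  alpha <- sim$samples$sample_id[sim$samples$species_label == "alpha"]
  gamma <- sim$samples$sample_id[sim$samples$species_label == "gamma"]

  # pick two invariant sites and plant controlled homoplasy there:
  # one repeat of alpha's derived state on an out-group tip (-> ingroup),
  # one repeat inside the in-group (-> combination)
  inv <- which(apply(m, 2, function(col) length(unique(col)) == 1L))
  s1 <- inv[1]
  s2 <- inv[2]
  base1 <- m[1, s1]
  to1 <- setdiff(c("A", "C", "G", "T"), base1)[1]
  m[alpha, s1] <- to1
  m["og_1", s1] <- to1
  base2 <- m[1, s2]
  to2 <- setdiff(c("A", "C", "G", "T"), base2)[1]
  m[alpha, s2] <- to2
  m[gamma[1], s2] <- to2
  aln <- dna_alignment(m)
  map <- fitch_optimize(sim$tree, aln)
  d <- stem_diagnostics(map, sim$tree, alpha, aln)

  excl <- setNames(
    vapply(seq_len(nrow(d)), function(i) {
      classify_exclusivity(map, d[i, ], ing, sim$tree)
    }, ""),
    as.character(d$site))
  planted <- sim$ledger$mutations
  orig <- as.character(planted$site[planted$branch ==
                                    attr(d, "clade_node")])
  expect_true(all(excl[orig] == "global"))
  expect_equal(unname(excl[as.character(s1)]), "ingroup")
  expect_equal(unname(excl[as.character(s2)]), "combination")
})

test_that("diagnose_all reports planted per-species and per-clade counts", {
  sim <- diag_sim()
  rep <- diagnose_all(sim$tree, sim$alignment, sim$samples)
  s <- rep$summary
  get <- function(lab) s[s$label == lab & s$type == "species", ]
  for (lab in c("alpha", "beta", "gamma")) {
    row <- get(lab)
    expect_equal(row$total, c(alpha = 2L, beta = 5L, gamma = 5L)[[lab]])
    expect_equal(row$global, row$total)  # homoplasy-free: all exclusive
    expect_equal(row$retained, row$total)
  }
  # the named clade above the (alpha, beta) sister pair shares 2 diagnostics
  north <- s[s$label == "north" & s$type == "clade", ]
  expect_equal(north$total, 2L)
  expect_equal(north$global, 2L)
  # the in-group stem is the root edge shared with the out-group clade: it
  # carries the 3 in-group substitutions plus the out-group's 2, reversed
  ingr <- s[s$label == "ingroup", ]
  expect_equal(ingr$total, 5L)
  expect_true(all(rep$details$ingroup$exclusivity == "global"))
  planted <- sim$ledger$mutations
  og_node <- attr(stem_diagnostics(rep$map, sim$tree, paste0("og_", 1:2),
                                   sim$alignment), "clade_node")
  ing_node <- attr(rep$details$ingroup, "clade_node")
  expect_setequal(rep$details$ingroup$site,
                  planted$site[planted$branch %in% c(og_node, ing_node)])
  # verdicts: diagnosed species delimited, empty stems are not
  expect_true(all(s$cbb_delimited[s$label %in% c("alpha", "beta", "gamma")]))
})

test_that("a species with an empty stem is not delimited by CBB", {
  sim <- simulate_structured(
    list(clade_spec("a", label = "spA", n = 3L, theta = 0, stem = 0L,
                    tip_subs = 1L),
         clade_spec("b", label = "spB", n = 3L, theta = 0, stem = 3L),
         clade_spec("c", label = "spC", n = 2L, theta = 0, stem = 2L)),
    "((a,b),c);", L = 150, seed = 12)
  rep <- diagnose_all(sim$tree, sim$alignment, sim$samples)
  row <- rep$summary[rep$summary$label == "spA" &
                     rep$summary$type == "species", ]
  expect_equal(row$total, 0L)
  expect_false(row$cbb_delimited)
})

test_that("relabeling tips permutes outputs without changing counts", {
  sim <- diag_sim()
  perm <- function(x) paste0("Z", x)
  aln2 <- sim$alignment
  rownames(aln2) <- perm(rownames(sim$alignment))
  tr2 <- sim$tree
  tr2$tip.label <- perm(tr2$tip.label)
  sm2 <- sim$samples
  sm2$sample_id <- perm(sm2$sample_id)
  r1 <- diagnose_all(sim$tree, sim$alignment, sim$samples)
  r2 <- diagnose_all(tr2, dna_alignment(unclass(aln2)), sample_table(sm2))
  cols <- c("label", "type", "total", "global", "ingroup_exclusive",
            "retained", "cbb_delimited")
  expect_equal(r1$summary[cols], r2$summary[cols])
})

test_that("require_exclusive and min_diagnostics tighten the verdict", {
  sim <- diag_sim()
  strict <- diagnose_all(sim$tree, sim$alignment, sim$samples,
                         min_diagnostics = 3L)
  row <- strict$summary[strict$summary$label == "alpha" &
                        strict$summary$type == "species", ]
  expect_false(row$cbb_delimited)  # alpha has only 2 diagnostics
  excl <- diagnose_all(sim$tree, sim$alignment, sim$samples,
                       require_exclusive = TRUE)
  expect_true(excl$summary$cbb_delimited[excl$summary$label == "beta" &
                                         excl$summary$type == "species"])
})

test_that("diagnostics carry reference positions when a map is supplied", {
  sim <- diag_sim()
  ref <- paste0("TTTTT", consensus_of(sim$alignment))
  pm <- map_positions(sim$alignment, ref)
  rep <- diagnose_all(sim$tree, sim$alignment, sim$samples, position_map = pm)
  d <- rep$details$beta
  expect_equal(as.integer(d$position), d$site + 5L)
})

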