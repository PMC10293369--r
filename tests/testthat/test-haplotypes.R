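test_that("strict collapsing groups identical sequences and orders by count", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGA"))
  h <- collapse_haplotypes(aln)
  expect_equal(length(h$haplotypes), 2L)
  expect_equal(vapply(h$haplotypes, `[[`, 1L, "count"), c(3L, 1L))
  expect_setequal(h$haplotypes[[1]]$members, c("a", "b", "c"))

  uniq <- dna_alignment(c(a = "ACGT", b = "ACGA", c = "ACTT", d = "GCGT"))
  expect_equal(length(collapse_haplotypes(uniq)$haplotypes), 4L)
})

test_that("strict collapsing is an equivalence relation on random data", {
  sim <- simulate_demographic(n = 20, theta0 = 2, L = 80, seed = 4)
  h <- collapse_haplotypes(sim$alignment)
  expect_equal(sum(vapply(h$haplotypes, `[[`, 1L, "count")), 20L)
  strs <- alignment_strings <- apply(unclass(sim$alignment), 1, paste, collapse = "")
  for (hp in h$haplotypes) {
    expect_equal(length(unique(strs[hp$members])), 1L)  # within: identical
  }
  # across haplotypes: representative sequences all distinct
  reps <- vapply(h$haplotypes, `[[`, "", "sequence")
  expect_equal(anyDuplicated(reps), 0L)
})

test_that("new records identical to a known haplotype join its node", {
  # mirrors adding six new field samples that share a known haplotype
  base <- simulate_structured(
    list(clade_spec("x", n = 3L, theta = 1, stem = 1L),
         clade_spec("y", n = 2L, theta = 0, stem = 2L)),
    "(x,y);", L = 200, seed = 9)
  known <- base$alignment["x_1", , drop = FALSE]
  new_seqs <- do.call(rbind, rep(list(unclass(known)), 6))
  rownames(new_seqs) <- paste0("new_", 1:6)
  aln <- dna_alignment(rbind(unclass(base$alignment), new_seqs))
  h <- collapse_haplotypes(aln)
  hit <- h$haplotypes[[h$index[["x_1"]]]]
  expect_true(all(paste0("new_", 1:6) %in% hit$members))
  expect_equal(hit$count, 6L + sum(apply(unclass(base$alignment), 1,
                                         paste, collapse = "") ==
                                   paste(unclass(known)[1, ], collapse = "")))
})

test_that("ignore-missing policy merges across gaps and N", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "AC-T", d = "ANGT",
                         e = "TTTT"))
  strict <- collapse_haplotypes(aln, "strict")
  expect_equal(length(strict$haplotypes), 4L)
  loose <- collapse_haplotypes(aln, "ignore-missing")
  expect_equal(length(loose$haplotypes), 2L)
  expect_setequal(loose$haplotypes[[1]]$members, c("a", "b", "c", "d"))
})

test_that("identical sequences give a single genealogy node", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  tr <- read_tree(text = "((a,b),(c,d));")
  g <- build_genealogy(tr, aln)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(g$nodes$size, 4L)
  expect_equal(nrow(g$edges), 0L)
})

test_that("two haplotypes differing at three sites give one weight-3 edge", {
  aln <- dna_alignment(c(h1a = "AAACGT", h1b = "AAACGT",
                         h2a = "TTTCGT", h2b = "TTTCGT"))
  tr <- read_tree(text = "((h1a,h1b),(h2a,h2b));")
  g <- build_genealogy(tr, aln)
  expect_equal(sort(g$nodes$size), c(2L, 2L))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 3L)
})

test_that("genealogy conserves record counts and the parsimony score", {
  for (seed in c(2, 31)) {
    sim <- simulate_structured(
      list(clade_spec("p", n = 6L, theta = 2, stem = 3L),
           clade_spec("q", n = 5L, theta = 1, stem = 2L),
           clade_spec("r", n = 4L, theta = 0, stem = 4L, tip_subs = 1L)),
      "((p,q),r);", L = 400, seed = seed)
    g <- build_genealogy(sim$tree, sim$alignment)
    expect_equal(sum(g$nodes$size), nrow(sim$alignment))
    expect_true(all(g$edges$weight >= 1L))
    # independent check of the score on the reduced tree via phangorn
    haps <- collapse_haplotypes(sim$alignment)
    reps <- vapply(haps$haplotypes, function(h) h$members[1], "")
    red <- ape::drop.tip(sim$tree, setdiff(sim$tree$tip.label, reps))
    pd <- phangorn::phyDat(tolower(unclass(sim$alignment[reps, ])),
                           type = "DNA")
    expect_equal(sum(g$edges$weight), phangorn::fitch(red, pd))
    # homoplasy-free: total substitutions equal the planted mutation count
    expect_equal(sum(g$edges$weight), nrow(sim$ledger$mutations))
  }
})

test_that("the genealogy equals the true mutational genealogy of a simulation", {
  for (seed in c(8, 21, 55)) {
    sim <- simulate_structured(
      list(clade_spec("p", n = 5L, theta = 1.5, stem = 3L),
           clade_spec("q", n = 4L, theta = 1, stem = 2L),
           clade_spec("o", n = 3L, theta = 0.5, stem = 2L, ingroup = FALSE)),
      "((p,q),o);", L = 500, seed = seed)
    g <- build_genealogy(sim$tree, sim$alignment)
    expect_equal(canon_genealogy(g), canon_from_ledger(sim$ledger))
  }
})

test_that("DOT export renders nodes and weighted edges", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGT"))
  tr <- read_tree(text = "(a,b);")
  g1 <- build_genealogy(tr, aln)
  dot1 <- export_genealogy(g1, "dot")
  expect_match(dot1, "\"H1\" \\[width=")
  expect_false(grepl("--", dot1))

  aln2 <- dna_alignment(c(a = "ACGT", b = "TCGT"))
  dot2 <- export_genealogy(build_genealogy(read_tree(text = "(a,b);"), aln2),
                           "dot")
  expect_match(dot2, '"H1" -- "H2" \\[label="1"\\]')
})

test_that("JSON export round-trips the genealogy exactly", {
  sim <- simulate_structured(
    list(clade_spec("p", n = 4L, theta = 2, stem = 2L),
         clade_spec("q", n = 4L, theta = 1, stem = 1L)),
    "(p,q);", L = 300, seed = 13)
  g <- build_genealogy(sim$tree, sim$alignment)
  g2 <- import_genealogy(export_genealogy(g, "json"))
  expect_identical(g$nodes, g2$nodes)
  expect_identical(g$edges, g2$edges)
  expect_identical(g$members, g2$members)
  expect_identical(g$n_sequences, g2$n_sequences)
})
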