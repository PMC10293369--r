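# hand-built fixture: three labels with controllable supports
# tree: ((a-clade)S_a, (b-clade)S_b) under an in-group node, plus out-group
hand_fixture <- function(s_a = "1.0", s_b = "1.0", s_ab = "1.0",
                         c_single_hap = FALSE) {
  txt <- sprintf(
    "(((a1:1,a2:1)%s:1,(b1:1,b2:1)%s:1)%s:1,(c1:1,c2:1)0.4:1);",
    s_a, s_b, s_ab)
  tree <- read_tree(text = txt)
  cseq <- if (c_single_hap) c(c1 = "TTTTTTAA", c2 = "TTTTTTAA") else
    c(c1 = "TTTTTTAA", c2 = "TTTTTTAT")
  aln <- dna_alignment(c(a1 = "AAAAAAAA", a2 = "AAAAAAAC",
                         b1 = "GGGGAAAA", b2 = "GGGGAAAC", cseq))
  samples <- sample_table(data.frame(
    sample_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    species_label = c("spA", "spA", "spB", "spB", "spC", "spC"),
    ingroup = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)))
  list(tree = tree, alignment = aln, samples = samples,
       haps = collapse_haplotypes(aln))
}

test_that("exclusivity assessment distinguishes the three statuses", {
  fx <- hand_fixture()
  ex <- assess_exclusivity(fx$tree, fx$samples, "spA", fx$haps)
  expect_equal(ex$status, "exclusive")
  expect_length(ex$partners, 0)

  # interdigitated labels: MRCA of the relabeled set spans the other label
  sm <- fx$samples
  sm$species_label[sm$sample_id %in% c("a1", "b1")] <- "spX"
  sm$species_label[sm$sample_id %in% c("a2", "b2")] <- "spY"
  ex2 <- assess_exclusivity(fx$tree, sm, "spX", fx$haps)
  expect_equal(ex2$status, "non-exclusive")
  expect_equal(ex2$partners, "spY")

  fx2 <- hand_fixture(c_single_hap = TRUE)
  ex3 <- assess_exclusivity(fx2$tree, fx2$samples, "spC", fx2$haps)
  expect_equal(ex3$status, "single-haplotype")
  expect_error(assess_exclusivity(fx$tree, fx$samples, "nope", fx$haps),
               "no samples")
})

test_that("WP applies own-support, sister-rescue and ambiguity rules", {
  # rule 1: exclusive clade with support 1.0
  fx <- hand_fixture(s_a = "1.0")
  wp <- wp_delimit(fx$tree, fx$samples, fx$haps)
  a <- wp[wp$label == "spA", ]
  expect_equal(a$decision, "delimited")
  expect_equal(a$rule, "own-support")

  # rule 2: own support 0.7 but a well-supported sister rescues
  fx <- hand_fixture(s_a = "0.7", s_b = "1.0")
  wp <- wp_delimit(fx$tree, fx$samples, fx$haps)
  a <- wp[wp$label == "spA", ]
  expect_equal(a$decision, "delimited")
  expect_equal(a$rule, "sister-rescue")
  expect_equal(a$own_support, 0.7)

  # rule 3: both below the threshold -> ambiguous
  fx <- hand_fixture(s_a = "0.7", s_b = "0.9")
  wp <- wp_delimit(fx$tree, fx$samples, fx$haps)
  expect_equal(wp$decision[wp$label == "spA"], "ambiguous")

  # the threshold comparison is strict: exactly 0.95 does not pass
  fx <- hand_fixture(s_a = "0.95", s_b = "0.9")
  wp <- wp_delimit(fx$tree, fx$samples, fx$haps)
  expect_equal(wp$decision[wp$label == "spA"], "ambiguous")
})

test_that("single-haplotype labels are delimited through their sister's support", {
  fx <- hand_fixture(c_single_hap = TRUE, s_ab = "1.0")
  wp <- wp_delimit(fx$tree, fx$samples, fx$haps)
  cc <- wp[wp$label == "spC", ]
  expect_equal(cc$exclusivity, "single-haplotype")
  expect_equal(cc$decision, "delimited")
  expect_equal(cc$rule, "single-haplotype")

  # without a supported sister the single haplotype stays ambiguous
  fx2 <- hand_fixture(c_single_hap = TRUE, s_ab = "0.5")
  wp2 <- wp_delimit(fx2$tree, fx2$samples, fx2$haps)
  expect_equal(wp2$decision[wp2$label == "spC"], "ambiguous")
})

test_that("interdigitated labels are not delimited and report their partners", {
  fx <- hand_fixture()
  sm <- fx$samples
  sm$species_label[sm$sample_id %in% c("a1", "b1")] <- "spX"
  sm$species_label[sm$sample_id %in% c("a2", "b2")] <- "spY"
  wp <- wp_delimit(fx$tree, sm, fx$haps)
  x <- wp[wp$label == "spX", ]
  expect_equal(x$decision, "not-delimited")
  expect_equal(x$lump_partners, "spY")
})

test_that("raising the support threshold never delimits new labels", {
  sim <- make_paper_analogue(seed = 33)
  haps <- collapse_haplotypes(sim$alignment)
  thresholds <- c(0.5, 0.69, 0.95, 0.999)
  prev <- NULL
  for (th in thresholds) {
    wp <- wp_delimit(sim$tree, sim$samples, haps, support_threshold = th)
    del <- wp$label[wp$decision == "delimited"]
    if (!is.null(prev)) expect_true(all(del %in% prev))
    prev <- del
  }
})

test_that("decisions are invariant to tip order and label renaming", {
  sim <- make_paper_analogue(seed = 5)
  haps <- collapse_haplotypes(sim$alignment)
  wp1 <- wp_delimit(sim$tree, sim$samples, haps)
  sm <- sim$samples[rev(seq_len(nrow(sim$samples))), ]
  wp2 <- wp_delimit(sim$tree, sm, haps)
  o1 <- wp1[order(wp1$label), c("label", "exclusivity", "decision", "rule")]
  o2 <- wp2[order(wp2$label), c("label", "exclusivity", "decision", "rule")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)

  sm3 <- sim$samples
  sm3$species_label <- paste0("X_", sm3$species_label)
  wp3 <- wp_delimit(sim$tree, sm3, haps)
  expect_equal(paste0("X_", wp1$label[order(wp1$label)]),
               wp3$label[order(wp3$label)])
  expect_equal(wp1$decision[order(wp1$label)], wp3$decision[order(wp3$label)])
})

test_that("consensus requires corroboration by both methods", {
  sim <- make_paper_analogue(seed = 2)
  haps <- collapse_haplotypes(sim$alignment)
  cbb <- diagnose_all(sim$tree, sim$alignment, sim$samples)
  wp <- wp_delimit(sim$tree, sim$samples, haps)
  dec <- consensus_delimit(wp, cbb)
  # WP delimited + CBB diagnostics -> valid
  expect_equal(dec$final[dec$label == "species_C"], "valid")
  expect_equal(attr(dec, "n_valid"), 3L)
  # the decisions-table invariant: valid iff WP delimited and CBB delimited
  expect_equal(dec$final == "valid",
               dec$wp_decision == "delimited" & dec$cbb_delimited)

  # WP delimited but an empty CBB stem -> unresolved
  sim0 <- make_paper_analogue(seed = 2, stem_override = 0L)
  cbb0 <- diagnose_all(sim0$tree, sim0$alignment, sim0$samples)
  wp0 <- wp_delimit(sim0$tree, sim0$samples,
                    collapse_haplotypes(sim0$alignment))
  dec0 <- consensus_delimit(wp0, cbb0)
  expect_equal(attr(dec0, "n_valid"), 0L)
  expect_true(all(dec0$final[dec0$label %in%
                             c("species_A", "species_B", "species_C")] ==
                  "unresolved"))
})

test_that("lowering all supports leaves nothing delimited", {
  sim <- make_paper_analogue(seed = 2, support_override = 0.5)
  haps <- collapse_haplotypes(sim$alignment)
  wp <- wp_delimit(sim$tree, sim$samples, haps)
  expect_true(all(wp$decision != "delimited"))
  dec <- consensus_delimit(wp, diagnose_all(sim$tree, sim$alignment,
                                            sim$samples))
  expect_equal(attr(dec, "n_valid"), 0L)
})

test_that("planted species are recovered and shuffled labels break exclusivity", {
  for (seed in c(4, 9)) {
    sim <- simulate_structured(
      list(clade_spec("u", label = "spU", n = 4L, theta = 1, stem = 2L),
           clade_spec("v", label = "spV", n = 4L, theta = 1, stem = 3L),
           clade_spec("w", label = "spW", n = 3L, theta = 0.5, stem = 2L),
           clade_spec("o", label = "spO", n = 2L, theta = 0, stem = 1L,
                      ingroup = FALSE)),
      "(((u,v),w)ing,o);", L = 400, seed = seed)
    haps <- collapse_haplotypes(sim$alignment)
    wp <- wp_delimit(sim$tree, sim$samples, haps)
    dec <- consensus_delimit(wp, diagnose_all(sim$tree, sim$alignment,
                                              sim$samples))
    expect_setequal(attr(dec, "valid_species"), c("spU", "spV", "spW"))

    # shuffle species labels across clades: everything becomes non-exclusive
    sm <- sim$samples
    ing <- sm$ingroup
    set.seed(seed)
    sm$species_label[ing] <- sample(sm$species_label[ing])
    wps <- wp_delimit(sim$tree, sm, haps)
    shuffled <- wps[wps$label %in% c("spU", "spV", "spW"), ]
    multi <- shuffled[shuffled$n_haplotypes > 1L, ]
    expect_true(all(multi$exclusivity == "non-exclusive"))
  }
})
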