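---
title: "Single-locus species delimitation with haplodelim: models, rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-locus species delimitation with haplodelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodelim)
```

## The problem

Single-locus phylogeographic studies of small species groups — for example
mitochondrial cytochrome *b* surveys of freshwater fishes — typically ask
two questions of the same alignment and tree: which of the a-priori named
species and populations deserve recognition as separate lineages, and what
demographic history (stability vs. recent expansion) shaped each major
clade. `haplodelim` implements that complete workflow for a fixed, rooted,
bifurcating input tree with node supports: it never infers the tree itself
(use any ML/Bayesian program for that) and never invents species — it only
evaluates the labels the investigator supplies.

Two delimitation criteria are combined:

* **WP (tree-based)** — a label is delimited when its haplotypes form an
  exclusive, well-supported clade, with two special cases described below.
* **CBB (character-based barcoding)** — a label is delimited when the
  branch subtending its clade carries diagnostic nucleotide substitutions
  under parsimony optimization.

Only labels corroborated by *both* methods are reported as valid; labels
whose haplotypes interdigitate with a valid species are flagged as possible
junior synonyms of that species.

## Haplotypes and the genealogy

`collapse_haplotypes()` merges identical sequences. The default `strict`
policy compares character-by-character and is a true equivalence relation.
The `ignore-missing` policy skips sites where either sequence has `-` or
`N`; because that relation is not transitive, strict haplotypes are merged
greedily in descending count order and an ambiguous merge (a haplotype
compatible with two clusters) is resolved toward the largest cluster with a
warning. This mirrors common haplotype-network practice; at the scale of a
single mitochondrial fragment the ambiguity is rare.

`build_genealogy()` converts the bifurcating tree into a haplotype
genealogy: the tree is reduced to one representative tip per haplotype,
per-site substitutions are optimized onto the reduced tree by the same
deterministic Fitch pass used for CBB (so the genealogy and the diagnostics
ledger can never disagree), zero-substitution edges are contracted, and
memberless degree-2 nodes — including the root — are spliced out with edge
weights summed. The result is the familiar network picture: node area
proportional to the number of sequence records, edge weight equal to the
number of substitutions, unrooted semantics. Its two structural invariants
are checked in the constructor: node sizes sum to the number of sequences,
and the sum of edge weights equals the parsimony score of the reduced tree.

## Demographic statistics

All population-genetic statistics treat gaps, `N` and IUPAC ambiguity codes
as missing and, by default, exclude a site for the whole group when any
sequence has missing data there (*complete deletion*, the DnaSP
convention). This is why a group's effective length $L_\mathrm{eff}$ is
typically a few sites short of the alignment length, and it is the reason
per-group published tables show slightly different "bp" values per group.
A `pairwise-deletion` policy is available; with it $L_\mathrm{eff}$ is the
mean number of comparable sites over pairs.

For a group of $n$ sequences with $S$ segregating sites and mean pairwise
difference $\bar k$:

* nucleotide diversity $\pi = \bar k / L_\mathrm{eff}$;
* Tajima's $D = (\bar k - S/a_1)\,/\,\sqrt{e_1 S + e_2 S(S-1)}$ with the
  standard constants $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$; reported as
  *undefined* when $S = 0$ (division by zero) or $n < 4$ (degenerate
  constants);
* Ramos-Onsins & Rozas $R_2 = \sqrt{\tfrac1n \sum_i (U_i - \bar k/2)^2}/S$,
  where $U_i$ counts sites at which sequence $i$ carries a state found in
  no other sequence of the group; undefined when $S = 0$;
* Harpending's raggedness $r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2$ over the
  observed mismatch classes $0..d$ with the terminal convention
  $x_{d+1} = 0$. Note that this convention has no leading $(x_0 - 0)^2$
  term: a distribution with all mass at class 0 gives $r = 1$, and a
  uniform distribution over $0..d$ gives $r = 1/(d+1)^2$. Other programs
  differ in this boundary convention; ours is fixed, documented here, and
  oracle-tested against the formula as written.

A group of one sequence reports every multi-sequence statistic as an
explicit *undefined* with a reason, rather than crashing — single-sequence
species are common in these datasets.

The mismatch distribution's expected curve comes in two flavours. Under
`constant` population size the closed form
$e_i = \hat\theta^i/(\hat\theta+1)^{i+1}$ with $\hat\theta = \bar k$ is
used. Under `expansion-sim` the curve is the mean of coalescent replicates
simulated by this package at supplied or moment-matched sudden-expansion
parameters, with the replicate count and seed recorded in the object. We
chose simulation over a closed-form sudden-expansion formula so that the
expected curve and the simulator can never drift apart; the closed form
can be added later behind the same interface.

## Parsimony optimization and CBB diagnostics

`fitch_optimize()` is a per-site Fitch pass over the fixed tree:
intersection if non-empty, else union (the union count is the site's Fitch
length), followed by a deterministic top-down resolution — the root takes
the alphabetically smallest member of its set (A < C < G < T), and each
child keeps its parent's state when possible, otherwise takes the smallest
member of its own set, recording a substitution event on that branch. The
classical ACCTRAN/DELTRAN choice is replaced by this fixed lexicographic
rule so that event placement is bit-reproducible; the per-site event count
always equals the site's Fitch length, which the test suite verifies
against exhaustive minimal-assignment search on trees of up to 10 leaves.
Gaps and `N` contribute the full state set (missing data never forces an
event); IUPAC codes contribute their own state sets; indels are not coded
as characters.

One consequence of optimizing on a *rooted* tree deserves emphasis: the
two branches incident to the root are a single edge of the underlying
unrooted tree, and parsimony cannot polarize events on it. A mutation that
truly belongs to one root-adjacent stem may be recorded on the other, with
its states swapped. `stem_diagnostics()` therefore treats the two
root-adjacent branches as one physical edge: for a clade whose MRCA is a
child of the root it also collects the sister branch's events in reversed
orientation. The practical corollary — visible in the test suite — is that
the in-group clade and its out-group sister report the same shared-edge
sites from opposite directions. Deeper clades are unaffected.

Each diagnostic is classified for exclusivity by comparing (site, derived
state) pairs across branches: `global` when no other branch anywhere
carries the same derived state at that site, `ingroup` when repeats occur
only outside the in-group subtree, `combination` otherwise. An event at
the same site with a *different* derived state does not break exclusivity
(the closest reading of "not occurring in any other branch"). The
`retained` flag records whether every clade member still shows the derived
state, making both "all stem events" and "retained-only" counting
available, since published diagnostic counts do not always say whether
later reversals were excluded. The CBB verdict requires at least
`min_diagnostics` retained diagnostics (default 1); `require_exclusive`
restricts the count to globally or in-group exclusive ones.

## The WP decision rules

`wp_delimit()` evaluates every label with node support normalized to
[0, 1] and a **strict** "higher than" threshold (default 0.95, the
posterior-probability convention; values exactly at the threshold do not
pass, and absent support never passes):

1. exclusive clade, own support above the threshold → delimited;
2. exclusive clade, own support at or below the threshold, sister-group
   support above it → delimited (*sister-rescue*);
3. exclusive, both below → ambiguous;
4. all sequences one haplotype → delimited iff the sister lineage's
   support passes; otherwise ambiguous;
5. haplotypes interdigitated with other labels → not delimited, with the
   partners recorded.

"Sister support" is the support of the node subtending the sister clade.
When the sister is a single tip there is no such node; the parent node's
support is used instead and the substitution is flagged in the output.
Single-haplotype status is checked first, so a label whose sequences are
all identical is routed through rule 4 even when its tips also form an
exclusive clade.

`consensus_delimit()` marks a label valid only when WP delimits it *and*
CBB found diagnostics. WP-ambiguous labels propagate as `unresolved`
rather than `not-delimited` — ambiguity reflects missing support, not
positive evidence for lumping. A non-exclusive label becomes a possible
junior synonym of the valid label among its partners (the one with the
smallest clade when several qualify). Out-group labels receive verdicts
but are excluded from the valid-species count.

## The synthetic-data generator

`simulate_structured()` emulates the data such a study analyzes: a rooted
binary topology over clade instances; within each clade a neutral
coalescent genealogy (waiting times exponential at rate $k(k-1)/2$ in
coalescent units — no effective-size bookkeeping, since only relative
signatures matter); within-clade mutations Poisson with mean (branch
length × θ/2); and exactly `stem` planted diagnostic substitutions on each
clade's stem, at sites disjoint from all other mutations, so that in the
default homoplasy-free (infinite-sites) mode the ledger exactly predicts
every diagnostic, its exclusivity, the haplotype partition and the
genealogy. All draws come from one seeded stream in a documented order,
making outputs byte-identical across runs. What the generator does *not*
emulate: recombination, migration, selection, rate heterogeneity, indels,
and homoplasy under the default mode — so a passing ledger-recovery test
shows the optimization machinery is exact on clean signal, not that real
mitochondrial data are free of homoplasy.

`simulate_demographic()` adds a single-population model with an optional
instantaneous size change looking back (coalescent rate multiplied by $f$
beyond time $t$), used both for the expansion expected curves and for the
signature checks below.

`make_paper_analogue()` is a canned configuration shaped like a published
small-species-group study: six in-group labels, of which three are good
species carrying planted stems of 2, 5 and 5 substitutions, three are
interdigitated synonym analogues, two out-group labels, three
substitutions on the in-group stem, and supports of 1.0 everywhere except
the first species' own node (0.7) whose sister branch is fully supported.
Running the pipeline on it yields exactly 3 valid species and 3 synonym
candidates while exercising the sister-rescue and single-haplotype rules.

```{r analogue}
sim <- make_paper_analogue(seed = 1)
res <- run_pipeline(sim$alignment, sim$tree, sim$samples,
                    out_dir = file.path(tempdir(), "demo"))
attr(res$decisions, "valid_species")
subset(as.data.frame(res$wp), label %in% c("species_A", "species_B"),
       select = c(label, exclusivity, own_support, sister_support, rule))
```

## Numerical and design choices

* **Coordinates** are 1-based closed intervals throughout: diagnostic
  positions are reported to humans, not sliced.
* **Reference numbering** uses global pairwise alignment of the alignment
  consensus against the reference with fixed scores (match 1, mismatch −1,
  linear gap −2; `N` scores 0); columns opposite reference gaps are
  reported as `aln:<column>`. A reference shorter than half the alignment
  warns; an alignment below 40% identity on compared columns errors.
* **Polytomies** are rejected by default; an explicit flag resolves them
  deterministically (input order), since both WP and CBB need a binary
  tree. Support absent on a node is treated as 0 in threshold tests —
  absence must never pass.
* **Support scale** is auto-detected (any value > 1 means percent) and
  normalization is idempotent.
* **Simulation sizes** used by the checks: formula oracles on 20 fixtures
  with n ≤ 15, L ≤ 200; exhaustive parsimony on trees of 4–10 leaves;
  ledger recovery on 10 seeds of a four-clade configuration; constant-size
  signatures at n = 25, θ = 5 over 500 replicates (|mean D| < 0.2, mean S
  within 10% of θ·a₁); expansion signatures at n = 25, θ₀ = 50, t = 0.1,
  f = 100 over 200 replicates, with t and θ₀ chosen so the expected
  pairwise difference θ₀(t + 1/f) ≈ 5.5 falls in the unimodal-peak range
  typical of recently expanded mitochondrial clades.

## Known limitations

* The tree is taken as given: uncertainty in the topology beyond node
  support is not propagated.
* CBB diagnostics on a root-adjacent stem cannot be polarized (see above);
  with at least one out-group clade below the root's other child this
  never affects in-group species.
* Coalescent p-values for D and R2 (and Fu's Fs) are not computed; the
  statistics are reported for comparison against published values and for
  qualitative expansion signatures.
* `ignore-missing` haplotype merging is order-dependent in pathological
  cases; the greedy resolution is deterministic and warned about.
* Discovery-mode delimitation (inventing unlabeled species) is out of
  scope by design: the unit of analysis is the a-priori label.
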