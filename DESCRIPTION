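Package: haplodelim
Title: Tree-Based and Character-Based Species Delimitation from
    Single-Locus Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for single-locus phylogeographic analysis and species
    delimitation over a-priori species labels. Collapses aligned sequences
    into haplotypes, transforms a rooted bifurcating tree into a haplotype
    genealogy (node size = number of sequence records, edge weight = number
    of substitutions), computes mismatch distributions and the demographic
    statistics Tajima's D, Ramos-Onsins and Rozas's R2 and Harpending's
    raggedness, optimizes nucleotide substitutions onto a fixed topology by
    Fitch parsimony to extract character-based barcoding (CBB) diagnostics
    with exclusivity classification, applies the Wiens-Penkrot (WP)
    tree-based delimitation protocol with support-threshold, sister-rescue
    and single-haplotype rules, and reports the WP/CBB consensus. A
    coalescent simulator with planted diagnostic substitutions and optional
    sudden population expansion generates fully ledgered test fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
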