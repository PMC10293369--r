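#' Run the full delimitation pipeline
#'
#' Orchestrates every stage end-to-end: read inputs, collapse haplotypes,
#' per-group demographic statistics and mismatch distributions, haplotype
#' genealogy (DOT + JSON), parsimony optimization and CBB diagnostics, WP
#' delimitation, and the WP/CBB consensus, writing a report bundle with a
#' provenance MANIFEST. Groups for the demographic statistics are the whole
#' dataset ("All"), every a-priori species label and every named clade
#' label, mirroring the per-group tables of single-locus phylogeographic
#' studies.
#'
#' Any stage failure aborts with a stage-named message; outputs of completed
#' stages are retained and listed in `MANIFEST.json`.
#'
#' @param alignment a [dna_alignment] or path to a FASTA file.
#' @param tree a `phylo` (from [read_tree()]) or path to a Newick file.
#' @param samples a sample table or path to a TSV file.
#' @param out_dir output directory for the report bundle.
#' @param reference optional reference sequence (or FASTA path) for
#'   position numbering.
#' @param support_threshold WP support threshold (strict `>`).
#' @param site_policy site exclusion policy for the statistics.
#' @param haplotype_policy haplotype comparison policy.
#' @param min_diagnostics,require_exclusive CBB verdict settings.
#' @param mismatch_model expected-curve model for mismatch distributions.
#' @param seed seed for simulation-based expected curves.
#' @return invisibly, a list with `haplotypes`, `stats`, `mismatch`,
#'   `genealogy`, `cbb`, `wp`, `decisions`, `out_dir`.
#' @export
run_pipeline <- function(alignment, tree, samples, out_dir,
                         reference = NULL,
                         support_threshold = 0.95,
                         site_policy = "complete-deletion",
                         haplotype_policy = "strict",
                         min_diagnostics = 1L,
                         require_exclusive = FALSE,
                         mismatch_model = "constant",
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  completed <- character(0)
  inputs <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      write_manifest(out_dir, completed, inputs, support_threshold,
                     site_policy, haplotype_policy, min_diagnostics,
                     require_exclusive, mismatch_model, seed,
                     failed = name, error = conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    completed <<- c(completed, name)
    res
  }

  read_in <- stage("read-inputs", {
    if (is.character(alignment) && !inherits(alignment, "dna_alignment")) {
      inputs$alignment <- unname(tools::md5sum(alignment))
      alignment <- read_alignment(alignment)
    }
    if (is.character(tree)) {
      inputs$tree <- unname(tools::md5sum(tree))
      tree <- read_tree(tree)
    }
    if (is.character(samples)) {
      inputs$samples <- unname(tools::md5sum(samples))
      samples <- read_samples(samples)
    } else {
      samples <- sample_table(samples)
    }
    miss <- setdiff(tree$tip.label, samples$sample_id)
    if (length(miss)) stop("samples table lacks: ", paste(miss, collapse = ", "))
    pm <- NULL
    if (!is.null(reference)) {
      if (is.character(reference) && file.exists(reference)) {
        ref_aln <- read_alignment(reference)
        reference <- stats::setNames(alignment_strings(ref_aln)[1L],
                                     rownames(ref_aln)[1L])
      }
      pm <- map_positions(alignment, reference)
    }
    list(alignment = alignment, tree = tree, samples = samples, pm = pm)
  })
  alignment <- read_in$alignment
  tree <- read_in$tree
  samples <- read_in$samples
  pm <- read_in$pm

  haps <- stage("haplotypes", collapse_haplotypes(alignment, haplotype_policy))

  groups <- c(list(All = samples$sample_id),
              split(samples$sample_id, samples$species_label),
              split(samples$sample_id,
                    factor(samples$clade_label))["unassigned" !=
                      sort(unique(samples$clade_label))])
  groups <- groups[!duplicated(names(groups))]

  stats_list <- stage("popgen-stats", {
    out <- lapply(groups, function(ids) {
      group_stats(alignment[ids, , drop = FALSE], site_policy)
    })
    write_group_stats(out, file.path(out_dir, "group_stats.tsv"))
    out
  })

  mismatches <- stage("mismatch", {
    out <- list()
    for (g in names(groups)) {
      if (length(groups[[g]]) < 2L) next
      mm <- mismatch_distribution(alignment[groups[[g]], , drop = FALSE],
                                  model = mismatch_model,
                                  site_policy = site_policy, seed = seed)
      utils::write.table(
        as.data.frame(mm),
        file.path(out_dir, paste0("mismatch_", gsub("[^A-Za-z0-9_.-]", "_", g),
                                  ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      out[[g]] <- mm
    }
    out
  })

  genealogy <- stage("genealogy", {
    g <- build_genealogy(tree, alignment, haplotypes = haps)
    writeLines(export_genealogy(g, "dot", samples),
               file.path(out_dir, "genealogy.dot"))
    writeLines(export_genealogy(g, "json"),
               file.path(out_dir, "genealogy.json"))
    g
  })

  cbb <- stage("cbb-diagnostics", {
    rep <- diagnose_all(tree, alignment, samples, position_map = pm,
                        min_diagnostics = min_diagnostics,
                        require_exclusive = require_exclusive)
    write_cbb_report(rep, file.path(out_dir, "diagnostics.tsv"))
    rep
  })

  wp <- stage("wp-delimitation",
              wp_delimit(tree, samples, haplotypes = haps,
                         support_threshold = support_threshold))

  decisions <- stage("consensus", {
    d <- consensus_delimit(wp, cbb)
    utils::write.table(as.data.frame(d), file.path(out_dir, "decisions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d
  })

  stage("summary", {
    writeLines(summary_markdown(decisions, cbb, stats_list, haps),
               file.path(out_dir, "summary.md"))
  })
  write_manifest(out_dir, completed, inputs, support_threshold, site_policy,
                 haplotype_policy, min_diagnostics, require_exclusive,
                 mismatch_model, seed)

  invisible(list(haplotypes = haps, stats = stats_list,
                 mismatch = mismatches, genealogy = genealogy, cbb = cbb,
                 wp = wp, decisions = decisions, out_dir = out_dir))
}

#' @noRd
write_manifest <- function(out_dir, completed, inputs, support_threshold,
                           site_policy, haplotype_policy, min_diagnostics,
                           require_exclusive, mismatch_model, seed,
                           failed = NULL, error = NULL) {
  man <- list(
    tool = "haplodelim",
    version = as.character(utils::packageVersion("haplodelim")),
    seed = seed,
    config = list(support_threshold = support_threshold,
                  site_policy = site_policy,
                  haplotype_policy = haplotype_policy,
                  min_diagnostics = min_diagnostics,
                  require_exclusive = require_exclusive,
                  mismatch_model = mismatch_model),
    input_md5 = inputs,
    completed_stages = as.list(completed)
  )
  if (!is.null(failed)) {
    man$failed_stage <- failed
    man$error <- error
  }
  jsonlite::write_json(man, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' @noRd
summary_markdown <- function(decisions, cbb, stats_list, haps) {
  vs <- attr(decisions, "valid_species")
  syn <- decisions[grepl("^possible-junior-synonym-of", decisions$final), ]
  lines <- c(
    "# Species delimitation summary", "",
    sprintf("- Sequences: %d in %d haplotypes", haps$n,
            length(haps$haplotypes)),
    sprintf("- Valid in-group species (WP and CBB concordant): %d (%s)",
            length(vs), paste(vs, collapse = ", ")),
    ""
  )
  if (nrow(syn)) {
    lines <- c(lines, "## Possible junior synonyms", "",
               sprintf("- %s: %s", syn$label, syn$final), "")
  }
  cs <- cbb$summary[cbb$summary$applicable, , drop = FALSE]
  lines <- c(lines, "## Diagnostic substitutions per clade", "",
             sprintf("- %s (%s): %d diagnostics (%d globally exclusive, %d in-group exclusive, %d retained)",
                     cs$label, cs$type, cs$total, cs$global,
                     cs$ingroup_exclusive, cs$retained),
             "", "## Group statistics", "",
             sprintf("- %s: n=%d, pi=%s, D=%s", names(stats_list),
                     vapply(stats_list, `[[`, 1L, "n"),
                     vapply(stats_list, function(s)
                       ifelse(is.na(s$pi), "undefined", sprintf("%.4f", s$pi)), ""),
                     vapply(stats_list, function(s)
                       ifelse(is.na(s$D), "undefined", sprintf("%.4f", s$D)), "")))
  lines
}
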