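#' Diagnostic substitutions on a clade's stem branch
#'
#' Character-based barcoding (CBB) diagnoses a clade by the substitution
#' events that parsimony optimization places on the branch subtending the
#' clade's most recent common ancestor. Each diagnostic is annotated with
#' `retained`: whether every member of the clade still shows the derived
#' state at that site (i.e. no reversal within the clade; tips with missing
#' or compatible ambiguous states count as showing it).
#'
#' The two branches incident to the root are a single edge of the
#' underlying unrooted tree, so rooted optimization cannot orient events
#' between them: for a clade whose MRCA is a child of the root, events
#' recorded on the root's other child branch are also collected, with their
#' from/to states swapped.
#'
#' @param map a [fitch_optimize()] result.
#' @param tree the tree the map was computed on.
#' @param clade_tips character vector of sample ids; must form a clade.
#' @param alignment the [dna_alignment] used for the optimization.
#' @param position_map optional [map_positions()] result for
#'   reference-numbered positions.
#' @return a `diagnostic_set` data.frame with columns `site`, `position`,
#'   `from`, `to`, `retained` and attributes `clade_node`, `n_tips`.
#' @export
stem_diagnostics <- function(map, tree, clade_tips, alignment,
                             position_map = NULL) {
  stopifnot(inherits(map, "substitution_map"))
  node <- span_node(tree, clade_tips)
  below <- tips_below(tree, node)
  if (!setequal(below, clade_tips)) {
    stop("tip set is not monophyletic (clade also contains: ",
         paste(utils::head(setdiff(below, clade_tips), 5L), collapse = ", "),
         "); non-exclusive labels are handled by the WP method, not CBB")
  }
  if (node == root_node(tree)) {
    stop("clade spans the whole tree: it has no stem branch")
  }
  ev <- map$events[map$events$branch == node, , drop = FALSE]
  if (parent_of(tree, node) == root_node(tree)) {
    sib <- sister_of(tree, node)
    flip <- map$events[map$events$branch == sib, , drop = FALSE]
    if (nrow(flip)) {
      flip <- data.frame(site = flip$site, branch = flip$branch,
                         branch_label = flip$branch_label,
                         from = flip$to, to = flip$from,
                         stringsAsFactors = FALSE)
      ev <- rbind(ev, flip)
    }
  }
  ev <- ev[order(ev$site), , drop = FALSE]
  retained <- vapply(seq_len(nrow(ev)), function(i) {
    chars <- unclass(alignment)[clade_tips, ev$site[i]]
    all(bitwAnd(char_bits(chars), IUPAC_BITS[[ev$to[i]]]) > 0L)
  }, logical(1L))
  out <- data.frame(site = ev$site,
                    position = format_position(position_map, ev$site),
                    from = ev$from, to = ev$to,
                    branch = ev$branch,
                    retained = if (nrow(ev)) retained else logical(0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "clade_node") <- node
  attr(out, "n_tips") <- length(clade_tips)
  class(out) <- c("diagnostic_set", "data.frame")
  out
}

#' Classify the exclusivity of a substitution event
#'
#' An event is `global` when no other branch anywhere in the tree carries
#' an event at the same site with the same derived state ("not occurring in
#' any other branch"); `ingroup` when it is not global but no such event
#' occurs on a branch within the in-group subtree (exclusive within the
#' in-group); `combination` otherwise. An event at the same site with a
#' different derived state does not break exclusivity.
#'
#' @param map a [fitch_optimize()] result.
#' @param event a single row of a [stem_diagnostics()] result (or of
#'   `map$events`): needs `site`, `to`, `branch`.
#' @param ingroup_tips sample ids of the in-group.
#' @param tree the tree the map was computed on.
#' @return `"global"`, `"ingroup"` or `"combination"`.
#' @export
classify_exclusivity <- function(map, event, ingroup_tips, tree) {
  same <- map$events[map$events$site == event$site &
                     map$events$to == event$to &
                     map$events$branch != event$branch, , drop = FALSE]
  if (nrow(same) == 0L) return("global")
  in_node <- span_node(tree, ingroup_tips)
  in_nodes <- nodes_below(tree, in_node)
  if (any(same$branch %in% in_nodes)) "combination" else "ingroup"
}

#' CBB diagnostics for every a-priori species and named clade
#'
#' Runs [fitch_optimize()] (unless a map is supplied) and reports, for every
#' a-priori species label and every named clade label whose tips are
#' monophyletic, the stem-branch diagnostics with exclusivity and retention
#' counts. The CBB verdict delimits a label when it has at least
#' `min_diagnostics` retained diagnostics (only exclusive ones, i.e. global
#' or in-group-exclusive, when `require_exclusive = TRUE`). Non-monophyletic
#' labels are reported as not applicable.
#'
#' @param tree rooted binary `phylo` over all samples.
#' @param alignment a [dna_alignment].
#' @param samples a sample table (see [read_samples()]).
#' @param position_map optional [map_positions()] result.
#' @param min_diagnostics minimum retained diagnostics to delimit.
#' @param require_exclusive count only global/ingroup-exclusive diagnostics.
#' @param map optional precomputed [fitch_optimize()] result.
#' @return a `cbb_report`: list with `summary` (one row per unit: `label`,
#'   `type`, `n_tips`, `applicable`, `total`, `global`, `ingroup_exclusive`,
#'   `retained`, `cbb_delimited`, `note`), `details` (named list of
#'   diagnostic sets with an `exclusivity` column) and `map`.
#' @export
diagnose_all <- function(tree, alignment, samples, position_map = NULL,
                         min_diagnostics = 1L, require_exclusive = FALSE,
                         map = NULL) {
  map <- map %||% fitch_optimize(tree, alignment)
  ingroup_tips <- samples$sample_id[samples$ingroup]
  units <- data.frame(label = unique(samples$species_label), type = "species",
                      stringsAsFactors = FALSE)
  clades <- setdiff(unique(samples$clade_label), "unassigned")
  if (length(clades)) {
    units <- rbind(units, data.frame(label = clades, type = "clade",
                                     stringsAsFactors = FALSE))
  }
  if (length(ingroup_tips) && length(ingroup_tips) < nrow(samples)) {
    units <- rbind(units, data.frame(label = "ingroup", type = "clade",
                                     stringsAsFactors = FALSE))
  }

  details <- list()
  rows <- lapply(seq_len(nrow(units)), function(k) {
    lab <- units$label[k]
    tips <- if (units$type[k] == "species") {
      samples$sample_id[samples$species_label == lab]
    } else if (lab == "ingroup") {
      ingroup_tips
    } else {
      samples$sample_id[samples$clade_label == lab]
    }
    base <- data.frame(label = lab, type = units$type[k],
                       n_tips = length(tips), applicable = FALSE,
                       total = 0L, global = 0L, ingroup_exclusive = 0L,
                       retained = 0L, cbb_delimited = FALSE, note = "",
                       stringsAsFactors = FALSE)
    diag <- tryCatch(
      stem_diagnostics(map, tree, tips, alignment, position_map),
      error = function(e) conditionMessage(e)
    )
    if (is.character(diag)) {
      base$note <- if (grepl("monophyletic", diag)) {
        "CBB not applicable - non-exclusive"
      } else {
        diag
      }
      return(base)
    }
    excl <- vapply(seq_len(nrow(diag)), function(i) {
      classify_exclusivity(map, diag[i, ], ingroup_tips, tree)
    }, character(1L))
    diag$exclusivity <- if (nrow(diag)) excl else character(0)
    details[[lab]] <<- diag
    usable <- diag$retained &
      (!require_exclusive | diag$exclusivity %in% c("global", "ingroup"))
    base$applicable <- TRUE
    base$total <- nrow(diag)
    base$global <- sum(diag$exclusivity == "global")
    base$ingroup_exclusive <- sum(diag$exclusivity == "ingroup")
    base$retained <- sum(diag$retained)
    base$cbb_delimited <- sum(usable) >= min_diagnostics
    base
  })
  structure(list(summary = do.call(rbind, rows), details = details,
                 map = map),
            class = "cbb_report")
}

#' @export
print.cbb_report <- function(x, ...) {
  cat("CBB diagnostics report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a CBB report to TSV (with a JSON sidecar of the substitution map)
#'
#' @param report a `cbb_report`.
#' @param path output TSV path for the per-event table; the summary goes to
#'   `<path>` with `.summary.tsv`, and the substitution map to a `.json`
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_cbb_report <- function(report, path) {
  ev <- do.call(rbind, lapply(names(report$details), function(lab) {
    d <- report$details[[lab]]
    if (!nrow(d)) return(NULL)
    data.frame(clade = lab, site = d$site, position = d$position,
               from = d$from, to = d$to, exclusivity = d$exclusivity,
               retained = d$retained, stringsAsFactors = FALSE)
  }))
  if (is.null(ev)) {
    ev <- data.frame(clade = character(0), site = integer(0),
                     position = character(0), from = character(0),
                     to = character(0), exclusivity = character(0),
                     retained = logical(0))
  }
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary,
                     paste0(tools::file_path_sans_ext(path), ".summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(events = report$map$events,
         site_lengths = report$map$site_lengths,
         score = report$map$score),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
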