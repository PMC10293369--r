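#' Haplotype exclusivity of an a-priori species label
#'
#' Classifies a label as `single-haplotype` when all of its sequences
#' collapse to one haplotype; `exclusive` when its tips form a clade
#' containing no other label's tips; otherwise `non-exclusive`, reporting
#' the other labels found inside the MRCA of the label's tips (the
#' interdigitated partners).
#'
#' @param tree rooted binary `phylo`.
#' @param samples a sample table.
#' @param label a species label present in `samples`.
#' @param haplotypes a [collapse_haplotypes()] result over the same samples.
#' @return list with `status`, `partners` (character, empty unless
#'   non-exclusive), `node` (MRCA node id, or tip id for a single tip).
#' @export
assess_exclusivity <- function(tree, samples, label, haplotypes) {
  tips <- samples$sample_id[samples$species_label == label]
  if (length(tips) == 0L) stop("no samples carry label '", label, "'")
  node <- span_node(tree, tips)
  if (length(unique(haplotypes$index[tips])) == 1L) {
    return(list(status = "single-haplotype", partners = character(0),
                node = node))
  }
  below <- tips_below(tree, node)
  others <- setdiff(below, tips)
  if (length(others) == 0L) {
    list(status = "exclusive", partners = character(0), node = node)
  } else {
    partners <- sort(unique(samples$species_label[
      match(others, samples$sample_id)]))
    list(status = "non-exclusive", partners = partners, node = node)
  }
}

#' Wiens-Penkrot tree-based delimitation
#'
#' Applies the WP decision rules to every a-priori species label, using
#' node support on the unit scale and a strict "higher than" threshold
#' comparison (default 0.95, the posterior-probability convention):
#' \enumerate{
#'   \item exclusive and own MRCA support above the threshold: delimited;
#'   \item exclusive, own support at or below the threshold, but
#'     sister-group support above it: delimited (sister-rescue);
#'   \item exclusive with both below: ambiguous;
#'   \item single-haplotype with sister-lineage support above the
#'     threshold: delimited; otherwise ambiguous;
#'   \item non-exclusive: not delimited, with the interdigitated labels
#'     reported as lump partners (candidate synonyms).
#' }
#' "Sister support" is the support of the node subtending the sister clade;
#' when the sister is a single tip (which has no node of its own) the parent
#' node's support is used instead, and the substitution is noted. Absent
#' support never passes the threshold.
#'
#' @param tree rooted binary `phylo` with supports (see [read_tree()]).
#' @param samples a sample table.
#' @param haplotypes a [collapse_haplotypes()] result; computed from
#'   `alignment` when NULL.
#' @param support_threshold support threshold (strict `>`), default 0.95.
#' @param alignment alignment used when `haplotypes` is NULL.
#' @return a `wp_verdicts` data.frame: `label`, `ingroup`, `n_tips`,
#'   `n_haplotypes`, `exclusivity`, `own_support`, `sister_support`,
#'   `sister_is_tip`, `decision`, `rule`, `lump_partners` (comma-separated).
#' @export
wp_delimit <- function(tree, samples, haplotypes = NULL,
                       support_threshold = 0.95, alignment = NULL) {
  if (is.null(haplotypes)) {
    if (is.null(alignment)) stop("supply either haplotypes or alignment")
    haplotypes <- collapse_haplotypes(alignment)
  }
  if (support_threshold <= 0 || support_threshold > 1) {
    stop("support_threshold must be in (0, 1]")
  }
  labels <- unique(samples$species_label)
  passes <- function(s) !is.na(s) && s > support_threshold
  rows <- lapply(labels, function(lab) {
    tips <- samples$sample_id[samples$species_label == lab]
    ex <- assess_exclusivity(tree, samples, lab, haplotypes)
    own <- support_at(tree, ex$node)
    sib <- sister_of(tree, ex$node)
    sister_is_tip <- FALSE
    sister <- NA_real_
    if (!is.na(sib)) {
      if (sib <= length(tree$tip.label)) {
        sister_is_tip <- TRUE
        sister <- support_at(tree, parent_of(tree, ex$node))
      } else {
        sister <- support_at(tree, sib)
      }
    }
    decision <- "ambiguous"
    rule <- ""
    if (ex$status == "non-exclusive") {
      decision <- "not-delimited"
      rule <- "non-exclusive"
    } else if (ex$status == "single-haplotype") {
      if (passes(sister)) {
        decision <- "delimited"
        rule <- "single-haplotype"
      } else {
        rule <- "single-haplotype-unsupported"
      }
    } else {
      if (passes(own)) {
        decision <- "delimited"
        rule <- "own-support"
      } else if (passes(sister)) {
        decision <- "delimited"
        rule <- "sister-rescue"
      } else {
        rule <- "unsupported"
      }
    }
    data.frame(label = lab,
               ingroup = samples$ingroup[match(tips[1L], samples$sample_id)],
               n_tips = length(tips),
               n_haplotypes = length(unique(haplotypes$index[tips])),
               exclusivity = ex$status,
               own_support = own, sister_support = sister,
               sister_is_tip = sister_is_tip,
               decision = decision, rule = rule,
               lump_partners = paste(ex$partners, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "support_threshold") <- support_threshold
  class(out) <- c("wp_verdicts", "data.frame")
  out
}

#' Consensus of WP and CBB delimitation
#'
#' A species label is `valid` only when corroborated by both methods: the
#' WP decision is delimited and CBB found enough diagnostics. Non-exclusive
#' labels become possible junior synonyms of the valid label they
#' interdigitate with (the one with the smallest clade when several
#' qualify); everything else is `unresolved` (including WP-ambiguous
#' labels). Out-group labels receive decisions but are excluded from the
#' valid-species summary.
#'
#' @param wp a [wp_delimit()] result.
#' @param cbb a [diagnose_all()] result.
#' @return a `delimitation_decisions` data.frame with one row per label and
#'   attributes `valid_species` (in-group labels valid under both methods)
#'   and `n_valid`.
#' @export
consensus_delimit <- function(wp, cbb) {
  cs <- cbb$summary[cbb$summary$type == "species", , drop = FALSE]
  cbb_del <- stats::setNames(cs$cbb_delimited, cs$label)
  cbb_tot <- stats::setNames(cs$total, cs$label)
  cbb_exc <- stats::setNames(cs$global + cs$ingroup_exclusive, cs$label)

  valid <- wp$label[wp$decision == "delimited" &
                    cbb_del[wp$label] %in% TRUE]
  size_of <- stats::setNames(wp$n_tips, wp$label)

  final <- vapply(seq_len(nrow(wp)), function(i) {
    lab <- wp$label[i]
    if (lab %in% valid) return("valid")
    if (wp$exclusivity[i] == "non-exclusive") {
      partners <- strsplit(wp$lump_partners[i], ",", fixed = TRUE)[[1L]]
      cand <- intersect(partners, valid)
      if (length(cand)) {
        cand <- cand[order(size_of[cand])]
        return(paste0("possible-junior-synonym-of ", cand[1L]))
      }
    }
    "unresolved"
  }, character(1L))

  out <- data.frame(label = wp$label, ingroup = wp$ingroup,
                    exclusivity = wp$exclusivity,
                    own_support = wp$own_support,
                    sister_support = wp$sister_support,
                    wp_decision = wp$decision, wp_rule = wp$rule,
                    cbb_delimited = unname(cbb_del[wp$label] %in% TRUE),
                    cbb_total = unname(ifelse(is.na(cbb_tot[wp$label]), 0L,
                                              cbb_tot[wp$label])),
                    cbb_exclusive = unname(ifelse(is.na(cbb_exc[wp$label]), 0L,
                                                  cbb_exc[wp$label])),
                    final = final,
                    lump_partners = wp$lump_partners,
                    stringsAsFactors = FALSE)
  vs <- out$label[out$final == "valid" & out$ingroup]
  attr(out, "valid_species") <- vs
  attr(out, "n_valid") <- length(vs)
  class(out) <- c("delimitation_decisions", "data.frame")
  out
}

#' @export
print.delimitation_decisions <- function(x, ...) {
  vs <- attr(x, "valid_species") %||% x$label[x$final == "valid" & x$ingroup]
  cat("Delimitation decisions (", length(vs),
      " valid in-group species: ", paste(vs, collapse = ", "), ")\n",
      sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
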