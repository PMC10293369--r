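#' Map alignment columns to reference coordinates
#'
#' Diagnostic positions are conventionally reported in the coordinate system
#' of a complete reference sequence (for mitochondrial barcoding, a complete
#' mitogenome). This function globally aligns the majority-rule consensus of
#' the alignment against the reference (match 1, mismatch -1, linear gap -2;
#' `N` scores 0 against anything) and returns, for every alignment column,
#' the 1-based reference position, or `NA` for columns that fall opposite a
#' reference gap ("unnumbered" columns, reported by alignment coordinate
#' with an `aln:` prefix by [format_position()]).
#'
#' @param alignment a [dna_alignment].
#' @param reference a single reference sequence (character string, or a
#'   named character vector of length 1 whose name is used as the reference
#'   name).
#' @param reference_name name recorded for the reference coordinate system.
#' @return a `position_map`: list with `map` (integer vector of length
#'   `ncol(alignment)`, `NA` = unnumbered), `reference_name`,
#'   `reference_length`.
#' @export
map_positions <- function(alignment, reference,
                          reference_name = names(reference) %||% "reference") {
  stopifnot(inherits(alignment, "dna_alignment"))
  reference <- toupper(as.character(reference)[1L])
  if (!nzchar(reference)) stop("reference is empty")
  L <- ncol(alignment)
  if (nchar(reference) < 0.5 * L) {
    warning("reference is shorter than half the alignment length")
  }
  cons <- consensus_sequence(alignment)
  ref_clean <- gsub("[^ACGT]", "N", reference)

  letters5 <- c("A", "C", "G", "T", "N")
  sm <- matrix(-1, 5, 5, dimnames = list(letters5, letters5))
  diag(sm) <- 1
  sm["N", ] <- 0
  sm[, "N"] <- 0
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(cons),
    subject = Biostrings::DNAString(ref_clean),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 2
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]

  map <- rep(NA_integer_, L)
  ppos <- 0L
  spos <- 0L
  n_match <- 0L
  n_comp <- 0L
  for (k in seq_along(p)) {
    if (s[k] != "-") spos <- spos + 1L
    if (p[k] != "-") {
      ppos <- ppos + 1L
      if (s[k] != "-") {
        map[ppos] <- spos
        if (p[k] != "N" && s[k] != "N") {
          n_comp <- n_comp + 1L
          if (p[k] == s[k]) n_match <- n_match + 1L
        }
      }
    }
  }
  if (n_comp == 0L || n_match / n_comp < 0.4) {
    stop("alignment could not be mapped to the reference (identity ",
         if (n_comp) sprintf("%.1f%%", 100 * n_match / n_comp) else "0%", ")")
  }
  structure(
    list(map = map, reference_name = reference_name,
         reference_length = nchar(reference)),
    class = "position_map"
  )
}

#' @export
print.position_map <- function(x, ...) {
  cat("Position map onto '", x$reference_name, "' (length ",
      x$reference_length, "): ", sum(!is.na(x$map)), "/", length(x$map),
      " columns numbered\n", sep = "")
  invisible(x)
}

#' Format an alignment site in reference coordinates
#'
#' @param pm a `position_map`, or `NULL` (then the alignment coordinate is
#'   returned as-is).
#' @param site 1-based alignment column(s).
#' @return character vector: the reference position, or `"aln:<site>"` for
#'   unnumbered columns.
#' @export
format_position <- function(pm, site) {
  if (is.null(pm)) return(as.character(site))
  out <- as.character(pm$map[site])
  out[is.na(pm$map[site])] <- paste0("aln:", site[is.na(pm$map[site])])
  out
}

# majority-rule consensus; ties broken toward the alphabetically smallest
# base; columns with no unambiguous base become N
#' @noRd
consensus_sequence <- function(alignment) {
  m <- unclass(alignment)
  cons <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = BASES))
    if (sum(tab) == 0L) return("N")
    BASES[which.max(tab)]
  }, character(1L))
  paste(cons, collapse = "")
}
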