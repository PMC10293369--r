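#' Nucleotide alignment objects
#'
#' A `dna_alignment` is a character matrix of aligned, equal-length
#' nucleotide sequences: one row per sample, one column per site, uppercase
#' IUPAC codes plus `-` for gaps. Row names are the (unique, non-empty)
#' sample ids. All coordinates in the package are 1-based alignment columns.
#'
#' @param x character matrix, or a named character vector of equal-length
#'   sequence strings.
#' @return a `dna_alignment` object.
#' @examples
#' aln <- dna_alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' nrow(aln); ncol(aln)
#' @export
dna_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by sample id")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      bad <- names(x)[which(lens != lens[1L])[1L]]
      stop("alignment error: sequence '", bad, "' has length ", nchar(x[bad]),
           ", expected ", lens[1L])
    }
    x <- do.call(rbind, strsplit(toupper(x), ""))
  }
  if (!is.matrix(x) || !is.character(x)) stop("expected a character matrix")
  ids <- rownames(x)
  if (is.null(ids) || any(!nzchar(ids))) stop("sample ids must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate sample id: ", ids[duplicated(ids)][1L])
  }
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), names(IUPAC_BITS))
  if (length(bad)) {
    stop("invalid nucleotide code(s) in alignment: ", paste(bad, collapse = ", "))
  }
  structure(x, class = c("dna_alignment", "matrix", "array"))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x), "sequences x", ncol(x), "sites\n")
  show <- utils::head(rownames(x), 6L)
  for (id in show) {
    s <- paste(x[id, seq_len(min(ncol(x), 50L))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s, if (ncol(x) > 50L) "..." else ""))
  }
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more\n")
  invisible(x)
}

#' @export
`[.dna_alignment` <- function(x, i, j, ..., drop = FALSE) {
  m <- NextMethod(drop = FALSE)
  structure(m, class = c("dna_alignment", "matrix", "array"))
}

#' Read an aligned FASTA file
#'
#' Reads a pre-aligned nucleotide FASTA matrix. All records must have the
#' same length; ids must be unique. Record order follows file order.
#'
#' @param path path to a FASTA file.
#' @return a [dna_alignment].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(seqs) || length(seqs) == 0L) stop("empty FASTA file: ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[which(lens != lens[1L])[1L]]
    stop("alignment error: record '", bad, "' has length ",
         lens[[which(lens != lens[1L])[1L]]], ", expected ", lens[[1L]])
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sample id in FASTA: ",
         names(seqs)[duplicated(names(seqs))][1L])
  }
  m <- do.call(rbind, as.character(seqs))
  rownames(m) <- names(seqs)
  dna_alignment(m)
}

#' Write an alignment to FASTA
#'
#' @param x a [dna_alignment].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "dna_alignment"))
  d <- ape::as.DNAbin(unclass(x))
  ape::write.FASTA(d, path)
  invisible(path)
}

#' @noRd
alignment_strings <- function(x) {
  apply(unclass(x), 1L, paste, collapse = "")
}
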