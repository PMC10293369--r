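#' Read a sample metadata table
#'
#' Reads a TSV with one row per sample. Required columns: `sample_id`,
#' `species_label` (the a-priori species or population assignment that the
#' delimitation methods evaluate). Optional columns: `clade_label`
#' (defaults to `"unassigned"`), `ingroup` (logical, defaults to `TRUE`),
#' `lat`, `lon` (decimal degrees, default `NA`).
#'
#' @param path path to a tab-separated file with a header row.
#' @return a data.frame with columns sample_id, species_label, clade_label,
#'   ingroup, lat, lon.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_table(df)
}

#' Build a sample table from a data.frame
#'
#' @param df data.frame with at least `sample_id` and `species_label`.
#' @return a validated sample table (see [read_samples()]).
#' @export
sample_table <- function(df) {
  req <- c("sample_id", "species_label")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$species_label <- as.character(df$species_label)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id: ", df$sample_id[duplicated(df$sample_id)][1L])
  }
  if (any(!nzchar(df$sample_id)) || any(!nzchar(df$species_label))) {
    stop("sample ids and species labels must be non-empty")
  }
  if (is.null(df$clade_label)) df$clade_label <- "unassigned"
  df$clade_label <- as.character(df$clade_label)
  df$clade_label[!nzchar(df$clade_label) | is.na(df$clade_label)] <- "unassigned"
  if (is.null(df$ingroup)) df$ingroup <- TRUE
  df$ingroup <- as.logical(df$ingroup)
  if (anyNA(df$ingroup)) stop("column 'ingroup' must be logical")
  if (is.null(df$lat)) df$lat <- NA_real_
  if (is.null(df$lon)) df$lon <- NA_real_
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  # ingroup status should be constant within a named clade
  for (cl in setdiff(unique(df$clade_label), "unassigned")) {
    if (length(unique(df$ingroup[df$clade_label == cl])) > 1L) {
      warning("clade '", cl, "' mixes in-group and out-group samples")
    }
  }
  df[c("sample_id", "species_label", "clade_label", "ingroup", "lat", "lon")]
}

#' Write a sample table to TSV
#'
#' @param df a sample table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
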