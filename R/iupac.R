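# IUPAC nucleotide codes as bitmasks: A=1, C=2, G=4, T=8.
# Gap and N carry the full state set {A,C,G,T}: they constrain nothing.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L,
  N = 15L, "-" = 15L
)

BASES <- c("A", "C", "G", "T")

#' @noRd
char_bits <- function(x) {
  b <- IUPAC_BITS[x]
  if (anyNA(b)) {
    bad <- unique(x[is.na(b)])
    stop("invalid nucleotide code(s): ", paste(bad, collapse = ", "))
  }
  unname(b)
}

# lowest set bit of a positive integer; with A<C<G<T encoded on ascending
# bits this is the lexicographically smallest base of a state set
#' @noRd
lowest_bit <- function(x) x - bitwAnd(x, x - 1L)

#' @noRd
bit_base <- function(b) BASES[match(b, c(1L, 2L, 4L, 8L))]

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
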