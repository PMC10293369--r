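#' Pairwise nucleotide difference matrix
#'
#' Entry (i, j) is the number of admitted sites at which sequences i and j
#' differ. Gaps, `N` and IUPAC ambiguity codes are treated as missing for
#' all population-genetic statistics. Under `complete-deletion` (the DnaSP
#' convention, and the default) every site with a missing state in any
#' sequence of the group is excluded for all pairs, which is what produces
#' per-group effective lengths slightly below the alignment length; under
#' `pairwise-deletion` sites are excluded per pair.
#'
#' @param alignment a [dna_alignment] with at least 2 sequences.
#' @param site_policy `"complete-deletion"` or `"pairwise-deletion"`.
#' @return symmetric integer matrix with attributes `L_eff` (sites used;
#'   under pairwise-deletion, the mean over pairs) and `site_policy`.
#' @export
pairwise_difference_matrix <- function(alignment,
    site_policy = c("complete-deletion", "pairwise-deletion")) {
  site_policy <- match.arg(site_policy)
  stopifnot(inherits(alignment, "dna_alignment"), nrow(alignment) >= 2L)
  codes <- encode_acgt(alignment)
  n <- nrow(codes)
  D <- matrix(0L, n, n, dimnames = list(rownames(alignment), rownames(alignment)))
  if (site_policy == "complete-deletion") {
    keep <- colSums(is.na(codes)) == 0L
    if (!any(keep)) stop("no comparable sites after complete deletion")
    cc <- codes[, keep, drop = FALSE]
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- sum(cc[i, ] != cc[j, ])
        D[i, j] <- d
        D[j, i] <- d
      }
    }
    attr(D, "L_eff") <- sum(keep)
    attr(D, "admitted_sites") <- which(keep)
  } else {
    tot <- 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
        if (!any(ok)) stop("no comparable sites for pair ",
                           rownames(codes)[i], " / ", rownames(codes)[j])
        d <- sum(codes[i, ok] != codes[j, ok])
        D[i, j] <- d
        D[j, i] <- d
        tot <- tot + sum(ok)
      }
    }
    attr(D, "L_eff") <- tot / (n * (n - 1L) / 2)
  }
  attr(D, "site_policy") <- site_policy
  D
}

#' @noRd
encode_acgt <- function(alignment) {
  m <- unclass(alignment)
  codes <- matrix(match(m, BASES), nrow(m), ncol(m),
                  dimnames = dimnames(m))
  codes
}

#' Per-group demographic and diversity statistics
#'
#' Computes, on the sites admitted by `site_policy`: the number of
#' segregating sites S; the mean pairwise difference k-bar; nucleotide
#' diversity per site pi = k-bar / L_eff; per-sequence singleton counts U_i
#' (sites where sequence i carries a state found in no other sequence of
#' the group); Tajima's D,
#' \deqn{D = (\bar k - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}}
#' with the standard constants a1, a2, b1, b2, c1, c2, e1, e2; the
#' Ramos-Onsins & Rozas statistic
#' \deqn{R_2 = \sqrt{\frac{1}{n}\sum_i (U_i - \bar k/2)^2} / S;}
#' and Harpending's raggedness of the observed mismatch distribution.
#'
#' Statistics that are not computable are reported as `NA` with the reason
#' in the `undefined` field: everything but n for n = 1 groups; D when
#' S = 0 or n < 4; R2 and raggedness when S = 0 resp. n < 2.
#'
#' @param alignment a [dna_alignment] (one group).
#' @param site_policy see [pairwise_difference_matrix()].
#' @return a `group_stats` object (fields `n`, `L_eff`, `S`, `k_bar`, `pi`,
#'   `D`, `R2`, `r`, `U`, `site_policy`, `undefined`).
#' @export
group_stats <- function(alignment,
    site_policy = c("complete-deletion", "pairwise-deletion")) {
  site_policy <- match.arg(site_policy)
  stopifnot(inherits(alignment, "dna_alignment"))
  n <- nrow(alignment)
  undef <- character(0)
  if (n == 1L) {
    codes <- encode_acgt(alignment)
    out <- list(n = 1L, L_eff = sum(!is.na(codes)), S = NA_integer_,
                k_bar = NA_real_, pi = NA_real_, D = NA_real_, R2 = NA_real_,
                r = NA_real_, U = NA_integer_, site_policy = site_policy,
                undefined = c(S = "n = 1", k_bar = "n = 1", pi = "n = 1",
                              D = "n = 1", R2 = "n = 1", r = "n = 1"))
    return(structure(out, class = "group_stats"))
  }
  M <- pairwise_difference_matrix(alignment, site_policy)
  L_eff <- attr(M, "L_eff")
  k_bar <- sum(M) / (n * (n - 1L))
  pi <- k_bar / L_eff

  codes <- encode_acgt(alignment)
  if (site_policy == "complete-deletion") {
    codes <- codes[, attr(M, "admitted_sites"), drop = FALSE]
  }
  S <- 0L
  U <- integer(n)
  for (j in seq_len(ncol(codes))) {
    col <- codes[, j]
    tab <- tabulate(col, nbins = 4L)
    if (sum(tab > 0L) >= 2L) S <- S + 1L
    singleton_states <- which(tab == 1L)
    if (length(singleton_states) && sum(tab > 0L) >= 2L) {
      hit <- which(col %in% singleton_states)
      U[hit] <- U[hit] + 1L
    }
  }

  D <- NA_real_
  if (S == 0L) {
    undef["D"] <- "S = 0"
  } else if (n < 4L) {
    undef["D"] <- "n < 4"
  } else {
    D <- tajima_d(n, S, k_bar)
  }
  R2 <- NA_real_
  if (S == 0L) {
    undef["R2"] <- "S = 0"
  } else {
    R2 <- sqrt(mean((U - k_bar / 2)^2)) / S
  }
  mm <- mismatch_from_matrix(M)
  r <- raggedness(mm)

  structure(list(n = n, L_eff = L_eff, S = S, k_bar = k_bar, pi = pi,
                 D = D, R2 = R2, r = r, U = U, site_policy = site_policy,
                 undefined = undef),
            class = "group_stats")
}

#' Tajima's D from summary quantities
#'
#' @param n number of sequences (>= 4).
#' @param S number of segregating sites (> 0).
#' @param k_bar mean pairwise difference.
#' @return Tajima's D.
#' @export
tajima_d <- function(n, S, k_bar) {
  stopifnot(n >= 4L, S > 0L)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' @export
print.group_stats <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf(
    "n=%d  L_eff=%s  S=%s  k_bar=%s  pi=%s  D=%s  R2=%s  r=%s\n",
    x$n, format(x$L_eff),
    if (is.na(x$S)) "undefined" else x$S,
    fmt(x$k_bar), fmt(x$pi), fmt(x$D), fmt(x$R2), fmt(x$r)))
  if (length(x$undefined)) {
    cat("  undefined:", paste(names(x$undefined), "(", x$undefined, ")",
                              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Mismatch distribution of a group
#'
#' The observed relative frequencies x_i of pairwise-difference classes
#' i = 0..d_max, together with expected frequencies under a stated model:
#' under `constant` population size the closed form
#' \deqn{e_i = \hat\theta^i / (\hat\theta + 1)^{i+1}, \quad \hat\theta = \bar k;}
#' under `expansion-sim`, the mean observed mismatch frequencies over
#' `reps` coalescent replicates simulated by [simulate_demographic()] at
#' the supplied or moment-matched sudden-expansion parameters
#' (theta0, t, f), with the replicate count and seed recorded.
#'
#' @param alignment a [dna_alignment] with n >= 2.
#' @param model `"constant"` or `"expansion-sim"`.
#' @param site_policy see [pairwise_difference_matrix()].
#' @param expansion list with elements `theta0`, `t`, `f` for
#'   `expansion-sim`; when `NULL`, `f = 100`, `t = 0.1` and `theta0`
#'   matched so that theta0 (t + 1/f) equals the observed k-bar.
#' @param reps number of simulation replicates for `expansion-sim`.
#' @param seed seed for the expected-curve simulation.
#' @return a `mismatch_distribution` data.frame with columns `class`,
#'   `count`, `observed`, `expected` and attributes `model`, `k_bar`, `n`,
#'   and for `expansion-sim` also `params`, `reps`, `seed`.
#' @export
mismatch_distribution <- function(alignment,
    model = c("constant", "expansion-sim"),
    site_policy = c("complete-deletion", "pairwise-deletion"),
    expansion = NULL, reps = 200L, seed = 1L) {
  model <- match.arg(model)
  site_policy <- match.arg(site_policy)
  M <- pairwise_difference_matrix(alignment, site_policy)
  mm <- mismatch_from_matrix(M)
  k_bar <- sum(mm$class * mm$observed)
  n <- nrow(alignment)

  if (model == "constant") {
    th <- k_bar
    i <- mm$class
    mm$expected <- if (th == 0) as.numeric(i == 0L) else th^i / (th + 1)^(i + 1)
    attr(mm, "model") <- "constant"
    attr(mm, "theta_hat") <- th
  } else {
    if (is.null(expansion)) {
      f <- 100
      t <- 0.1
      expansion <- list(theta0 = max(k_bar, 1e-8) / (t + 1 / f), t = t, f = f)
    }
    L_sim <- max(1000L, ceiling(50 * expansion$theta0))
    dmax <- max(mm$class)
    acc <- numeric(dmax + 1L)
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max, reps)
    for (r in seq_len(reps)) {
      sim <- simulate_demographic(n = n, theta0 = expansion$theta0,
                                  expansion = c(t = expansion$t,
                                                f = expansion$f),
                                  L = L_sim, seed = seeds[r])
      Ms <- pairwise_difference_matrix(sim$alignment, "complete-deletion")
      xs <- mismatch_from_matrix(Ms)$observed
      xs <- c(xs, numeric(max(0L, dmax + 1L - length(xs))))[seq_len(dmax + 1L)]
      acc <- acc + xs
    }
    mm$expected <- acc / reps
    attr(mm, "model") <- "expansion-sim"
    attr(mm, "params") <- expansion
    attr(mm, "reps") <- reps
    attr(mm, "seed") <- seed
  }
  attr(mm, "k_bar") <- k_bar
  attr(mm, "n") <- n
  class(mm) <- c("mismatch_distribution", "data.frame")
  mm
}

#' @noRd
mismatch_from_matrix <- function(M) {
  d <- M[upper.tri(M)]
  dmax <- max(d)
  counts <- tabulate(d + 1L, nbins = dmax + 1L)
  data.frame(class = 0:dmax, count = counts,
             observed = counts / length(d), expected = NA_real_)
}

#' Harpending's raggedness statistic
#'
#' \deqn{r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2}
#' over mismatch classes 0..d (d = maximum observed pairwise difference),
#' with the terminal convention x_{d+1} = 0. Low values indicate the smooth
#' unimodal mismatch distributions typical of recent expansion.
#'
#' @param mismatch a [mismatch_distribution()] result, or a numeric vector
#'   of observed class frequencies x_0..x_d.
#' @return raggedness r >= 0.
#' @export
raggedness <- function(mismatch) {
  x <- if (is.data.frame(mismatch)) mismatch$observed else as.numeric(mismatch)
  sum(diff(c(x, 0))^2)
}

#' Write per-group statistics to TSV (with a full-precision JSON sidecar)
#'
#' @param stats named list of `group_stats` objects (names = group labels).
#' @param path output TSV path; a `.json` sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_group_stats <- function(stats, path) {
  rows <- lapply(names(stats), function(g) {
    s <- stats[[g]]
    data.frame(group = g, n = s$n, L_eff = s$L_eff,
               S = ifelse(is.na(s$S), NA, s$S),
               k_bar = round(s$k_bar, 4), pi = round(s$pi, 4),
               D = round(s$D, 4), R2 = round(s$R2, 4), r = round(s$r, 4),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- lapply(stats, function(s) {
    s$undefined <- as.list(s$undefined)
    unclass(s)
  })
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
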