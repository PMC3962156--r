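# Infinite-sites binarisation of alignments and the classical
# site-frequency-spectrum summary statistics: segregating sites,
# singletons, folded SFS, theta_pi, Watterson's theta_W, Tajima's D,
# Kelly's ZnS, and Fay & Wu's H.

#' Binary (0/1) site matrix
#'
#' Rows are sequences, columns segregating or monomorphic sites; states
#' are 0, 1 or `NA` (missing). The `ancestral` flag records whether state
#' 0 is the true ancestral state (simulation output) or merely the
#' majority state (alignments binarised with [binarize_msa()]).
#'
#' @param mat integer matrix of 0/1/`NA`.
#' @param ancestral `"known"` or `"majority"`.
#' @return an object of class `binary_matrix`.
#' @export
binary_matrix <- function(mat, ancestral = c("known", "majority")) {
  ancestral <- match.arg(ancestral)
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (!all(mat %in% c(0L, 1L, NA_integer_))) {
    stop("binary matrix may only contain 0, 1 and NA")
  }
  all_missing <- which(colSums(!is.na(mat)) == 0L)
  structure(list(mat = mat, ancestral = ancestral,
                 all_missing = all_missing), class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat("<binary_matrix> ", nrow(x$mat), " sequences x ", ncol(x$mat),
      " sites (ancestral: ", x$ancestral, ")\n", sep = "")
  invisible(x)
}

#' Binarise an alignment under the infinite-sites convention
#'
#' For every column the most frequent nucleotide (A/C/G/T; ties broken
#' alphabetically) becomes state 0 and all remaining nucleotides state 1.
#' Gaps are missing. By default N and the other ambiguity codes are also
#' treated as missing; `n_handling = "minor"` codes N as state 1 instead.
#'
#' @param alignment character matrix (rows sequences) or named character
#'   vector of equal-length strings.
#' @param n_handling `"missing"` (default) or `"minor"`.
#' @return a [binary_matrix()] with `ancestral = "majority"`.
#' @export
binarize_msa <- function(alignment, n_handling = c("missing", "minor")) {
  n_handling <- match.arg(n_handling)
  if (!is.matrix(alignment)) {
    alignment <- do.call(rbind, lapply(.as_msa(alignment), .chars))
  }
  nuc <- c("A", "C", "G", "T")
  out <- matrix(NA_integer_, nrow(alignment), ncol(alignment),
                dimnames = dimnames(alignment))
  for (j in seq_len(ncol(alignment))) {
    cells <- alignment[, j]
    counts <- c(sum(cells == "A"), sum(cells == "C"),
                sum(cells == "G"), sum(cells == "T"))
    is_nuc <- cells %in% nuc
    if (any(is_nuc)) {
      major <- nuc[which.max(counts)]
      out[is_nuc, j] <- ifelse(cells[is_nuc] == major, 0L, 1L)
    }
    if (n_handling == "minor") out[cells == "N", j] <- 1L
  }
  binary_matrix(out, ancestral = "majority")
}

.a_n <- function(n) sum(1 / seq_len(n - 1L))

.col_counts <- function(mat) {
  n1 <- colSums(mat == 1L, na.rm = TRUE)
  nc <- colSums(!is.na(mat))
  list(n1 = n1, n0 = nc - n1, nc = nc)
}

#' Basic diversity statistics from a binary site matrix
#'
#' Segregating sites `S` (columns with both states observed), the folded
#' site frequency spectrum over minor-state counts, singletons (folded SFS
#' class 1), the mean pairwise difference estimator `theta_pi` (with a
#' missing-aware pairwise denominator per column), and Watterson's
#' `theta_w = S / a_n` with `a_n` the harmonic number for the full sample
#' size.
#'
#' @param bm a [binary_matrix()] with at least 2 rows.
#' @return list with elements `S`, `singletons`, `sfs`, `theta_pi`,
#'   `theta_w`.
#' @export
basic_diversity_stats <- function(bm) {
  stopifnot(inherits(bm, "binary_matrix"))
  n <- nrow(bm$mat)
  if (n < 2L) stop("at least two sequences required")
  cc <- .col_counts(bm$mat)
  seg <- cc$n1 > 0L & cc$n0 > 0L
  S <- sum(seg)
  minor <- pmin(cc$n1, cc$n0)[seg]
  sfs <- tabulate(minor, nbins = floor(n / 2))
  ok <- cc$nc >= 2L
  theta_pi <- sum((2 * cc$n1[ok] * cc$n0[ok]) /
                    (cc$nc[ok] * (cc$nc[ok] - 1)))
  list(S = S, singletons = if (length(sfs)) sfs[[1L]] else 0L, sfs = sfs,
       theta_pi = theta_pi, theta_w = S / .a_n(n))
}

#' Tajima's D
#'
#' Normalised difference between `theta_pi` and Watterson's `theta_w`,
#' with the standard variance constants (a1, a2, b1, b2, c1, c2, e1, e2)
#' computed for the full sample size. Negative values indicate an excess
#' of rare alleles. Undefined (`NA`) when there are no segregating sites.
#'
#' @param bm a [binary_matrix()].
#' @return Tajima's D, or `NA_real_` when S = 0.
#' @export
tajimas_d <- function(bm) {
  stopifnot(inherits(bm, "binary_matrix"))
  n <- nrow(bm$mat)
  st <- basic_diversity_stats(bm)
  S <- st$S
  if (S == 0L) return(NA_real_)
  a1 <- .a_n(n)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (st$theta_pi - st$theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Kelly's ZnS linkage statistic
#'
#' Mean squared correlation (r^2) over all pairs of segregating sites;
#' pairs whose pairwise-complete genotypes are monomorphic are skipped.
#' Undefined (`NA`) with fewer than two segregating sites.
#'
#' @param bm a [binary_matrix()].
#' @return ZnS, or `NA_real_` when S < 2.
#' @export
zns <- function(bm) {
  stopifnot(inherits(bm, "binary_matrix"))
  cc <- .col_counts(bm$mat)
  seg <- which(cc$n1 > 0L & cc$n0 > 0L)
  if (length(seg) < 2L) return(NA_real_)
  m <- bm$mat[, seg, drop = FALSE]
  r <- if (anyNA(m)) {
    suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  } else {
    cor(m)  # complete data: identical result through the fast path
  }
  r2 <- r[upper.tri(r)]^2
  mean(r2, na.rm = TRUE)
}

#' Fay and Wu's H
#'
#' `H = theta_pi - theta_H`, where `theta_H = sum 2 d^2 / (nc (nc - 1))`
#' over columns with derived-state count `d`. Requires known ancestral
#' states (simulation output); on majority-binarised data the statistic is
#' undefined and `NA` is returned.
#'
#' @param bm a [binary_matrix()] with `ancestral = "known"`.
#' @return H, or `NA_real_` when ancestral states are unknown or S = 0.
#' @export
fay_wu_h <- function(bm) {
  stopifnot(inherits(bm, "binary_matrix"))
  if (bm$ancestral != "known") return(NA_real_)
  cc <- .col_counts(bm$mat)
  seg <- cc$n1 > 0L & cc$n0 > 0L
  if (!any(seg)) return(NA_real_)
  st <- basic_diversity_stats(bm)
  ok <- cc$nc >= 2L
  theta_h <- sum((2 * cc$n1[ok]^2) / (cc$nc[ok] * (cc$nc[ok] - 1)))
  st$theta_pi - theta_h
}

#' Average summary statistics across independent loci
#'
#' Arithmetic means of `theta_pi`, `theta_w`, `ZnS` and `H` across loci;
#' per-locus undefined values are skipped and counted.
#'
#' @param datasets list of [binary_matrix()] objects (one per locus).
#' @return list with the four averaged summaries and `n_dropped`, the
#'   per-statistic count of skipped loci.
#' @export
multilocus_summaries <- function(datasets) {
  if (length(datasets) < 1L) stop("at least one locus required")
  per <- vapply(datasets, function(bm) {
    st <- basic_diversity_stats(bm)
    c(theta_pi = st$theta_pi, theta_w = st$theta_w,
      zns = zns(bm), h = fay_wu_h(bm))
  }, numeric(4L))
  means <- rowMeans(per, na.rm = TRUE)
  list(theta_pi = means[["theta_pi"]], theta_w = means[["theta_w"]],
       zns = means[["zns"]], h = means[["h"]],
       n_dropped = rowSums(is.na(per)))
}
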