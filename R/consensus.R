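# Consensus generation for a forward/reverse read pair: local alignment of
# seqF against the reverse-complemented reverse read (seqRC), reattachment
# of the non-overlapping overhangs, and per-column consensus under the N or
# AMB mismatch strategy, with full provenance propagation.

# Scoring --------------------------------------------------------------------

#' Scoring scheme for local alignment
#'
#' Either a simple match/mismatch scheme or a full symmetric matrix over
#' the 15-letter IUPAC alphabet, always with a linear gap penalty.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gap linear gap score (<= 0).
#' @param matrix optional symmetric numeric matrix with IUPAC row/column
#'   names, overriding `match`/`mismatch`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -2,
                           matrix = NULL) {
  if (gap > 0) stop("gap score must be <= 0")
  if (is.null(matrix)) {
    if (match <= 0) stop("match score must be > 0")
    if (mismatch > 0) stop("mismatch score must be <= 0")
    matrix <- base::matrix(mismatch, 15L, 15L,
                           dimnames = list(.IUPAC_CHARS, .IUPAC_CHARS))
    diag(matrix) <- match
  } else {
    if (!all(.IUPAC_CHARS %in% rownames(matrix)) ||
        !all(.IUPAC_CHARS %in% colnames(matrix))) {
      stop("scoring matrix must cover the 15 IUPAC characters")
    }
    matrix <- matrix[.IUPAC_CHARS, .IUPAC_CHARS]
    if (!isSymmetric(unname(matrix))) {
      stop("scoring matrix must be symmetric")
    }
  }
  structure(list(matrix = matrix, gap = gap), class = "scoring_scheme")
}

#' Read a user-defined IUPAC scoring matrix
#'
#' Tab-separated 15x15 table with IUPAC characters as row and column names.
#'
#' @param path TSV path.
#' @param gap linear gap score to pair with the matrix.
#' @return a [scoring_scheme()].
#' @export
read_scoring_matrix <- function(path, gap = -2) {
  m <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE))
  scoring_scheme(gap = gap, matrix = m)
}

# Local alignment -------------------------------------------------------------

#' Smith-Waterman local alignment of two provenance-carrying sequences
#'
#' Optimal local alignment under a linear gap penalty with a fully
#' deterministic traceback: ties are resolved preferring the diagonal move,
#' then the vertical (gap in `b`), then the horizontal (gap in `a`); among
#' equal-scoring end cells the smallest row, then smallest column is used.
#'
#' @param a,b gap-free [prov_seq()] objects (`a` is the forward read,
#'   `b` the reverse-complemented reverse read in the consensus pipeline).
#' @param scheme a [scoring_scheme()].
#' @param min_overlap_score alignments scoring below this raise a
#'   no-overlap error (the pipeline assumes partially overlapping reads).
#' @return an object of class `pair_alignment` with fields `a_idx`/`b_idx`
#'   (1-based positions per alignment column, 0 for a gap), `score`, and
#'   the local span on each input.
#' @export
smith_waterman_local <- function(a, b, scheme = scoring_scheme(),
                                 min_overlap_score = 8) {
  stopifnot(inherits(a, "prov_seq"), inherits(b, "prov_seq"),
            inherits(scheme, "scoring_scheme"))
  if (any(a$chars == "-") || any(b$chars == "-")) {
    stop("local alignment inputs must be gap-free")
  }
  ai <- match(a$chars, .IUPAC_CHARS)
  bi <- match(b$chars, .IUPAC_CHARS)
  res <- .sw_local(ai, bi, scheme$matrix, scheme$gap)
  if (res$score < min_overlap_score) {
    stop("no overlap: best local alignment score ", res$score,
         " is below the minimum of ", min_overlap_score)
  }
  structure(list(a_idx = res$a_idx, b_idx = res$b_idx, score = res$score,
                 a_span = range(res$a_idx[res$a_idx > 0L]),
                 b_span = range(res$b_idx[res$b_idx > 0L]),
                 extended = FALSE),
            class = "pair_alignment")
}

#' Reattach the non-overlapping overhangs to a local alignment
#'
#' The unaligned prefix and suffix of each input are appended to the local
#' alignment with gap padding in the partner row, yielding the full layout:
#' leading one-read-only part, overlap, trailing one-read-only part. When
#' both inputs have an overhang on the same side (one read's clean region
#' contained in the other) the `a` overhang precedes the `b` overhang.
#'
#' @param aln a [pair_alignment()] produced from `a` and `b`.
#' @param a,b the aligned [prov_seq()] inputs.
#' @return the extended `pair_alignment`.
#' @export
extend_with_overhangs <- function(aln, a, b) {
  stopifnot(inherits(aln, "pair_alignment"))
  na <- length(a$chars)
  nb <- length(b$chars)
  pre_a <- seq_len(aln$a_span[1L] - 1L)
  pre_b <- seq_len(aln$b_span[1L] - 1L)
  suf_a <- if (aln$a_span[2L] < na) (aln$a_span[2L] + 1L):na else integer()
  suf_b <- if (aln$b_span[2L] < nb) (aln$b_span[2L] + 1L):nb else integer()
  a_idx <- c(pre_a, rep(0L, length(pre_b)), aln$a_idx,
             suf_a, rep(0L, length(suf_b)))
  b_idx <- c(rep(0L, length(pre_a)), pre_b, aln$b_idx,
             rep(0L, length(suf_a)), suf_b)
  structure(list(a_idx = a_idx, b_idx = b_idx, score = aln$score,
                 a_span = c(1L, na), b_span = c(1L, nb), extended = TRUE),
            class = "pair_alignment")
}

# Consensus -------------------------------------------------------------------

.merge_refs <- function(out, src, i, j) {
  if (!is.na(src$fw_pos[[j]])) {
    if (!is.na(out$fw_pos[[i]])) {
      stop("consensus error: two forward references for one base")
    }
    out$fw_pos[[i]] <- src$fw_pos[[j]]
    out$fw_char[[i]] <- src$fw_char[[j]]
  }
  if (!is.na(src$rv_pos[[j]])) {
    if (!is.na(out$rv_pos[[i]])) {
      stop("consensus error: two reverse references for one base")
    }
    out$rv_pos[[i]] <- src$rv_pos[[j]]
    out$rv_char[[i]] <- src$rv_char[[j]]
  }
  out
}

#' Consensus character for one alignment column
#'
#' Implements the mismatch rules: equal characters keep the character; a
#' gap paired with a character keeps the character (the insertion variant
#' is always selected); two distinct unambiguous characters become `N`
#' (N strategy) or the IUPAC code for the pair (AMB strategy); an
#' unambiguous character paired with an ambiguous one keeps the unambiguous
#' character; two distinct ambiguous characters become `N` under both
#' strategies.
#'
#' @param ca,cb the two column characters (IUPAC or `-`).
#' @param strategy `"N"` or `"AMB"`.
#' @return single consensus character.
#' @export
consensus_char <- function(ca, cb, strategy = c("N", "AMB")) {
  strategy <- match.arg(strategy)
  if (ca == "-" && cb == "-") stop("empty alignment column")
  if (ca == "-") return(cb)
  if (cb == "-") return(ca)
  if (ca == cb) return(ca)
  ua <- .is_unambiguous(ca)
  ub <- .is_unambiguous(cb)
  if (ua && ub) {
    if (strategy == "N") return("N")
    return(unname(.IUPAC_PAIR_CODE[paste(sort(c(ca, cb)), collapse = "|")]))
  }
  if (ua) return(ca)
  if (ub) return(cb)
  "N"  # two distinct ambiguity codes: conservative, flagged later by ACD
}

#' Build a consensus sequence from an extended pair alignment
#'
#' Applies [consensus_char()] column by column. The consensus contains no
#' gaps; every base carries the union of its column's chromatogram
#' references, so mismatch columns keep both the forward and the reverse
#' raw call as the recorded mismatch pair.
#'
#' @param aln an extended [pair_alignment()] (see [extend_with_overhangs()]).
#' @param a,b the aligned [prov_seq()] inputs.
#' @param strategy `"N"` or `"AMB"`.
#' @param name consensus sequence name.
#' @return a [prov_seq()] of origin `"CONSENSUS"`.
#' @export
build_consensus <- function(aln, a, b, strategy = c("N", "AMB"),
                            name = "consensus") {
  strategy <- match.arg(strategy)
  stopifnot(inherits(aln, "pair_alignment"))
  if (!aln$extended) stop("build_consensus expects an extended alignment")
  n <- length(aln$a_idx)
  chars <- character(n)
  out <- list(fw_pos = rep(NA_integer_, n), rv_pos = rep(NA_integer_, n),
              fw_char = rep(NA_character_, n),
              rv_char = rep(NA_character_, n))
  for (i in seq_len(n)) {
    ia <- aln$a_idx[[i]]
    ib <- aln$b_idx[[i]]
    ca <- if (ia > 0L) a$chars[[ia]] else "-"
    cb <- if (ib > 0L) b$chars[[ib]] else "-"
    chars[[i]] <- consensus_char(ca, cb, strategy)
    if (ia > 0L) out <- .merge_refs(out, a, i, ia)
    if (ib > 0L) out <- .merge_refs(out, b, i, ib)
  }
  trim <- Filter(Negate(is.null),
                 list(fw = a$trim$fw %||% b$trim$fw,
                      rv = b$trim$rv %||% a$trim$rv))
  prov_seq(name, chars, fw_pos = out$fw_pos, rv_pos = out$rv_pos,
           fw_char = out$fw_char, rv_char = out$rv_char,
           origin = "CONSENSUS", trim = trim)
}

#' Assemble a forward/reverse read pair into a consensus sequence
#'
#' Convenience wrapper for the whole consensus step: parse trim indicators
#' and trim both reads, reverse-complement the reverse read, locally align,
#' reattach overhangs, and build the consensus.
#'
#' @param fw_read,rv_read TI-annotated residue strings or [trace_doc()]s.
#' @param name consensus name.
#' @param strategy mismatch strategy, `"N"` or `"AMB"`.
#' @param scheme a [scoring_scheme()].
#' @param min_overlap_score minimum acceptable local alignment score.
#' @return a consensus [prov_seq()].
#' @export
assemble_pair <- function(fw_read, rv_read, name = "consensus",
                          strategy = c("N", "AMB"),
                          scheme = scoring_scheme(),
                          min_overlap_score = 8) {
  strategy <- match.arg(strategy)
  f <- trim_read(fw_read, direction = "FW", name = paste0(name, "_F"))
  r <- trim_read(rv_read, direction = "RV", name = paste0(name, "_R"))
  rc <- reverse_complement_prov(r)
  aln <- smith_waterman_local(f, rc, scheme, min_overlap_score)
  ext <- extend_with_overhangs(aln, f, rc)
  build_consensus(ext, f, rc, strategy = strategy, name = name)
}
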