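# Core provenance machinery: trim-indicator parsing, trimming, reverse
# complement, preliminary-FASTA/sidecar emission, and the arithmetic that
# maps any MSA cell back to a chromatogram base-call position.
#
# Coordinate convention (used throughout the package): a chromatogram
# position is the 1-based index of a base call in the full, untrimmed raw
# read. MSA columns are 1-based. Gap character is "-" everywhere; "N" is a
# base call, never a gap.

# Trim specification ---------------------------------------------------------

#' Trim specification for one raw read
#'
#' @param left_cut number of raw-read positions removed at the 5' end
#'   (including the trim-indicator gap run).
#' @param right_cut number of positions removed at the 3' end.
#' @param original_length length of the untrimmed raw read.
#' @return an object of class `trim_spec`.
#' @export
trim_spec <- function(left_cut, right_cut, original_length) {
  left_cut <- as.integer(left_cut)
  right_cut <- as.integer(right_cut)
  original_length <- as.integer(original_length)
  stopifnot(left_cut >= 0L, right_cut >= 0L)
  if (left_cut + right_cut >= original_length) {
    stop("trim error: cuts leave no clean region")
  }
  structure(list(left_cut = left_cut, right_cut = right_cut,
                 original_length = original_length), class = "trim_spec")
}

#' Parse user-inserted trim indicators
#'
#' A trim indicator (TI) is a run of one or more gap characters that the
#' user inserts into a raw read to mark the boundary between the
#' undetermined edge and the clean region: the last X characters of the
#' left edge are replaced by X gaps and the first Y characters of the right
#' edge by Y gaps. With two runs, everything up to the end of the first run
#' and everything from the start of the last run is cut. A single run is
#' assigned to the left edge when it starts in the first half of the
#' sequence and to the right edge otherwise. No gaps means no trimming.
#'
#' @param residues TI-annotated residue string (same length as the raw
#'   read, since gaps replace characters).
#' @return a [trim_spec()].
#' @export
parse_trim_indicators <- function(residues) {
  .assert_scalar_string(residues, "residues")
  L <- nchar(residues)
  runs <- gregexpr("-+", residues)[[1L]]
  if (runs[1L] == -1L) return(trim_spec(0L, 0L, L))
  starts <- as.integer(runs)
  ends <- starts + attr(runs, "match.length") - 1L
  k <- length(starts)
  if (k > 2L) {
    stop("trim indicator error: ", k, " gap runs found (at most 2 allowed)")
  }
  if (k == 2L) {
    if (starts[2L] - ends[1L] < 2L) {
      stop("trim indicator error: no clean region between indicators")
    }
    left_cut <- ends[1L]
    right_cut <- L - starts[2L] + 1L
  } else if (starts[1L] <= L / 2) {
    left_cut <- ends[1L]
    right_cut <- 0L
  } else {
    left_cut <- 0L
    right_cut <- L - starts[1L] + 1L
  }
  trim_spec(left_cut, right_cut, L)
}

# Provenance-carrying sequences ----------------------------------------------

#' Construct a provenance-carrying sequence
#'
#' A `prov_seq` stores, for every base, up to two chromatogram references:
#' a forward one (`fw_pos`, `fw_char`) and a reverse one (`rv_pos`,
#' `rv_char`). Positions index the untrimmed raw read; the stored
#' characters are the raw base calls at those positions (for reverse
#' references this is the call in read orientation, i.e. the complement of
#' what the base represents in forward orientation).
#'
#' @param name sequence name.
#' @param chars character vector of single IUPAC characters (or gaps, for
#'   aligned rows).
#' @param fw_pos,rv_pos integer vectors of raw-read positions (`NA` where a
#'   direction contributes nothing).
#' @param fw_char,rv_char raw base calls at those positions.
#' @param origin `"FW"`, `"RV"` or `"CONSENSUS"`.
#' @param trim list with elements `fw` and/or `rv`, each a [trim_spec()].
#' @return an object of class `prov_seq`.
#' @export
prov_seq <- function(name, chars, fw_pos = NULL, rv_pos = NULL,
                     fw_char = NULL, rv_char = NULL,
                     origin = c("FW", "RV", "CONSENSUS"), trim = list()) {
  origin <- match.arg(origin)
  n <- length(chars)
  blank_i <- rep(NA_integer_, n)
  blank_c <- rep(NA_character_, n)
  fw_pos <- if (is.null(fw_pos)) blank_i else as.integer(fw_pos)
  rv_pos <- if (is.null(rv_pos)) blank_i else as.integer(rv_pos)
  fw_char <- if (is.null(fw_char)) blank_c else as.character(fw_char)
  rv_char <- if (is.null(rv_char)) blank_c else as.character(rv_char)
  stopifnot(length(fw_pos) == n, length(rv_pos) == n,
            length(fw_char) == n, length(rv_char) == n)
  nongap <- chars != "-"
  if (any(nongap & is.na(fw_pos) & is.na(rv_pos))) {
    stop("prov_seq error: non-gap base without chromatogram reference")
  }
  structure(list(name = name, chars = chars,
                 fw_pos = fw_pos, rv_pos = rv_pos,
                 fw_char = fw_char, rv_char = rv_char,
                 origin = origin, trim = trim),
            class = "prov_seq")
}

#' @export
print.prov_seq <- function(x, ...) {
  cat("<prov_seq> ", x$name, " (", x$origin, "), ", length(x$chars),
      " bases\n", sep = "")
  cat(" ", .collapse(utils::head(x$chars, 60)),
      if (length(x$chars) > 60) "...", "\n", sep = "")
  invisible(x)
}

#' Sequence string of a provenance-carrying sequence
#' @param p a [prov_seq()].
#' @return residue string.
#' @export
prov_seq_string <- function(p) .collapse(p$chars)

#' Trim a raw read according to a trim specification
#'
#' Base `i` (1-based) of the trimmed result carries raw-read position
#' `left_cut + i` in the read's own direction.
#'
#' @param read a [trace_doc()], or a residue string (raw or TI-annotated:
#'   gaps are only allowed inside the cut regions).
#' @param trimspec a [trim_spec()]; when `NULL` it is parsed from the
#'   read's trim indicators.
#' @param direction `"FW"` or `"RV"` (taken from the trace document's
#'   direction hint when available).
#' @param name sequence name (defaults to the trace document's read id).
#' @return a [prov_seq()] holding the clean region with per-base
#'   chromatogram references.
#' @export
trim_read <- function(read, trimspec = NULL, direction = NULL, name = NULL) {
  if (inherits(read, "trace_doc")) {
    residues <- read$base_calls
    if (is.null(direction)) direction <- read$direction_hint
    if (is.null(name)) name <- read$read_id
  } else {
    .assert_scalar_string(read, "read")
    residues <- toupper(read)
    if (is.null(name)) name <- "read"
  }
  if (is.null(direction) || !direction %in% c("FW", "RV")) {
    stop("direction must be 'FW' or 'RV'")
  }
  if (is.null(trimspec)) trimspec <- parse_trim_indicators(residues)
  stopifnot(inherits(trimspec, "trim_spec"))
  L <- nchar(residues)
  if (L != trimspec$original_length) {
    stop("trim error: read length ", L, " does not match trim spec (",
         trimspec$original_length, ")")
  }
  keep <- (trimspec$left_cut + 1L):(L - trimspec$right_cut)
  chars <- .chars(residues)[keep]
  if (any(chars == "-")) {
    stop("trim error: gap character inside the clean region")
  }
  if (!all(.is_iupac(chars))) {
    stop("trim error: non-IUPAC character inside the clean region")
  }
  pos <- trimspec$left_cut + seq_along(keep)
  if (direction == "FW") {
    prov_seq(name, chars, fw_pos = pos, fw_char = chars,
             origin = "FW", trim = list(fw = trimspec))
  } else {
    prov_seq(name, chars, rv_pos = pos, rv_char = chars,
             origin = "RV", trim = list(rv = trimspec))
  }
}

#' Reverse-complement a provenance-carrying reverse read
#'
#' Characters are complemented under the full IUPAC complement and the
#' order reversed; every base keeps its original raw-read position and raw
#' call (references are never renumbered). Applying the operation twice is
#' the identity.
#'
#' @param p a [prov_seq()] of reverse origin.
#' @return the reverse-complemented [prov_seq()].
#' @export
reverse_complement_prov <- function(p) {
  stopifnot(inherits(p, "prov_seq"))
  if (p$origin != "RV") {
    stop("reverse_complement_prov expects a reverse-origin read")
  }
  if (any(p$chars == "-")) {
    stop("raw reads may not contain internal gaps")
  }
  ix <- rev(seq_along(p$chars))
  prov_seq(p$name, iupac_complement(p$chars)[ix],
           fw_pos = p$fw_pos[ix], rv_pos = p$rv_pos[ix],
           fw_char = p$fw_char[ix], rv_char = p$rv_char[ix],
           origin = "RV", trim = p$trim)
}

# Sidecar --------------------------------------------------------------------

.SIDECAR_FORMAT <- "provseq-sidecar"
.SIDECAR_VERSION <- 1L

.encode_char_track <- function(x) .collapse(ifelse(is.na(x), ".", x))
.decode_char_track <- function(s) {
  x <- .chars(s)
  x[x == "."] <- NA_character_
  x
}

.trim_to_list <- function(tr) {
  if (is.null(tr)) NULL
  else list(left_cut = tr$left_cut, right_cut = tr$right_cut,
            original_length = tr$original_length)
}
.trim_from_list <- function(x) {
  if (is.null(x) || length(x) == 0L) NULL  # jsonlite writes NULL as {}
  else trim_spec(x$left_cut, x$right_cut, x$original_length)
}

#' Write a provenance sidecar
#'
#' The sidecar is a versioned JSON document holding, for every record of a
#' preliminary FASTA file, the full per-base chromatogram reference lists
#' and trim specifications. The FASTA alone is deliberately insufficient to
#' reconstruct provenance.
#'
#' @param records list of gap-free [prov_seq()] objects.
#' @param path output path.
#' @export
write_sidecar <- function(records, path) {
  recs <- lapply(records, function(p) {
    stopifnot(inherits(p, "prov_seq"))
    list(name = p$name, sequence = prov_seq_string(p), origin = p$origin,
         fw_pos = p$fw_pos, rv_pos = p$rv_pos,
         fw_char = .encode_char_track(p$fw_char),
         rv_char = .encode_char_track(p$rv_char),
         trim = list(fw = .trim_to_list(p$trim$fw),
                     rv = .trim_to_list(p$trim$rv)))
  })
  jsonlite::write_json(list(format = .SIDECAR_FORMAT,
                            version = .SIDECAR_VERSION, records = recs),
                       path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' Read a provenance sidecar
#'
#' @param path sidecar path.
#' @return named list of [prov_seq()] objects.
#' @export
read_sidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, .SIDECAR_FORMAT)) {
    stop("not a provseq sidecar: ", path)
  }
  recs <- lapply(x$records, function(r) {
    unlist_int <- function(v) {
      vapply(v, function(e) if (is.null(e)) NA_integer_ else as.integer(e),
             integer(1L))
    }
    prov_seq(r$name, .chars(r$sequence),
             fw_pos = unlist_int(r$fw_pos), rv_pos = unlist_int(r$rv_pos),
             fw_char = .decode_char_track(r$fw_char),
             rv_char = .decode_char_track(r$rv_char),
             origin = r$origin,
             trim = Filter(Negate(is.null),
                           list(fw = .trim_from_list(r$trim$fw),
                                rv = .trim_from_list(r$trim$rv))))
  })
  names(recs) <- vapply(recs, `[[`, "", "name")
  recs
}

#' Write the preliminary unaligned FASTA plus provenance sidecar
#'
#' Emits the cleaned, unaligned sequences (post-trim, post-consensus) as
#' FASTA together with the sidecar that anchors every base to its
#' chromatogram position. Any MSA later computed from this FASTA can be
#' mapped back to the chromatograms with [map_site_to_chromatogram()].
#'
#' @param records list of gap-free [prov_seq()] objects.
#' @param fasta_path,sidecar_path output paths.
#' @export
write_preliminary_fasta <- function(records, fasta_path, sidecar_path) {
  seqs <- vapply(records, prov_seq_string, character(1L))
  if (any(grepl("-", seqs, fixed = TRUE))) {
    stop("records contain gaps; degap before writing the preliminary file")
  }
  names(seqs) <- vapply(records, `[[`, "", "name")
  if (anyDuplicated(names(seqs))) {
    stop("duplicate record names in preliminary file")
  }
  write_fasta(seqs, fasta_path)
  write_sidecar(records, sidecar_path)
  invisible(fasta_path)
}

# Mapping --------------------------------------------------------------------

#' Chromatogram reference
#'
#' A pointer into a raw chromatogram's base-call sequence: direction,
#' 1-based base-call index, and the raw call at that index.
#'
#' @param direction `"FW"` or `"RV"`.
#' @param pos 1-based base-call index in the untrimmed raw read.
#' @param called_char raw call at that index (read orientation).
#' @return an object of class `chrom_ref`.
#' @export
chrom_ref <- function(direction, pos, called_char = NA_character_) {
  stopifnot(direction %in% c("FW", "RV"), pos >= 1L)
  structure(list(direction = direction, pos = as.integer(pos),
                 called_char = called_char), class = "chrom_ref")
}

#' @export
format.chrom_ref <- function(x, ...) paste0(x$direction, ".", x$pos)

#' @export
print.chrom_ref <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.as_msa <- function(msa) {
  if (is.matrix(msa)) {
    msa <- apply(msa, 1L, .collapse)
  }
  if (!is.character(msa) || is.null(names(msa))) {
    stop("msa must be a named character vector of aligned strings ",
         "or a named character matrix")
  }
  if (length(unique(nchar(msa))) != 1L) {
    stop("msa rows have unequal lengths")
  }
  toupper(msa)
}

.degap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Check that an MSA is consistent with its provenance sidecar
#'
#' A row passes iff its degapped characters equal the sidecar sequence for
#' that name exactly (rows are matched by name, so row order is free).
#'
#' @param msa named character vector of aligned strings (or a character
#'   matrix with row names).
#' @param sidecar named list of [prov_seq()] records, or a sidecar path.
#' @return data frame with columns `name`, `pass`, `first_mismatch` (1-based
#'   position in the degapped row of the first differing character, `NA`
#'   when the row passes or is absent from the sidecar).
#' @export
validate_msa_consistency <- function(msa, sidecar) {
  msa <- .as_msa(msa)
  if (is.character(sidecar)) sidecar <- read_sidecar(sidecar)
  res <- lapply(names(msa), function(nm) {
    row <- .degap(msa[[nm]])
    p <- sidecar[[nm]]
    if (is.null(p)) {
      return(data.frame(name = nm, pass = FALSE,
                        first_mismatch = NA_integer_))
    }
    ref <- prov_seq_string(p)
    if (identical(row, ref)) {
      data.frame(name = nm, pass = TRUE, first_mismatch = NA_integer_)
    } else {
      a <- .chars(row)
      b <- .chars(ref)
      k <- min(length(a), length(b))
      diff <- which(a[seq_len(k)] != b[seq_len(k)])
      first <- if (length(diff)) diff[[1L]] else k + 1L
      data.frame(name = nm, pass = FALSE, first_mismatch = first)
    }
  })
  do.call(rbind, res)
}

.refs_at <- function(p, i) {
  refs <- list()
  if (!is.na(p$fw_pos[[i]])) {
    refs <- c(refs, list(chrom_ref("FW", p$fw_pos[[i]], p$fw_char[[i]])))
  }
  if (!is.na(p$rv_pos[[i]])) {
    refs <- c(refs, list(chrom_ref("RV", p$rv_pos[[i]], p$rv_char[[i]])))
  }
  refs
}

#' Map an MSA cell back to its chromatogram position(s)
#'
#' The cell at `column` of row `seq_name` is mapped to the
#' `(column - number of gaps before it)`-th base of the sidecar record, and
#' that base's chromatogram references are returned. A gap cell yields an
#' empty list.
#'
#' @inheritParams validate_msa_consistency
#' @param seq_name row name.
#' @param column 1-based alignment column.
#' @param validate check row/sidecar consistency first (default `TRUE`);
#'   inconsistency raises an error naming the row.
#' @return list of 0-2 [chrom_ref()] objects.
#' @export
map_site_to_chromatogram <- function(msa, sidecar, seq_name, column,
                                     validate = TRUE) {
  msa <- .as_msa(msa)
  if (is.character(sidecar)) sidecar <- read_sidecar(sidecar)
  if (!seq_name %in% names(msa)) stop("no MSA row named '", seq_name, "'")
  row <- msa[[seq_name]]
  if (column < 1L || column > nchar(row)) {
    stop("column ", column, " outside alignment of width ", nchar(row))
  }
  if (validate) {
    v <- validate_msa_consistency(msa[seq_name], sidecar)
    if (!v$pass[[1L]]) {
      stop("CGP violated: MSA row '", seq_name,
           "' does not match its sidecar record (first mismatch at ",
           "degapped position ", v$first_mismatch[[1L]], ")")
    }
  }
  cells <- .chars(row)
  if (cells[[column]] == "-") return(list())
  ungapped <- column - sum(cells[seq_len(column - 1L)] == "-")
  .refs_at(sidecar[[seq_name]], ungapped)
}
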