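# Ambiguous Character Detection (ACD) and Polymorphic Site Detection (PSD):
# scans over a provenance-consistent MSA that anchor every suspect cell to
# its chromatogram base-call position(s).

#' ACD report entry
#'
#' One ambiguous character (any IUPAC code other than A/C/G/T, including N)
#' found in the MSA, with its chromatogram reference(s) and an editable
#' `changed_to` field.
#'
#' @param seq_name MSA row name.
#' @param msa_site 1-based alignment column.
#' @param character the ambiguous character.
#' @param fw,rv forward/reverse chromatogram position (`NA` when absent).
#' @param changed_to `"?"`, a gap, or an IUPAC character.
#' @return an object of class `acd_entry`.
#' @export
acd_entry <- function(seq_name, msa_site, character, fw = NA_integer_,
                      rv = NA_integer_, changed_to = "?") {
  if (!.is_ambiguous(character)) {
    stop("acd_entry character must be an ambiguity code, got '",
         character, "'")
  }
  if (is.na(fw) && is.na(rv)) {
    stop("acd_entry needs at least one chromatogram reference")
  }
  structure(list(seq_name = seq_name, msa_site = as.integer(msa_site),
                 character = character, fw = as.integer(fw),
                 rv = as.integer(rv),
                 changed_to = .check_changed_to(changed_to)),
            class = "acd_entry")
}

#' PSD report entry
#'
#' One suspect polymorphic site: the nucleotide (and gap) frequencies at
#' the column, the minority sequences with their characters and
#' chromatogram references, and the rule that triggered the report.
#'
#' @param msa_site 1-based alignment column.
#' @param counts named integer vector `c(A=,C=,G=,T=,gap=)`.
#' @param suspects list of `list(seq_name, character, fw, rv, changed_to)`.
#' @param rule `"minority"` (low-frequency nucleotides) or
#'   `"gap_dominated"` (site dominated by gaps and a few characters).
#' @return an object of class `psd_entry`.
#' @export
psd_entry <- function(msa_site, counts, suspects,
                      rule = c("minority", "gap_dominated")) {
  rule <- match.arg(rule)
  stopifnot(all(c("A", "C", "G", "T", "gap") %in% names(counts)))
  if (length(suspects) == 0L) stop("psd_entry needs at least one suspect")
  suspects <- lapply(suspects, function(s) {
    s$fw <- as.integer(s$fw)
    s$rv <- as.integer(s$rv)
    s$changed_to <- .check_changed_to(s$changed_to %||% "?")
    s[c("seq_name", "character", "fw", "rv", "changed_to")]
  })
  ord <- order(vapply(suspects, `[[`, "", "seq_name"))
  structure(list(msa_site = as.integer(msa_site),
                 counts = vapply(counts[c("A", "C", "G", "T", "gap")],
                                 as.integer, integer(1L)),
                 suspects = suspects[ord], rule = rule),
            class = "psd_entry")
}

.validate_or_abort <- function(msa, sidecar) {
  v <- validate_msa_consistency(msa, sidecar)
  if (!all(v$pass)) {
    stop("CGP violated: MSA row '", v$name[!v$pass][1L],
         "' does not match its sidecar record")
  }
}

.row_refs <- function(p, ungapped_idx) {
  list(fw = p$fw_pos[[ungapped_idx]], rv = p$rv_pos[[ungapped_idx]])
}

#' Scan an MSA for ambiguous characters
#'
#' Emits one [acd_entry()] per ambiguous-character cell (IUPAC codes other
#' than A/C/G/T; gaps are not characters), each carrying the chromatogram
#' position(s) obtained through the provenance sidecar. The MSA must be
#' consistent with the sidecar ([validate_msa_consistency()]), otherwise
#' the scan aborts naming the offending row.
#'
#' @inheritParams validate_msa_consistency
#' @return a [report_doc()] of kind `"ACD"`.
#' @export
acd_scan <- function(msa, sidecar) {
  msa <- .as_msa(msa)
  if (is.character(sidecar)) sidecar <- read_sidecar(sidecar)
  .validate_or_abort(msa, sidecar)
  entries <- list()
  for (nm in names(msa)) {
    cells <- .chars(msa[[nm]])
    ungapped <- cumsum(cells != "-")
    amb <- which(.is_ambiguous(cells))
    p <- sidecar[[nm]]
    for (col in amb) {
      r <- .row_refs(p, ungapped[[col]])
      entries[[length(entries) + 1L]] <-
        acd_entry(seq_name = nm, msa_site = col, character = cells[[col]],
                  fw = r$fw, rv = r$rv)
    }
  }
  report_doc("ACD", entries)
}

#' Scan an MSA for suspect polymorphic sites
#'
#' A column is reported under the `minority` rule iff it shows at least two
#' distinct nucleotides (A/C/G/T) and the fraction of non-majority
#' nucleotides among the column's nucleotides is at most `threshold`; the
#' majority nucleotide is the most frequent one, ties broken
#' alphabetically. A column is additionally reported under the
#' `gap_dominated` rule iff it contains at least one gap and its fraction
#' of non-gap cells among all rows is at most `threshold` (the signature
#' left by always selecting the insertion variant during consensus
#' generation); there all non-gap characters are suspects. Ambiguity codes are the ACD scan's domain and
#' are excluded from nucleotide counts and denominators.
#'
#' @inheritParams validate_msa_consistency
#' @param threshold maximum suspect fraction, in (0, 1]. Default 0.1.
#' @return a [report_doc()] of kind `"PSD"` with the threshold recorded.
#' @export
psd_scan <- function(msa, sidecar, threshold = 0.1) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a number in (0, 1]")
  }
  msa <- .as_msa(msa)
  if (is.character(sidecar)) sidecar <- read_sidecar(sidecar)
  .validate_or_abort(msa, sidecar)
  mat <- do.call(rbind, lapply(msa, .chars))
  ungapped <- do.call(rbind, lapply(msa, function(s) {
    cumsum(.chars(s) != "-")
  }))
  n_rows <- nrow(mat)
  entries <- list()
  suspect_list <- function(col, rows) {
    lapply(unname(rows), function(ri) {
      nm <- names(msa)[[ri]]
      r <- .row_refs(sidecar[[nm]], ungapped[ri, col])
      list(seq_name = nm, character = unname(mat[ri, col]),
           fw = r$fw, rv = r$rv, changed_to = "?")
    })
  }
  for (col in seq_len(ncol(mat))) {
    cells <- mat[, col]
    counts <- c(A = sum(cells == "A"), C = sum(cells == "C"),
                G = sum(cells == "G"), T = sum(cells == "T"),
                gap = sum(cells == "-"))
    nuc_total <- sum(counts[c("A", "C", "G", "T")])
    n_distinct <- sum(counts[c("A", "C", "G", "T")] > 0L)
    if (n_distinct >= 2L) {
      majority <- c("A", "C", "G", "T")[
        which.max(counts[c("A", "C", "G", "T")])]
      minority_n <- nuc_total - counts[[majority]]
      if (minority_n / nuc_total <= threshold) {
        rows <- which(cells %in% c("A", "C", "G", "T") & cells != majority)
        entries[[length(entries) + 1L]] <-
          psd_entry(col, counts, suspect_list(col, rows), "minority")
      }
    }
    non_gap <- n_rows - counts[["gap"]]
    if (counts[["gap"]] > 0L && non_gap > 0L &&
        non_gap / n_rows <= threshold) {
      rows <- which(cells != "-")
      entries[[length(entries) + 1L]] <-
        psd_entry(col, counts, suspect_list(col, rows), "gap_dominated")
    }
  }
  report_doc("PSD", entries, threshold = threshold)
}
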