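# Readers and writers for the external formats the tool touches: FASTA
# (gap-tolerant), chromatogram trace documents (JSON dialect and a read-only
# ABIF subset), newick trees, and the ACD/PSD report formats.

# FASTA ---------------------------------------------------------------------

.FASTA_ALPHABET <- c(.IUPAC_CHARS, "-")

#' Read a FASTA file
#'
#' Strict, gap-tolerant FASTA reader. Residues are preserved byte-exactly
#' (including gap characters) and record order is kept. Lower-case residues
#' are accepted and upper-cased.
#'
#' @param path path to a FASTA file.
#' @return named character vector: names are record identifiers, values the
#'   residue strings.
#' @details Duplicate identifiers, empty files and characters outside the
#'   IUPAC nucleotide alphabet plus `-` raise errors naming the offending
#'   line.
#' @export
read_fasta <- function(path) {
  all_lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", all_lines)
  lines <- all_lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("FASTA error: file '", path, "' is empty")
  if (!startsWith(lines[[1L]], ">")) {
    stop("FASTA error: line ", lineno[[1L]], " does not start with '>'")
  }
  hdr <- startsWith(lines, ">")
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  if (any(names_ == "")) stop("FASTA error: empty record identifier")
  if (anyDuplicated(names_)) {
    stop("FASTA error: duplicate identifier '",
         names_[duplicated(names_)][1L], "'")
  }
  body <- toupper(lines)
  bad <- !hdr & grepl(paste0("[^", .collapse(.FASTA_ALPHABET), "]"), body)
  if (any(bad)) {
    ln <- which(bad)[1L]
    stop("FASTA error: invalid character on line ", lineno[[ln]], ": '",
         lines[[ln]], "'")
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(body[!hdr], grp[!hdr]), .collapse, character(1L))
  if (length(seqs) != length(names_) || any(nchar(seqs) == 0L)) {
    stop("FASTA error: record without residues")
  }
  names(seqs) <- names_
  seqs
}

#' Write records to a FASTA file
#'
#' @param records named character vector of residue strings.
#' @param path output path.
#' @param wrap_width line width for residues (default 70).
#' @export
write_fasta <- function(records, path, wrap_width = 70L) {
  if (is.null(names(records)) || any(names(records) == "")) {
    stop("records must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, nchar(s), by = wrap_width)
    writeLines(substring(s, starts, pmin(starts + wrap_width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

# Trace documents ------------------------------------------------------------

#' Construct a chromatogram trace document
#'
#' A trace document is the base caller's output for one read: the full,
#' untrimmed call string, optionally the scan-point (peak) index of each
#' call, and an optional direction hint. Chromatogram positions used
#' throughout the package are 1-based indices into `base_calls`; `peak_index`
#' is carried for display only.
#'
#' @param read_id read identifier.
#' @param base_calls IUPAC call string (untrimmed).
#' @param peak_index optional integer vector, one strictly increasing
#'   scan-point per call.
#' @param direction_hint optional `"FW"` or `"RV"`.
#' @return an object of class `trace_doc`.
#' @export
trace_doc <- function(read_id, base_calls, peak_index = NULL,
                      direction_hint = NULL) {
  .assert_scalar_string(read_id, "read_id")
  .assert_scalar_string(base_calls, "base_calls")
  base_calls <- toupper(base_calls)
  if (nchar(base_calls) == 0L) stop("base_calls must be non-empty")
  if (!all(.is_iupac(.chars(base_calls)))) {
    stop("base_calls contains non-IUPAC characters")
  }
  if (!is.null(peak_index)) {
    peak_index <- as.integer(peak_index)
    if (length(peak_index) != nchar(base_calls)) {
      stop("peak_index must have one entry per base call")
    }
    if (any(diff(peak_index) <= 0L)) {
      stop("peak_index must be strictly increasing")
    }
  }
  if (!is.null(direction_hint) &&
      !direction_hint %in% c("FW", "RV")) {
    stop("direction_hint must be 'FW' or 'RV'")
  }
  structure(list(read_id = read_id, base_calls = base_calls,
                 peak_index = peak_index, direction_hint = direction_hint),
            class = "trace_doc")
}

#' Read a chromatogram trace document
#'
#' Two dialects are supported: `"json"` (the canonical dialect, schema
#' `{read_id, base_calls, peak_index?, direction_hint?}`) and `"abif"`, a
#' read-only subset of the ABIF (.ab1) container that extracts the called
#' bases (`PBAS` tag) and, when present, the peak locations (`PLOC` tag).
#'
#' @param path file path.
#' @param dialect `"json"` or `"abif"`.
#' @return a [trace_doc()].
#' @export
read_trace_doc <- function(path, dialect = c("json", "abif")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(x$base_calls)) {
      stop("unsupported trace: no base_calls payload in '", path, "'")
    }
    trace_doc(read_id = x$read_id %||% basename(path),
              base_calls = x$base_calls,
              peak_index = x$peak_index,
              direction_hint = x$direction_hint)
  } else {
    .read_abif_trace(path)
  }
}

#' Write a chromatogram trace document
#'
#' Writes either the canonical JSON dialect or a minimal ABIF (.ab1)
#' container holding the `PBAS` (called bases) and optional `PLOC` (peak
#' location) tags. The ABIF writer exists so that synthetic fixtures can
#' exercise the ABIF reader; it emits only those two tags.
#'
#' @param doc a [trace_doc()].
#' @param path output path.
#' @param dialect `"json"` or `"abif"`.
#' @export
write_trace_doc <- function(doc, path, dialect = c("json", "abif")) {
  stopifnot(inherits(doc, "trace_doc"))
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    jsonlite::write_json(
      Filter(Negate(is.null),
             list(read_id = doc$read_id, base_calls = doc$base_calls,
                  peak_index = doc$peak_index,
                  direction_hint = doc$direction_hint)),
      path, auto_unbox = TRUE)
  } else {
    .write_abif_trace(doc, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ABIF subset ----------------------------------------------------------------
# ABIF is a big-endian tagged container: a 4-byte "ABIF" magic, an int16
# version, and a root directory entry pointing at the tag directory. Each
# 28-byte entry is: name (4 chars), number (int32), element type (int16),
# element size (int16), number of elements (int32), data size (int32),
# data offset (int32, holds the data itself when data size <= 4), handle.

.read_abif_trace <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 34L || rawToChar(raw[1:4]) != "ABIF") {
    stop("unsupported trace: '", path, "' is not an ABIF file")
  }
  int32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4L,
                                 endian = "big")
  int16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2L,
                                 endian = "big")
  n_entries <- int32(18L)
  dir_off <- int32(26L)
  read_entry <- function(off) {
    list(name = rawToChar(raw[off + 1:4]), number = int32(off + 4L),
         type = int16(off + 8L), elt_size = int16(off + 10L),
         n = int32(off + 12L), size = int32(off + 16L),
         offset = int32(off + 20L), raw_offset = off + 20L)
  }
  entries <- lapply(seq_len(n_entries) - 1L, function(k) {
    read_entry(dir_off + 28L * k)
  })
  get_data <- function(e) {
    if (e$size <= 4L) raw[e$raw_offset + 1:e$size]
    else raw[e$offset + 1:e$size]
  }
  find <- function(name) {
    hit <- Filter(function(e) e$name == name, entries)
    if (length(hit) == 0L) return(NULL)
    hit[[order(vapply(hit, `[[`, 1L, "number"))[1L]]]
  }
  pbas <- find("PBAS")
  if (is.null(pbas)) {
    stop("unsupported trace: no called-bases (PBAS) payload in '", path, "'")
  }
  calls <- rawToChar(get_data(pbas))
  ploc <- find("PLOC")
  peaks <- if (!is.null(ploc)) {
    readBin(get_data(ploc), "integer", n = ploc$n, size = 2L,
            endian = "big", signed = FALSE)
  }
  trace_doc(read_id = sub("\\.ab1$", "", basename(path)),
            base_calls = calls, peak_index = peaks)
}

.write_abif_trace <- function(doc, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "big")
  calls <- charToRaw(doc$base_calls)
  has_ploc <- !is.null(doc$peak_index)
  n_entries <- 1L + has_ploc
  header_len <- 128L
  pbas_off <- header_len
  ploc_off <- pbas_off + length(calls)
  dir_off <- ploc_off + if (has_ploc) 2L * length(doc$peak_index) else 0L
  writeBin(charToRaw("ABIF"), con)
  wint(101L, 2L)                       # version
  writeBin(charToRaw("tdir"), con)     # root directory entry
  wint(1L, 4L); wint(1023L, 2L); wint(28L, 2L)
  wint(n_entries, 4L); wint(28L * n_entries, 4L); wint(dir_off, 4L)
  wint(0L, 4L)
  writeBin(raw(header_len - 34L), con) # pad header to 128 bytes
  writeBin(calls, con)
  if (has_ploc) wint(doc$peak_index, 2L)
  entry <- function(name, type, elt_size, n, size, offset) {
    writeBin(charToRaw(name), con)
    wint(1L, 4L); wint(type, 2L); wint(elt_size, 2L)
    wint(n, 4L); wint(size, 4L)
    if (size <= 4L) {
      stop("inline ABIF data not emitted by this writer")
    }
    wint(offset, 4L); wint(0L, 4L)
  }
  entry("PBAS", 2L, 1L, length(calls), length(calls), pbas_off)
  if (has_ploc) {
    entry("PLOC", 4L, 2L, length(doc$peak_index),
          2L * length(doc$peak_index), ploc_off)
  }
  invisible(path)
}

# Newick ---------------------------------------------------------------------

#' Read a newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]: rejects unbalanced
#' parentheses and duplicate leaf labels before delegating.
#'
#' @param text newick string (or a file path when `text` names an existing
#'   file).
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(text) {
  .assert_scalar_string(text, "text")
  if (file.exists(text) && !grepl("\\(", text)) text <- readLines(text)[[1L]]
  op <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  cl <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (op != cl) stop("newick error: unbalanced parentheses")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick error: cannot parse tree")
  if (anyDuplicated(tr$tip.label)) {
    stop("newick error: duplicate leaf label '",
         tr$tip.label[duplicated(tr$tip.label)][1L], "'")
  }
  tr
}

#' Write a tree as newick text
#'
#' @param tree an [ape::phylo] tree.
#' @return newick string; branch lengths keep 10 significant digits.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 10L)
}

# ACD / PSD report documents --------------------------------------------------

.render_chrom <- function(fw, rv) {
  if (!is.na(fw) && !is.na(rv)) paste0("FW.", fw, " - RV.", rv)
  else if (!is.na(fw)) paste0("FW.", fw)
  else if (!is.na(rv)) paste0("RV.", rv)
  else stop("report entry without chromatogram reference")
}

.parse_chrom <- function(s) {
  fw <- rv <- NA_integer_
  for (part in strsplit(s, " - ", fixed = TRUE)[[1L]]) {
    if (grepl("^FW\\.[0-9]+$", part)) fw <- as.integer(sub("FW\\.", "", part))
    else if (grepl("^RV\\.[0-9]+$", part)) {
      rv <- as.integer(sub("RV\\.", "", part))
    } else stop("report parse error: bad chromatogram field '", s, "'")
  }
  list(fw = fw, rv = rv)
}

.check_changed_to <- function(x) {
  ok <- x == "?" | x == "-" | x %in% .IUPAC_CHARS
  if (!all(ok)) {
    stop("report parse error: invalid 'Changed To' value '",
         x[!ok][1L], "' (must be ?, gap, or IUPAC)")
  }
  x
}

.render_freqs <- function(counts) {
  lab <- c("A", "C", "G", "T", "gap")
  keep <- counts > 0L
  paste(paste(counts[keep], lab[keep]), collapse = ", ")
}

.parse_freqs <- function(s) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, gap = 0L)
  for (tok in strsplit(s, ", ", fixed = TRUE)[[1L]]) {
    bits <- strsplit(tok, " ", fixed = TRUE)[[1L]]
    if (length(bits) != 2L || !bits[2L] %in% names(counts)) {
      stop("report parse error: bad frequency token '", tok, "'")
    }
    counts[bits[2L]] <- as.integer(bits[1L])
  }
  counts
}

#' Construct a report document
#'
#' Container for a set of ACD ([acd_entry()]) or PSD ([psd_entry()]) report
#' entries; entries are kept sorted by MSA site and sequence name.
#'
#' @param kind `"ACD"` or `"PSD"`.
#' @param entries list of entries of the matching kind.
#' @param threshold the PSD threshold used (PSD reports only).
#' @return an object of class `report_doc`.
#' @export
report_doc <- function(kind = c("ACD", "PSD"), entries, threshold = NULL) {
  kind <- match.arg(kind)
  if (kind == "ACD") {
    stopifnot(all(vapply(entries, inherits, TRUE, "acd_entry")))
    ord <- order(vapply(entries, `[[`, 1L, "msa_site"),
                 vapply(entries, `[[`, "", "seq_name"))
  } else {
    stopifnot(all(vapply(entries, inherits, TRUE, "psd_entry")))
    ord <- order(vapply(entries, `[[`, 1L, "msa_site"),
                 vapply(entries, `[[`, "", "rule"))
  }
  structure(list(kind = kind, tool = .tool_string(),
                 threshold = threshold, entries = unname(entries[ord])),
            class = "report_doc")
}

.tool_string <- function() {
  paste("provseq", as.character(utils::packageVersion("provseq")))
}

#' Write an ACD/PSD report
#'
#' The text format renders one block per entry with `site`,
#' `sequence`/`suspect`, `character`, chromatogram position
#' (`FW.X - RV.Y`, or a single `FW.X`/`RV.Y`), nucleotide frequencies (PSD
#' only) and an editable `changed to` field initialised to `?`. The TSV
#' format is one suspect per row. [read_report()] inverts both.
#'
#' @param doc a [report_doc()].
#' @param path output path.
#' @param format `"text"` or `"tsv"`.
#' @export
write_report <- function(doc, path, format = c("text", "tsv")) {
  stopifnot(inherits(doc, "report_doc"))
  format <- match.arg(format)
  if (format == "text") .write_report_text(doc, path)
  else .write_report_tsv(doc, path)
  invisible(path)
}

.write_report_text <- function(doc, path) {
  out <- c(paste0("# provseq ", doc$kind, " report"),
           paste0("# tool: ", doc$tool))
  if (!is.null(doc$threshold)) {
    out <- c(out, paste0("# threshold: ", format(doc$threshold)))
  }
  out <- c(out, paste0("# entries: ", length(doc$entries)))
  for (e in doc$entries) {
    out <- c(out, "")
    if (doc$kind == "ACD") {
      out <- c(out,
               paste0("site: ", e$msa_site),
               paste0("sequence: ", e$seq_name),
               paste0("character: ", e$character),
               paste0("chromatogram: ", .render_chrom(e$fw, e$rv)),
               paste0("changed to: ", e$changed_to))
    } else {
      out <- c(out,
               paste0("site: ", e$msa_site),
               paste0("rule: ", e$rule),
               paste0("frequencies: ", .render_freqs(e$counts)))
      for (s in e$suspects) {
        out <- c(out, paste("suspect:", s$seq_name, "|", s$character, "|",
                            .render_chrom(s$fw, s$rv), "|", s$changed_to))
      }
    }
  }
  writeLines(out, path)
}

.write_report_tsv <- function(doc, path) {
  if (doc$kind == "ACD") {
    df <- data.frame(
      site = vapply(doc$entries, `[[`, 1L, "msa_site"),
      sequence = vapply(doc$entries, `[[`, "", "seq_name"),
      character = vapply(doc$entries, `[[`, "", "character"),
      chromatogram = vapply(doc$entries, function(e) {
        .render_chrom(e$fw, e$rv)
      }, ""),
      changed_to = vapply(doc$entries, `[[`, "", "changed_to"),
      stringsAsFactors = FALSE)
  } else {
    rows <- lapply(doc$entries, function(e) {
      do.call(rbind, lapply(e$suspects, function(s) {
        data.frame(site = e$msa_site, rule = e$rule,
                   A = e$counts[["A"]], C = e$counts[["C"]],
                   G = e$counts[["G"]], T = e$counts[["T"]],
                   gap = e$counts[["gap"]],
                   sequence = s$seq_name, character = s$character,
                   chromatogram = .render_chrom(s$fw, s$rv),
                   changed_to = s$changed_to, stringsAsFactors = FALSE)
      }))
    })
    df <- do.call(rbind, rows)
  }
  hdr <- c(paste0("# provseq ", doc$kind, " report (tsv)"),
           paste0("# tool: ", doc$tool))
  if (!is.null(doc$threshold)) {
    hdr <- c(hdr, paste0("# threshold: ", format(doc$threshold)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
}

#' Read an ACD/PSD report written by [write_report()]
#'
#' @param path report path (text or TSV; format is sniffed).
#' @return a [report_doc()].
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("report parse error: empty file")
  m <- regmatches(lines[[1L]],
                  regexec("^# provseq (ACD|PSD) report( \\(tsv\\))?$",
                          lines[[1L]]))[[1L]]
  if (length(m) == 0L) stop("report parse error: unrecognised header")
  kind <- m[[2L]]
  tsv <- m[[3L]] != ""
  thr_line <- grep("^# threshold: ", lines, value = TRUE)
  threshold <- if (length(thr_line)) {
    as.numeric(sub("^# threshold: ", "", thr_line[[1L]]))
  }
  doc <- if (tsv) .read_report_tsv(lines, kind)
         else .read_report_text(lines, kind)
  report_doc(kind, doc, threshold = threshold)
}

.read_report_text <- function(lines, kind) {
  body <- lines[!startsWith(lines, "#")]
  blocks <- split(body, cumsum(body == ""))
  blocks <- Filter(function(b) any(b != ""), blocks)
  lapply(blocks, function(b) {
    b <- b[b != ""]
    field <- function(key) {
      hit <- grep(paste0("^", key, ": "), b, value = TRUE)
      if (length(hit) != 1L) {
        stop("report parse error: missing field '", key, "'")
      }
      sub(paste0("^", key, ": "), "", hit)
    }
    if (kind == "ACD") {
      ref <- .parse_chrom(field("chromatogram"))
      acd_entry(seq_name = field("sequence"),
                msa_site = as.integer(field("site")),
                character = field("character"),
                fw = ref$fw, rv = ref$rv,
                changed_to = .check_changed_to(field("changed to")))
    } else {
      suspects <- lapply(grep("^suspect: ", b, value = TRUE), function(s) {
        bits <- strsplit(sub("^suspect: ", "", s), " | ",
                         fixed = TRUE)[[1L]]
        if (length(bits) != 4L) {
          stop("report parse error: bad suspect line '", s, "'")
        }
        ref <- .parse_chrom(bits[[3L]])
        list(seq_name = bits[[1L]], character = bits[[2L]],
             fw = ref$fw, rv = ref$rv,
             changed_to = .check_changed_to(bits[[4L]]))
      })
      psd_entry(msa_site = as.integer(field("site")),
                counts = .parse_freqs(field("frequencies")),
                suspects = suspects, rule = field("rule"))
    }
  })
}

.read_report_tsv <- function(lines, kind) {
  body <- lines[!startsWith(lines, "#")]
  df <- read.delim(text = paste(body, collapse = "\n"),
                   colClasses = "character")
  if (kind == "ACD") {
    lapply(seq_len(nrow(df)), function(i) {
      ref <- .parse_chrom(df$chromatogram[[i]])
      acd_entry(seq_name = df$sequence[[i]],
                msa_site = as.integer(df$site[[i]]),
                character = df$character[[i]], fw = ref$fw, rv = ref$rv,
                changed_to = .check_changed_to(df$changed_to[[i]]))
    })
  } else {
    keys <- paste(df$site, df$rule)
    lapply(split(seq_len(nrow(df)), factor(keys, unique(keys))),
           function(ix) {
      first <- ix[[1L]]
      suspects <- lapply(ix, function(i) {
        ref <- .parse_chrom(df$chromatogram[[i]])
        list(seq_name = df$sequence[[i]], character = df$character[[i]],
             fw = ref$fw, rv = ref$rv,
             changed_to = .check_changed_to(df$changed_to[[i]]))
      })
      psd_entry(msa_site = as.integer(df$site[[first]]),
                counts = c(A = as.integer(df$A[[first]]),
                           C = as.integer(df$C[[first]]),
                           G = as.integer(df$G[[first]]),
                           T = as.integer(df$T[[first]]),
                           gap = as.integer(df$gap[[first]])),
                suspects = suspects, rule = df$rule[[first]])
    })
  }
}
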