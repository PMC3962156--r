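# Synthetic forward/reverse Sanger read-pair fixtures with ground-truth
# chromatogram coordinates. The generator emulates bidirectional
# sequencing of a template: a 5'-anchored forward read and a 3'-anchored
# reverse read (stored as its reverse complement) whose windows overlap,
# each flanked by N-rich undetermined edges, optionally with injected
# mis-calls. Every template position carries its ground-truth chromatogram
# reference(s), which makes the full assembly pipeline testable without
# any sequencing data.

.random_dna <- function(L) {
  .collapse(sample(c("A", "C", "G", "T"), L, replace = TRUE))
}

.random_edge <- function(L) {
  if (L == 0L) return("")
  .collapse(sample(c("N", "A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.6, 0.1, 0.1, 0.1, 0.1)))
}

.insert_tis <- function(raw, edge_left, edge_right, ti_length) {
  ch <- .chars(raw)
  if (edge_left > 0L) {
    k <- min(ti_length, edge_left)
    ch[(edge_left - k + 1L):edge_left] <- "-"
  }
  if (edge_right > 0L) {
    k <- min(ti_length, edge_right)
    start <- length(ch) - edge_right + 1L
    ch[start:(start + k - 1L)] <- "-"
  }
  .collapse(ch)
}

#' Generate a synthetic forward/reverse read-pair fixture
#'
#' Emits a random template, a forward read covering a 5'-anchored window
#' and a reverse read that is the reverse complement of a 3'-anchored
#' window (the windows must overlap), each flanked by N-rich undetermined
#' edges of the requested lengths, plus trim-indicator-annotated versions
#' of both reads. Optional substitution mis-calls are injected into the
#' clean regions and recorded. The ground truth maps every template
#' position to its forward and/or reverse chromatogram position.
#'
#' @param template_length template length.
#' @param edge_lengths list with integer elements `fw` and `rv`, each
#'   `c(left, right)` undetermined-edge lengths.
#' @param error_spec `NULL`, or a list `list(n_sub =, chars =)` giving the
#'   number of substitution mis-calls to inject (split at random between
#'   the two reads) and the replacement alphabet (default A/C/G/T/N; the
#'   replacement always differs from the original call).
#' @param seed integer seed fixing all randomness.
#' @param fw_fraction,rv_fraction window lengths as fractions of the
#'   template (must overlap: `fw_fraction + rv_fraction > 1`).
#' @param ti_length gap-run length of the inserted trim indicators.
#' @return an object of class `fixture_truth`: list with `template`,
#'   `fw_raw`, `rv_raw`, `fw_ti`, `rv_ti`, trace documents `fw_trace` and
#'   `rv_trace`, `edge_lengths`, window lengths, `errors` (data frame of
#'   injected mis-calls with read, raw position, template position, old
#'   and new call), and `truth`, a data frame mapping every template
#'   position to `fw_pos`/`rv_pos` and the raw calls there.
#' @export
generate_read_pair_fixture <- function(template_length = 120L,
                                       edge_lengths = list(fw = c(6L, 5L),
                                                           rv = c(6L, 5L)),
                                       error_spec = NULL, seed = 1L,
                                       fw_fraction = 0.7,
                                       rv_fraction = 0.7,
                                       ti_length = 3L) {
  set.seed(seed)
  L <- as.integer(template_length)
  fw_len <- as.integer(round(fw_fraction * L))
  rv_len <- as.integer(round(rv_fraction * L))
  if (fw_len + rv_len <= L) {
    stop("parameter error: forward and reverse windows do not overlap")
  }
  template <- .random_dna(L)
  tch <- .chars(template)
  rv_start <- L - rv_len + 1L
  fw_clean <- tch[seq_len(fw_len)]
  rv_clean <- rev(iupac_complement(tch[rv_start:L]))
  e_fw <- as.integer(edge_lengths$fw)
  e_rv <- as.integer(edge_lengths$rv)
  errors <- data.frame(read = character(), clean_index = integer(),
                       raw_pos = integer(), template_pos = integer(),
                       old = character(), new = character(),
                       stringsAsFactors = FALSE)
  if (!is.null(error_spec) && (error_spec$n_sub %||% 0L) > 0L) {
    chars <- error_spec$chars %||% c("A", "C", "G", "T", "N")
    n_sub <- error_spec$n_sub
    which_read <- sample(c("FW", "RV"), n_sub, replace = TRUE)
    for (k in seq_len(n_sub)) {
      if (which_read[[k]] == "FW") {
        i <- sample.int(fw_len, 1L)
        old <- fw_clean[[i]]
        new <- sample(setdiff(chars, old), 1L)
        fw_clean[[i]] <- new
        errors[nrow(errors) + 1L, ] <-
          list("FW", i, e_fw[[1L]] + i, i, old, new)
      } else {
        j <- sample.int(rv_len, 1L)
        old <- rv_clean[[j]]
        new <- sample(setdiff(chars, old), 1L)
        rv_clean[[j]] <- new
        errors[nrow(errors) + 1L, ] <-
          list("RV", j, e_rv[[1L]] + j, L - j + 1L, old, new)
      }
    }
  }
  fw_raw <- paste0(.random_edge(e_fw[[1L]]), .collapse(fw_clean),
                   .random_edge(e_fw[[2L]]))
  rv_raw <- paste0(.random_edge(e_rv[[1L]]), .collapse(rv_clean),
                   .random_edge(e_rv[[2L]]))
  fw_ti <- .insert_tis(fw_raw, e_fw[[1L]], e_fw[[2L]], ti_length)
  rv_ti <- .insert_tis(rv_raw, e_rv[[1L]], e_rv[[2L]], ti_length)
  fw_raw_ch <- .chars(fw_raw)
  rv_raw_ch <- .chars(rv_raw)
  truth <- data.frame(
    template_pos = seq_len(L),
    fw_pos = ifelse(seq_len(L) <= fw_len, e_fw[[1L]] + seq_len(L),
                    NA_integer_),
    rv_pos = ifelse(seq_len(L) >= rv_start,
                    e_rv[[1L]] + (L - seq_len(L) + 1L), NA_integer_))
  truth$fw_raw_char <- ifelse(is.na(truth$fw_pos), NA_character_,
                              fw_raw_ch[pmin.int(truth$fw_pos,
                                                 length(fw_raw_ch))])
  truth$rv_raw_char <- ifelse(is.na(truth$rv_pos), NA_character_,
                              rv_raw_ch[pmin.int(truth$rv_pos,
                                                 length(rv_raw_ch))])
  mk_peaks <- function(k) cumsum(sample(8:14, k, replace = TRUE))
  structure(list(
    template = template, fw_raw = fw_raw, rv_raw = rv_raw,
    fw_ti = fw_ti, rv_ti = rv_ti,
    fw_trace = trace_doc("fix_F", fw_raw, mk_peaks(nchar(fw_raw)), "FW"),
    rv_trace = trace_doc("fix_R", rv_raw, mk_peaks(nchar(rv_raw)), "RV"),
    edge_lengths = list(fw = e_fw, rv = e_rv),
    fw_window = fw_len, rv_window = c(rv_start, L),
    errors = errors, truth = truth, seed = seed),
    class = "fixture_truth")
}

#' @export
print.fixture_truth <- function(x, ...) {
  cat("<fixture_truth> template ", nchar(x$template), " bp, forward window ",
      x$fw_window, " bp, reverse window ", x$rv_window[[1L]], "-",
      x$rv_window[[2L]], ", ", nrow(x$errors), " injected mis-call(s)\n",
      sep = "")
  invisible(x)
}
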