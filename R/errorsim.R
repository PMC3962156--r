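# Per-base sequencing-error injection into alignments. Errors are applied
# to alignment rows post-hoc so that site homology is preserved: an
# inserted base in one sequence inserts a gap column in all others.

.ERROR_ALPHABET <- c("A", "C", "G", "T", "N")

#' Per-base sequencing error model
#'
#' Four per-base, per-sequence error rates: misidentification
#' (substitution by A, C, G, T or N), base insertion, base deletion, and
#' base-call extension (duplication of the call, the signature of an
#' erroneously widened chromatogram peak).
#'
#' @param p_sub,p_ins,p_del,p_ext rates in \[0, 1).
#' @return an object of class `error_model`.
#' @seealso [error_model_preset()] for the `errA`/`errB` presets.
#' @export
error_model <- function(p_sub, p_ins, p_del, p_ext) {
  rates <- c(p_sub = p_sub, p_ins = p_ins, p_del = p_del, p_ext = p_ext)
  if (any(rates < 0) || any(rates >= 1)) stop("rates must be in [0, 1)")
  if (p_ins + p_del + p_ext >= 1) stop("frameshift rates must sum below 1")
  structure(as.list(rates), class = "error_model")
}

#' Named error-rate presets
#'
#' `errA`: substitution 0.001, insertion/deletion/extension 0.0001 per
#' base. `errB`: substitution 0.01, insertion/deletion/extension 0.0005
#' per base.
#'
#' @param name `"errA"` or `"errB"`.
#' @return an [error_model()].
#' @export
error_model_preset <- function(name = c("errA", "errB")) {
  name <- match.arg(name)
  if (name == "errA") error_model(0.001, 0.0001, 0.0001, 0.0001)
  else error_model(0.01, 0.0005, 0.0005, 0.0005)
}

#' Inject sequencing errors into an alignment
#'
#' Errors are drawn independently and uniformly for every sequence and
#' every non-gap base. A substitution replaces the base by a uniform draw
#' from A/C/G/T/N excluding the current base (so that every drawn event is
#' an actual error; set `allow_self = TRUE` for the unrestricted draw). At
#' most one frameshift event fires per base: a deletion replaces the base
#' by a gap (the column is retained, preserving homology), an insertion
#' adds a new column after the base holding a uniform A/C/G/T/N draw in
#' that row and gaps in all other rows, and an extension duplicates the
#' base into a new column the same way.
#'
#' @param alignment character matrix (rows sequences) or named character
#'   vector of equal-length strings.
#' @param model an [error_model()].
#' @param seed optional integer seed.
#' @param allow_self allow substitutions to redraw the original base.
#' @return list with `alignment` (the errored matrix), `log` (data frame
#'   of events: `row`, `col` in original coordinates, `type`, `old`,
#'   `new`), and `col_map` (original column -> errored column index).
#' @export
inject_errors <- function(alignment, model, seed = NULL,
                          allow_self = FALSE) {
  stopifnot(inherits(model, "error_model"))
  if (!is.matrix(alignment)) {
    alignment <- do.call(rbind, lapply(.as_msa(alignment), .chars))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(alignment)
  L <- ncol(alignment)
  if (is.null(rownames(alignment))) {
    rownames(alignment) <- paste0("seq", seq_len(n))
  }
  mat <- alignment
  nongap <- mat != "-"
  log_rows <- list()
  add_log <- function(cells, type, old, new) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      row = rownames(mat)[(cells - 1L) %% n + 1L],
      col = (cells - 1L) %/% n + 1L,
      type = type, old = old, new = new, stringsAsFactors = FALSE)
  }
  # substitutions first, then a single frameshift draw per base
  sub_cells <- which(nongap & runif(n * L) < model$p_sub)
  if (length(sub_cells)) {
    old <- mat[sub_cells]
    new <- vapply(old, function(ch) {
      pool <- if (allow_self) .ERROR_ALPHABET
              else setdiff(.ERROR_ALPHABET, ch)
      pool[sample.int(length(pool), 1L)]
    }, character(1L), USE.NAMES = FALSE)
    add_log(sub_cells, "sub", old, new)
    mat[sub_cells] <- new
  }
  u <- runif(n * L)
  del_cells <- which(nongap & u < model$p_del)
  ins_cells <- which(nongap & u >= model$p_del &
                       u < model$p_del + model$p_ins)
  ext_cells <- which(nongap & u >= model$p_del + model$p_ins &
                       u < model$p_del + model$p_ins + model$p_ext)
  if (length(del_cells)) {
    add_log(del_cells, "del", mat[del_cells], "-")
    mat[del_cells] <- "-"
  }
  ins_new <- character(0)
  if (length(ins_cells)) {
    ins_new <- .ERROR_ALPHABET[sample.int(5L, length(ins_cells),
                                          replace = TRUE)]
    add_log(ins_cells, "ins", NA_character_, ins_new)
  }
  if (length(ext_cells)) {
    add_log(ext_cells, "ext", mat[ext_cells], mat[ext_cells])
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows)
         else data.frame(row = character(), col = integer(),
                         type = character(), old = character(),
                         new = character(), stringsAsFactors = FALSE)
  log <- log[order(log$col, match(log$row, rownames(mat)),
                   match(log$type, c("sub", "del", "ins", "ext"))), ,
             drop = FALSE]
  rownames(log) <- NULL
  out <- .apply_column_insertions(mat, log)
  list(alignment = out$mat, log = log, col_map = out$col_map)
}

# place insertion/extension events as new columns after their original
# column; events at the same column are ordered by row index
.apply_column_insertions <- function(mat, log) {
  n <- nrow(mat)
  L <- ncol(mat)
  ev <- log[log$type %in% c("ins", "ext"), , drop = FALSE]
  if (nrow(ev)) {
    ev <- ev[order(ev$col, match(ev$row, rownames(mat))), , drop = FALSE]
  }
  per_col <- tabulate(ev$col, nbins = L)
  col_map <- seq_len(L) + c(0L, cumsum(per_col))[seq_len(L)]
  out <- matrix("-", n, L + nrow(ev),
                dimnames = list(rownames(mat), NULL))
  out[, col_map] <- mat
  if (nrow(ev)) {
    rank_in_col <- sequence(rle(ev$col)$lengths)
    new_cols <- col_map[ev$col] + rank_in_col
    for (k in seq_len(nrow(ev))) {
      out[ev$row[[k]], new_cols[[k]]] <- ev$new[[k]]
    }
  }
  list(mat = out, col_map = col_map)
}

#' Replay an event log on a clean alignment
#'
#' Deterministically reapplies a log produced by [inject_errors()],
#' reproducing the errored alignment exactly.
#'
#' @param alignment the clean character matrix the log was generated from.
#' @param log event log data frame.
#' @return the errored character matrix.
#' @export
replay_events <- function(alignment, log) {
  if (!is.matrix(alignment)) {
    alignment <- do.call(rbind, lapply(.as_msa(alignment), .chars))
  }
  mat <- alignment
  for (ty in c("sub", "del")) {
    ev <- log[log$type == ty, , drop = FALSE]
    if (nrow(ev)) {
      mat[cbind(match(ev$row, rownames(mat)), ev$col)] <- ev$new
    }
  }
  .apply_column_insertions(mat, log)$mat
}

#' Revert injected errors
#'
#' Removes all inserted columns and restores logged substitutions and
#' deletions, recovering the clean alignment bit-exactly.
#'
#' @param errored errored alignment matrix from [inject_errors()].
#' @param log the event log.
#' @param col_map the original-to-errored column map.
#' @return the clean character matrix.
#' @export
revert_errors <- function(errored, log, col_map) {
  mat <- errored[, col_map, drop = FALSE]
  for (ty in c("del", "sub")) {
    ev <- log[log$type == ty, , drop = FALSE]
    if (nrow(ev)) {
      mat[cbind(match(ev$row, rownames(mat)), ev$col)] <- ev$old
    }
  }
  mat
}
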