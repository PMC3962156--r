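# Independent oracles used across the test files. These deliberately do
# not share code with the package internals.

# --- alignment oracles -------------------------------------------------------

# global (Needleman-Wunsch) score of two full strings, linear gaps
nw_global_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  m <- length(a)
  n <- length(b)
  H <- matrix(0, m + 1, n + 1)
  H[, 1] <- gap * (0:m)
  H[1, ] <- gap * (0:n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(H[i, j] + s, H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
    }
  }
  H[m + 1, n + 1]
}

# brute-force best local alignment score: maximise the global score over
# all pairs of (possibly empty) substrings
brute_local_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a)) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      sc <- nw_global_score(sa, substr(b, j1, j2), match, mismatch, gap)
      if (sc > best) best <- sc
    }
  }
  best
}

# --- consensus rule oracle ---------------------------------------------------

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_code_for_pair <- function(x, y) {
  target <- sort(c(x, y))
  for (code in names(ORACLE_SETS)) {
    if (identical(sort(ORACLE_SETS[[code]]), target)) return(code)
  }
  stop("no code for ", x, y)
}

# hand-written restatement of the mismatch rules
oracle_consensus <- function(ca, cb, strategy) {
  unamb <- c("A", "C", "G", "T")
  if (ca == "-") return(cb)
  if (cb == "-") return(ca)
  if (ca == cb) return(ca)
  if (ca %in% unamb && cb %in% unamb) {
    if (strategy == "N") return("N")
    return(oracle_code_for_pair(ca, cb))
  }
  if (ca %in% unamb) return(ca)
  if (cb %in% unamb) return(cb)
  "N"
}

ORACLE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y",
                       Y = "R", S = "S", W = "W", K = "M", M = "K",
                       B = "V", V = "B", D = "H", H = "D", N = "N")

# --- CGP property checker ----------------------------------------------------

# Assemble a fixture pair, build an MSA row with random gap columns, and
# map every non-gap cell back through the sidecar. Checks that the mapped
# references agree with the fixture ground truth and that the mapped raw
# calls reproduce the cell character (or the recorded mismatch pair).
# Returns the number of cells checked; any violation fails immediately.
check_cgp_fixture <- function(fx, strategy = "N", n_gap_cols = 8,
                              strict_only = FALSE) {
  cons <- assemble_pair(fx$fw_ti, fx$rv_ti, name = "cons",
                        strategy = strategy)
  sidecar <- list(cons = cons)
  L <- nchar(fx$template)
  strict <- length(cons$chars) == L
  if (strict_only && !strict) {
    stop("consensus length deviates from template on a strict fixture")
  }
  row <- cons$chars
  for (g in sort(sample.int(length(row) + 1, n_gap_cols, replace = TRUE),
                 decreasing = TRUE)) {
    row <- append(row, "-", after = g - 1)
  }
  msa <- stats::setNames(paste(row, collapse = ""), "cons")
  v <- validate_msa_consistency(msa, sidecar)
  if (!v$pass[1]) stop("validation failed on fixture MSA")
  fw_raw <- strsplit(fx$fw_raw, "")[[1]]
  rv_raw <- strsplit(fx$rv_raw, "")[[1]]
  nongap_cols <- which(row != "-")
  checked <- 0
  for (k in seq_along(nongap_cols)) {
    col <- nongap_cols[k]
    refs <- map_site_to_chromatogram(msa, sidecar, "cons", col,
                                     validate = FALSE)
    cell <- row[col]
    if (length(refs) == 0) stop("non-gap cell mapped to no reference")
    fw <- NULL
    rv <- NULL
    for (r in refs) {
      if (r$direction == "FW") fw <- r else rv <- r
    }
    if (strict) {
      tr <- fx$truth[k, ]  # k-th consensus base = template position k
      if (!identical(is.null(fw), is.na(tr$fw_pos)) ||
          !identical(is.null(rv), is.na(tr$rv_pos))) {
        stop("reference directions disagree with ground truth at ", k)
      }
      if (!is.null(fw) && fw$pos != tr$fw_pos) {
        stop("forward position disagrees with ground truth at ", k)
      }
      if (!is.null(rv) && rv$pos != tr$rv_pos) {
        stop("reverse position disagrees with ground truth at ", k)
      }
    }
    cf <- if (!is.null(fw)) fw_raw[fw$pos]
    cr <- if (!is.null(rv)) unname(ORACLE_COMPLEMENT[rv_raw[rv$pos]])
    expected <- if (!is.null(cf) && !is.null(cr)) {
      oracle_consensus(cf, cr, strategy)
    } else if (!is.null(cf)) cf else cr
    if (cell != expected) {
      stop("cell character ", cell, " at column ", col,
           " does not match mapped raw call(s) ", cf, "/", cr)
    }
    checked <- checked + 1
  }
  checked
}

# --- misc --------------------------------------------------------------------

random_dna_string <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

make_fw_prov <- function(s, name = "a") {
  ch <- strsplit(s, "")[[1]]
  prov_seq(name, ch, fw_pos = seq_along(ch), fw_char = ch, origin = "FW")
}
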