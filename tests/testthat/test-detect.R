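# helper: an MSA of simple forward-only rows plus its sidecar
make_simple_msa <- function(rows) {
  sidecar <- lapply(names(rows), function(nm) {
    make_fw_prov(gsub("-", "", rows[[nm]]), nm)
  })
  names(sidecar) <- names(rows)
  list(msa = rows, sidecar = sidecar)
}

test_that("ACD reports exactly the ambiguity-code cells with their refs", {
  x <- make_simple_msa(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_length(acd_scan(x$msa, x$sidecar)$entries, 0)

  y <- make_simple_msa(c(a = "ACNTACGT", b = "AC-TRCGT"))
  doc <- acd_scan(y$msa, y$sidecar)
  expect_length(doc$entries, 2)
  e1 <- doc$entries[[1]]
  expect_identical(e1$seq_name, "a")
  expect_identical(e1$msa_site, 3L)
  expect_identical(e1$character, "N")
  expect_identical(e1$fw, 3L)
  e2 <- doc$entries[[2]]
  expect_identical(e2$msa_site, 5L)
  expect_identical(e2$fw, 4L)  # gap before shifts the raw position

  # fixture MSA with k injected N mis-calls: k entries, ground-truth refs
  fx <- generate_read_pair_fixture(
    template_length = 130, seed = 77,
    error_spec = list(n_sub = 3, chars = "N"))
  cons <- assemble_pair(fx$fw_ti, fx$rv_ti, name = "c")
  msa <- stats::setNames(prov_seq_string(cons), "c")
  ents <- acd_scan(msa, list(c = cons))$entries
  n_cells <- sum(!cons$chars %in% c("A", "C", "G", "T"))
  expect_identical(length(ents), n_cells)
  for (e in ents) {
    tr <- fx$truth[e$msa_site, ]
    if (!is.na(e$fw)) expect_identical(e$fw, tr$fw_pos)
    if (!is.na(e$rv)) expect_identical(e$rv, tr$rv_pos)
  }
})

test_that("PSD applies the minority-fraction rule with threshold t", {
  rows <- c(stats::setNames(rep("AACA", 9), paste0("s", 1:9)),
            sX = "AAGA")
  x <- make_simple_msa(rows)
  doc <- psd_scan(x$msa, x$sidecar, 0.1)
  expect_length(doc$entries, 1)
  e <- doc$entries[[1]]
  expect_identical(e$msa_site, 3L)
  expect_identical(unname(e$counts[c("C", "G")]), c(9L, 1L))
  expect_identical(e$rule, "minority")
  expect_identical(e$suspects[[1]]$seq_name, "sX")
  expect_identical(e$suspects[[1]]$character, "G")

  # monomorphic columns and balanced polymorphisms are not reported
  bal <- make_simple_msa(c(stats::setNames(rep("AG", 5), paste0("a", 1:5)),
                           stats::setNames(rep("AC", 5), paste0("b", 1:5))))
  expect_length(psd_scan(bal$msa, bal$sidecar, 0.1)$entries, 0)

  expect_error(psd_scan(x$msa, x$sidecar, 1.5), "threshold")
  expect_error(psd_scan(x$msa, x$sidecar, 0), "threshold")
})

test_that("gap-dominated columns are reported with all characters suspect", {
  rows <- c(stats::setNames(rep("A-", 28), paste0("g", 1:28)),
            c1 = "AC", c2 = "AC")
  x <- make_simple_msa(rows)
  doc <- psd_scan(x$msa, x$sidecar, 0.1)
  expect_length(doc$entries, 1)
  e <- doc$entries[[1]]
  expect_identical(e$rule, "gap_dominated")
  expect_identical(e$msa_site, 2L)
  expect_identical(unname(e$counts[c("C", "gap")]), c(2L, 28L))
  expect_identical(vapply(e$suspects, `[[`, "", "seq_name"),
                   c("c1", "c2"))
})

test_that("PSD report size is monotone in t, and t = 1 reports all polymorphic sites", {
  set.seed(41)
  n <- 12
  mat <- matrix(sample(c("A", "C", "G", "T"), n * 40, TRUE,
                       prob = c(0.85, 0.05, 0.05, 0.05)), n, 40)
  rownames(mat) <- paste0("s", 1:n)
  rows <- apply(mat, 1, paste, collapse = "")
  x <- make_simple_msa(rows)
  sizes <- vapply(c(0.1, 0.3, 0.5, 1), function(t) {
    length(psd_scan(x$msa, x$sidecar, t)$entries)
  }, 0L)
  expect_true(all(diff(sizes) >= 0))
  n_poly <- sum(apply(mat, 2, function(col) length(unique(col)) >= 2))
  expect_identical(sizes[4], n_poly)
})

test_that("injected pseudo-polymorphisms are flagged with ground-truth refs", {
  # 10 identical individuals; one gets substitution mis-calls
  set.seed(55)
  template <- random_dna_string(120)
  rows <- stats::setNames(rep(template, 9), paste0("ind", 1:9))
  sidecar <- lapply(names(rows), function(nm) make_fw_prov(rows[[nm]], nm))
  names(sidecar) <- names(rows)
  fx <- generate_read_pair_fixture(template_length = 120, seed = 56,
                                   error_spec = list(
                                     n_sub = 2, chars = c("A", "C", "G", "T")))
  cons <- assemble_pair(fx$fw_ti, fx$rv_ti, name = "indX", strategy = "N")
  # replace the shared template so rows align column-for-column
  rows <- stats::setNames(rep(fx$template, 9), paste0("ind", 1:9))
  sidecar <- lapply(names(rows), function(nm) make_fw_prov(rows[[nm]], nm))
  names(sidecar) <- names(rows)
  msa <- c(rows, indX = prov_seq_string(cons))
  sidecar$indX <- cons
  doc <- psd_scan(msa, sidecar, 0.1)
  clean_cols <- which(strsplit(fx$template, "")[[1]] ==
                        strsplit(prov_seq_string(cons), "")[[1]])
  err_cols <- setdiff(seq_len(120), clean_cols)
  nuc_cols <- err_cols[cons$chars[err_cols] %in% c("A", "C", "G", "T")]
  expect_identical(vapply(doc$entries, `[[`, 1L, "msa_site"), nuc_cols)
  for (e in doc$entries) {
    tr <- fx$truth[e$msa_site, ]
    s <- e$suspects[[1]]
    expect_identical(s$seq_name, "indX")
    if (!is.na(s$fw)) expect_identical(s$fw, tr$fw_pos)
    if (!is.na(s$rv)) expect_identical(s$rv, tr$rv_pos)
  }
})
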