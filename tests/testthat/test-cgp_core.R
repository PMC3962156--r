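test_that("trim indicators are parsed by the two-run, one-run and no-run rules", {
  ts <- parse_trim_indicators("AN--CGTACG--NA")
  expect_identical(ts$left_cut, 4L)
  expect_identical(ts$right_cut, 4L)

  ts0 <- parse_trim_indicators("ACGTACGT")
  expect_identical(c(ts0$left_cut, ts0$right_cut), c(0L, 0L))

  expect_error(parse_trim_indicators("A--CG--TA--GG"), "3 gap runs")
  expect_error(parse_trim_indicators("ACG----ACG"), NA)
  expect_error(parse_trim_indicators("----"), "clean region")
  expect_error(parse_trim_indicators("-"), "clean region")

  # single run: assigned by the midpoint of its start position
  left <- parse_trim_indicators("N--ACGTACGTAC")
  expect_identical(c(left$left_cut, left$right_cut), c(3L, 0L))
  right <- parse_trim_indicators("ACGTACGTAC--N")
  expect_identical(c(right$left_cut, right$right_cut), c(0L, 3L))
})

test_that("trimming assigns chromatogram positions left_cut + i", {
  p <- trim_read("NNNACGTNN", trim_spec(3, 2, 9), direction = "FW")
  expect_identical(p$chars, c("A", "C", "G", "T"))
  expect_identical(p$fw_pos, 4:7)
  expect_identical(p$fw_char, c("A", "C", "G", "T"))

  p0 <- trim_read("ACGTAC", trim_spec(0, 0, 6), direction = "RV")
  expect_identical(p0$rv_pos, 1:6)

  # fixture: every trimmed base recovers the raw-read character
  fx <- generate_read_pair_fixture(seed = 13)
  tp <- trim_read(fx$fw_ti, direction = "FW")
  raw <- strsplit(fx$fw_raw, "")[[1]]
  expect_identical(tp$chars, raw[tp$fw_pos])
})

test_that("reverse complement keeps raw positions and is an involution", {
  p <- trim_read("ACGTN", trim_spec(0, 0, 5), direction = "RV")
  rc <- reverse_complement_prov(p)
  expect_identical(paste(rc$chars, collapse = ""), "NACGT")
  expect_identical(rc$rv_pos, 5:1)
  expect_identical(rc$rv_char, c("N", "T", "G", "C", "A"))
  expect_identical(reverse_complement_prov(rc), p)

  # full IUPAC closure
  expect_identical(iupac_complement(iupac_complement(names(ORACLE_SETS))),
                   names(ORACLE_SETS))
  expect_identical(iupac_complement(names(ORACLE_SETS)),
                   unname(ORACLE_COMPLEMENT[names(ORACLE_SETS)]))
})

test_that("sidecar and preliminary FASTA round-trip", {
  fx <- generate_read_pair_fixture(seed = 2, error_spec = list(n_sub = 1))
  cons <- assemble_pair(fx$fw_ti, fx$rv_ti, name = "c1")
  single <- trim_read(fx$fw_ti, direction = "FW", name = "f1")
  fa <- withr::local_tempfile(fileext = ".fasta")
  sc <- withr::local_tempfile(fileext = ".json")
  write_preliminary_fasta(list(cons, single), fa, sc)
  back <- read_sidecar(sc)
  expect_equal(back, list(c1 = cons, f1 = single))
  expect_identical(read_fasta(fa),
                   c(c1 = prov_seq_string(cons),
                     f1 = prov_seq_string(single)))

  gapped <- prov_seq("g", c("A", "-", "C"), fw_pos = c(1L, NA, 2L),
                     fw_char = c("A", NA, "C"), origin = "FW")
  expect_error(write_preliminary_fasta(list(gapped), fa, sc), "degap")
})

test_that("MSA cells map back through gap-aware arithmetic", {
  p <- make_fw_prov("ACGTACGTAC", "row")
  sidecar <- list(row = p)
  msa <- c(row = "--ACGTAC-GTAC")  # two gaps before column 7
  refs <- map_site_to_chromatogram(msa, sidecar, "row", 7)
  expect_length(refs, 1)
  expect_identical(format(refs[[1]]), "FW.5")
  expect_identical(map_site_to_chromatogram(msa, sidecar, "row", 9),
                   list())

  # consensus cell from the overlap region carries FW and RV references
  fx <- generate_read_pair_fixture(seed = 4)
  cons <- assemble_pair(fx$fw_ti, fx$rv_ti, name = "c")
  m2 <- stats::setNames(prov_seq_string(cons), "c")
  ov <- which(!is.na(fx$truth$fw_pos) & !is.na(fx$truth$rv_pos))[1]
  refs2 <- map_site_to_chromatogram(m2, list(c = cons), "c", ov)
  expect_identical(sort(vapply(refs2, `[[`, "", "direction")),
                   c("FW", "RV"))
})

test_that("consistency validation is name-keyed and localises edits", {
  p <- make_fw_prov("ACGTACGT", "a")
  q <- make_fw_prov("TTTTCCCC", "b")
  sidecar <- list(a = p, b = q)
  msa <- c(b = "TTTT-CCCC", a = "AC-GTACGT")  # permuted row order
  v <- validate_msa_consistency(msa, sidecar)
  expect_true(all(v$pass))

  msa_bad <- c(a = "ACGTACGT", b = "TTTTCCCT")
  v2 <- validate_msa_consistency(msa_bad, sidecar)
  expect_identical(v2$pass, c(TRUE, FALSE))
  expect_identical(v2$first_mismatch[2], 8L)
  expect_error(map_site_to_chromatogram(msa_bad, sidecar, "b", 1),
               "CGP violated")
})

test_that("mapped cells of fixture MSAs agree with ground truth", {
  set.seed(99)
  total <- 0
  for (i in 1:12) {
    fx <- generate_read_pair_fixture(
      template_length = sample(90:140, 1), seed = 1000 + i,
      error_spec = if (i %% 2) list(n_sub = 2))
    total <- total + check_cgp_fixture(fx, strategy = "N")
  }
  expect_gt(total, 1000)  # spec-level property: >= 1000 cells, all exact
})
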