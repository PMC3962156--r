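test_that("FASTA reader parses, preserves gaps, and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "AC-GT"), f)
  expect_identical(read_fasta(f), c(s1 = "AC-GT"))

  set.seed(3)
  recs <- stats::setNames(
    vapply(1:100, function(i) random_dna_string(sample(10:200, 1)), ""),
    paste0("r", 1:100))
  recs[7] <- paste0(substr(recs[7], 1, 4), "--N-",
                    substr(recs[7], 5, nchar(recs[7])))
  write_fasta(recs, f, wrap_width = 37)
  expect_identical(read_fasta(f), recs)
})

test_that("FASTA reader rejects malformed input with line diagnostics", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate identifier 'a'")
  writeLines(c(">a", "ACGT", ">b", "ACJT"), f)
  expect_error(read_fasta(f), "invalid character on line 4")
})

test_that("trace documents round-trip through both dialects", {
  doc <- trace_doc("readX", "NNACGTNN", peak_index = cumsum(rep(10, 8)),
                   direction_hint = "FW")
  expect_identical(nchar(doc$base_calls), 8L)

  fj <- withr::local_tempfile(fileext = ".json")
  write_trace_doc(doc, fj, "json")
  expect_identical(read_trace_doc(fj, "json"), doc)

  fa <- withr::local_tempfile(fileext = ".ab1")
  write_trace_doc(doc, fa, "abif")
  back <- read_trace_doc(fa, "abif")
  expect_identical(back$base_calls, doc$base_calls)
  expect_identical(back$peak_index, doc$peak_index)

  # fixture-generated traces round-trip their call strings too
  fx <- generate_read_pair_fixture(seed = 5)
  write_trace_doc(fx$fw_trace, fa, "abif")
  expect_identical(read_trace_doc(fa, "abif")$base_calls, fx$fw_raw)
})

test_that("trace document invariants are enforced", {
  expect_error(trace_doc("r", ""), "non-empty")
  expect_error(trace_doc("r", "ACGT", peak_index = c(1, 2)),
               "one entry per base call")
  expect_error(trace_doc("r", "ACGT", peak_index = c(5, 4, 6, 7)),
               "strictly increasing")
  f <- withr::local_tempfile()
  jsonlite::write_json(list(read_id = "r", peak_index = 1:3), f,
                       auto_unbox = TRUE)
  expect_error(read_trace_doc(f, "json"), "no base_calls")
  writeLines("not an abif file at all, just text padding here", f)
  expect_error(read_trace_doc(f, "abif"), "not an ABIF")
})

test_that("newick wrapper validates and round-trips coalescent trees", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  expect_error(read_newick("((A:1,B:1):1,C:2;"), "unbalanced")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate leaf")

  set.seed(8)
  for (i in 1:50) {
    t1 <- sample_coalescent_tree(sample(4:30, 1))
    t2 <- read_newick(write_newick(t1))
    expect_setequal(t2$tip.label, t1$tip.label)
    expect_equal(sum(t2$edge.length), sum(t1$edge.length),
                 tolerance = 1e-9)
    expect_equal(rf_distance(t1, t2)[["absolute"]], 0)
  }
})

test_that("reports round-trip through text and tsv on random entries", {
  set.seed(21)
  rand_ref <- function() {
    k <- sample(3, 1)
    list(fw = if (k != 2) sample.int(900, 1) else NA_integer_,
         rv = if (k != 1) sample.int(900, 1) else NA_integer_)
  }
  acd_sites <- sample.int(5000, 100)
  psd_sites <- sample.int(5000, 100)
  acd <- lapply(1:100, function(i) {
    r <- rand_ref()
    acd_entry(paste0("seq", sample(50, 1)), acd_sites[i],
              sample(c("N", "R", "Y", "S", "W", "K", "M"), 1),
              fw = r$fw, rv = r$rv,
              changed_to = sample(c("?", "A", "T", "-"), 1))
  })
  psd <- lapply(1:100, function(i) {
    r <- rand_ref()
    counts <- c(A = sample.int(20, 1), C = sample(0:5, 1),
                G = sample(0:5, 1), T = 0L, gap = sample(0:10, 1))
    psd_entry(psd_sites[i], counts,
              suspects = list(list(seq_name = paste0("s", i),
                                   character = "G", fw = r$fw, rv = r$rv,
                                   changed_to = "?")),
              rule = sample(c("minority", "gap_dominated"), 1))
  })
  for (fmt in c("text", "tsv")) {
    f <- withr::local_tempfile()
    d1 <- report_doc("ACD", acd)
    write_report(d1, f, fmt)
    expect_equal(read_report(f), d1)
    d2 <- report_doc("PSD", psd, threshold = 0.1)
    write_report(d2, f, fmt)
    expect_equal(read_report(f), d2)
  }
})

test_that("malformed 'Changed To' values are rejected on parse", {
  f <- withr::local_tempfile()
  e <- acd_entry("seqX", 155, "Y", rv = 555)
  write_report(report_doc("ACD", list(e)), f, "text")
  txt <- sub("changed to: \\?", "changed to: J", readLines(f))
  writeLines(txt, f)
  expect_error(read_report(f), "Changed To")
})
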