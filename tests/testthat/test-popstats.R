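bm_from <- function(..., ancestral = "known") {
  binary_matrix(rbind(...), ancestral = ancestral)
}

test_that("binarisation maps majority to 0 with alphabetical tie-break", {
  aln <- rbind(s1 = c("A", "A", "A", "A"),
               s2 = c("A", "C", "G", "N"),
               s3 = c("G", "C", "-", "A"))
  bm <- binarize_msa(aln)
  expect_identical(bm$mat[, 1], c(s1 = 0L, s2 = 0L, s3 = 1L))
  expect_identical(bm$mat[, 2], c(s1 = 1L, s2 = 0L, s3 = 0L))  # C majority
  expect_identical(bm$mat[, 3], c(s1 = 0L, s2 = 1L, s3 = NA))
  expect_identical(bm$mat[, 4], c(s1 = 0L, s2 = NA, s3 = 0L))
  expect_identical(bm$ancestral, "majority")

  # two-state tie: alphabetically smaller nucleotide becomes 0
  tie <- binarize_msa(rbind(a = c("A"), b = c("G")))
  expect_identical(unname(tie$mat[, 1]), c(0L, 1L))

  # N as minor state when requested
  bm2 <- binarize_msa(aln, n_handling = "minor")
  expect_identical(bm2$mat[2, 4], c(s2 = 1L))
})

test_that("diversity statistics match hand-enumerated cases", {
  # one polymorphic column among 3 rows: 3 pairs, 2 differ
  bm <- bm_from(a = c(0L, 0L), b = c(0L, 0L), c = c(1L, 0L))
  st <- basic_diversity_stats(bm)
  expect_identical(st$S, 1L)
  expect_identical(st$singletons, 1L)
  expect_equal(st$theta_pi, 2 / 3)
  expect_equal(st$theta_w, 1 / (1 + 1 / 2))

  # Watterson at the published design point: S = 52, n = 100
  mat <- matrix(0L, 100, 52)
  mat[1, ] <- 1L
  expect_equal(basic_diversity_stats(binary_matrix(mat))$theta_w,
               52 / sum(1 / (1:99)), tolerance = 1e-12)
  expect_equal(52 / sum(1 / (1:99)), 10.0438, tolerance = 1e-4)

  # SFS sums to S and folded classes stay below n/2
  set.seed(81)
  m <- matrix(rbinom(20 * 40, 1, 0.3), 20, 40)
  st2 <- basic_diversity_stats(binary_matrix(m))
  expect_identical(sum(st2$sfs), st2$S)
  expect_identical(length(st2$sfs), 10L)
})

test_that("Tajima's D matches an independent constants calculation", {
  # n = 4, minor counts (1, 1, 2)
  bm <- bm_from(a = c(1L, 0L, 1L), b = c(0L, 1L, 1L),
                c = c(0L, 0L, 0L), d = c(0L, 0L, 0L))
  n <- 4; S <- 3
  a1 <- 1 + 1/2 + 1/3
  a2 <- 1 + 1/4 + 1/9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  pi_hand <- (2 * 1 * 3 + 2 * 1 * 3 + 2 * 2 * 2) / (4 * 3)
  d_hand <- (pi_hand - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  expect_equal(tajimas_d(bm), d_hand, tolerance = 1e-12)

  # no segregating sites: explicit not-a-value
  expect_true(is.na(tajimas_d(bm_from(a = 0L, b = 0L))))

  # theta_pi == theta_w numerically gives D = 0: with n = 4,
  # 8 singleton + 3 doubleton columns yield theta_pi = theta_w = 6
  m2 <- cbind(matrix(rep(c(1L, 0L, 0L, 0L), 8), 4),
              matrix(rep(c(1L, 1L, 0L, 0L), 3), 4))
  rownames(m2) <- letters[1:4]
  bm2 <- binary_matrix(m2)
  st2 <- basic_diversity_stats(bm2)
  expect_equal(st2$theta_pi, st2$theta_w)
  expect_equal(tajimas_d(bm2), 0)
})

test_that("neutral simulations give near-zero mean Tajima's D", {
  set.seed(82)
  d <- replicate(400, {
    tajimas_d(simulate_infinite_sites(sample_coalescent_tree(30), 8))
  })
  expect_gt(mean(d, na.rm = TRUE), -0.3)
  expect_lt(mean(d, na.rm = TRUE), 0.1)
})

test_that("ZnS equals brute-force r-squared averages", {
  # perfectly correlated pair and perfectly repulsed pair both give 1
  expect_equal(zns(bm_from(a = c(1L, 1L), b = c(1L, 1L),
                           c = c(0L, 0L), d = c(0L, 0L))), 1)
  expect_equal(zns(bm_from(a = c(1L, 0L), b = c(1L, 0L),
                           c = c(0L, 1L), d = c(0L, 1L))), 1)
  # a mixed pair against direct computation
  m <- rbind(a = c(1L, 1L), b = c(1L, 0L), c = c(0L, 1L), d = c(0L, 0L),
             e = c(1L, 1L), f = c(0L, 0L))
  expect_equal(zns(binary_matrix(m)), cor(m[, 1], m[, 2])^2)
  expect_true(is.na(zns(bm_from(a = c(1L), b = c(0L)))))
})

test_that("Fay-Wu H uses true ancestral states and the singleton closed form", {
  n <- 6
  mat <- matrix(0L, n, 4)
  mat[1, ] <- 1L  # every derived allele a singleton
  bm <- binary_matrix(mat, ancestral = "known")
  st <- basic_diversity_stats(bm)
  theta_h <- 2 * 4 / (n * (n - 1))
  expect_equal(fay_wu_h(bm), st$theta_pi - theta_h)
  expect_true(is.na(fay_wu_h(binary_matrix(mat, ancestral = "majority"))))
})

test_that("multi-locus summaries average and skip undefined loci", {
  set.seed(83)
  b1 <- simulate_infinite_sites(sample_coalescent_tree(20), 10)
  b2 <- simulate_infinite_sites(sample_coalescent_tree(20), 10)
  one <- multilocus_summaries(list(b1))
  expect_equal(one$theta_w, basic_diversity_stats(b1)$theta_w)
  two <- multilocus_summaries(list(b1, b2))
  expect_equal(two$theta_pi,
               mean(c(basic_diversity_stats(b1)$theta_pi,
                      basic_diversity_stats(b2)$theta_pi)))
  # a locus with S = 0 drops out of the ZnS average with a logged count
  b0 <- binary_matrix(matrix(0L, 20, 3), ancestral = "known")
  three <- multilocus_summaries(list(b1, b0))
  expect_identical(unname(three$n_dropped["zns"]), 1)
  expect_equal(three$theta_w, basic_diversity_stats(b1)$theta_w / 2)
})
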