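test_that("IGR size classes reproduce the published five-category counts", {
  gaps <- preceding_gaps(chrM1_table(), 31099L)
  cls <- classify_igr(gaps[gaps > 0])
  expect_equal(as.vector(table(factor(cls, c("I", "II", "III", "IV", "V")))),
               c(11L, 5L, 7L, 6L, 4L))
  expect_equal(classify_igr(1791L), "V")
  expect_equal(classify_igr(c(1L, 20L, 66L, 109L, 198L, 426L, 592L,
                              1108L, 1496L)),
               c("I", "I", "II", "II", "III", "III", "IV", "IV", "V"))
  expect_equal(classify_igr(50L), "unbinned")   # between classes I and II
  expect_equal(classify_igr(2500L), "unbinned") # beyond class V
  expect_equal(classify_igr(0L), "zero")
  expect_error(classify_igr(-1L), "negative")
  # total and idempotent: classifying any length twice gives the same class
  lens <- 0:2000
  expect_identical(classify_igr(lens), classify_igr(lens))
  expect_true(all(classify_igr(lens) %in%
                    c("zero", "I", "II", "III", "IV", "V", "unbinned")))
})

test_that("IGR extraction tiles the circle and attaches sequence", {
  tab <- chrM1_table()
  igrs <- extract_igrs(tab, 31099L)
  expect_equal(sum(igrs$length > 0), 33L)
  expect_equal(sum(igrs$length), 14064L)
  expect_equal(sum(igrs$length) + sum(feature_length(tab, 31099L)), 31099L)
  # the IGR before rnl wraps the origin: 30877..31099
  first <- igrs[igrs$downstream_gene == "rnl", ]
  expect_equal(c(first$start, first$end, first$length),
               c(30877L, 31099L, 223L))
  # a single gene covering the full circle leaves no IGR
  one <- feature_table(data.frame(gene = "g", start = 1L, end = 300L),
                       L = 300L)
  expect_equal(sum(extract_igrs(one, 300L)$length), 0L)
  # sequences attach and have the right lengths
  set.seed(71)
  chrom <- circular_chromosome("c", 200L, random_dna(200))
  t2 <- feature_table(data.frame(gene = c("a", "b"),
                                 start = c(10L, 120L), end = c(80L, 190L)),
                      chromosome_id = "c", L = 200L)
  ig2 <- extract_igrs(t2, chrom)
  nz <- ig2[ig2$length > 0, ]
  expect_equal(nchar(nz$sequence), nz$length)
})

test_that("planted terminal repeats are found exactly", {
  set.seed(81)
  core <- random_dna(100)
  arm <- "ACGTTGCAGCAT"
  tdr <- find_terminal_repeats(paste0(arm, core, arm), "direct",
                               min_len = 10, max_mismatch_frac = 0)
  expect_equal(nrow(tdr), 1L)
  expect_equal(tdr$arm_len, 12L)
  expect_equal(tdr$mismatches, 0L)
  expect_equal(c(tdr$a_start, tdr$b_end), c(1L, 124L))
  tir <- find_terminal_repeats(paste0(arm, core, revcomp(arm)), "inverted",
                               min_len = 10, max_mismatch_frac = 0)
  expect_equal(nrow(tir), 1L)
  expect_equal(tir$arm_len, 12L)
  expect_equal(c(tir$a_start, tir$b_end), c(1L, 124L))
  # an imperfect 3' copy is still found within the mismatch budget
  arm2 <- paste0(substr(arm, 1, 5), "A", substr(arm, 7, 12))
  imp <- find_terminal_repeats(paste0(arm, core, arm2), "direct",
                               min_len = 10, max_mismatch_frac = 0.15)
  expect_true(any(imp$arm_len >= 12 & imp$mismatches <= 1))
  # too short a sequence returns empty, not an error
  expect_equal(nrow(find_terminal_repeats("ACGTACG", "direct")), 0L)
})

test_that("repeat finder equals the brute-force oracle on seeded cases", {
  set.seed(91)
  for (case in 1:60) {
    n <- sample(20:40, 1)
    s <- random_dna(n)
    if (case %% 3 == 0) {           # plant an arm to make hits common
      arm <- random_dna(sample(6:10, 1))
      s <- paste0(arm, substr(s, 1, n - 2 * nchar(arm)),
                  if (case %% 2) arm else revcomp(arm))
    }
    for (mode in c("direct", "inverted")) {
      got <- find_terminal_repeats(s, mode, min_len = 6,
                                   max_mismatch_frac = 0)
      want <- oracle_terminal_repeats(s, mode, min_len = 6,
                                      max_mismatch_frac = 0)
      expect_equal(as.data.frame(got), want, info = paste(mode, case, s))
    }
  }
  # and with a nonzero mismatch budget
  set.seed(92)
  for (case in 1:20) {
    s <- random_dna(36)
    for (mode in c("direct", "inverted")) {
      got <- find_terminal_repeats(s, mode, min_len = 6,
                                   max_mismatch_frac = 0.2)
      want <- oracle_terminal_repeats(s, mode, min_len = 6,
                                      max_mismatch_frac = 0.2)
      expect_equal(as.data.frame(got), want, info = paste(mode, case, s))
    }
  }
})

test_that("direct-mode hits mirror their coordinates on the reverse complement", {
  set.seed(101)
  for (i in 1:10) {
    s <- paste0("ACGTTGCAGCAT", random_dna(60), "ACGTTGCAGCAT")
    n <- nchar(s)
    f <- find_terminal_repeats(s, "direct", min_len = 10,
                               max_mismatch_frac = 0)
    r <- find_terminal_repeats(revcomp(s), "direct", min_len = 10,
                               max_mismatch_frac = 0)
    expect_equal(nrow(f), nrow(r))
    if (nrow(f)) {
      # arms never exceed bounds
      expect_true(all(f$a_start >= 1 & f$b_end <= n))
      # the 5' arm of the forward scan maps onto the 3' arm of the
      # reverse-complement scan
      expect_setequal(n - f$b_end + 1L, r$a_start)
      expect_setequal(n - f$a_start + 1L, r$b_end)
    }
  }
})

test_that("tandem motif arrays are reported maximally and canonically", {
  set.seed(111)
  flank <- random_dna(60)
  flank2 <- random_dna(60)
  hit <- find_tandem_motifs(paste0(flank, strrep("CCAA", 7), flank2),
                            min_copies = 5)
  expect_true(any(hit$motif == canonical_motif("CCAA") &
                    hit$copies == 7))
  poly <- find_tandem_motifs(strrep("T", 11), motif_len_range = 1,
                             min_copies = 5)
  expect_equal(poly$kind, "homopolymer")
  expect_equal(poly$copies, 11L)
  expect_equal(poly$motif, "T")
  # random sequences match the brute-force enumeration
  set.seed(112)
  for (i in 1:6) {
    s <- random_dna(500)
    got <- find_tandem_motifs(s, 1:6, min_copies = 3)
    want <- oracle_tandem_motifs(s, 1:6, min_copies = 3)
    expect_equal(as.data.frame(got), want, info = i)
  }
})

test_that("OLS of counts on length matches the closed form and is stable", {
  r <- suppressWarnings(regress_counts_on_length(1:5, 2 * (1:5) + 1))
  expect_equal(r$r_squared, 1.0)
  expect_equal(r$slope, 2.0)
  x <- c(12, 40, 95, 210, 333, 520)
  y <- c(1, 2, 6, 9, 14, 20)
  got <- regress_counts_on_length(x, y)
  want <- oracle_ols(x, y)
  expect_equal(got$slope, want$slope)
  expect_equal(got$intercept, want$intercept)
  expect_equal(got$r_squared, want$r_squared)
  expect_equal(got$f_statistic, want$f_statistic)
  expect_equal(got$p_value, want$p_value)
  # invariant to reordering of the (x, y) pairs
  ord <- c(4, 1, 6, 2, 5, 3)
  got2 <- regress_counts_on_length(x[ord], y[ord])
  expect_equal(got2$slope, got$slope)
  expect_equal(got2$r_squared, got$r_squared)
  expect_error(regress_counts_on_length(c(1, 2), c(1, 2)), "at least 3")
  expect_error(regress_counts_on_length(c(2, 2, 2), c(1, 2, 3)),
               "degenerate")
})

test_that("MITE candidates require terminal TIRs plus a target-site duplication", {
  set.seed(121)
  arm <- "GCATTACGGTCA"
  elem <- paste0(arm, random_dna(80), revcomp(arm))
  tsd <- "TACGG"
  hit <- mite_candidates(elem, paste0(random_dna(20), tsd),
                         paste0(tsd, random_dna(20)))
  expect_gte(nrow(hit), 1L)
  expect_equal(hit$tsd[1], tsd)
  # no terminal TIR, no candidate
  none <- mite_candidates(random_dna(100), random_dna(20), random_dna(20))
  expect_equal(nrow(none), 0L)
})
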