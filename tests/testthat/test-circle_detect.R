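test_that("terminal overlaps are trimmed, longest first", {
  tr <- trim_terminal_overlap("ACGTTTACG", min_k = 3)
  expect_true(tr$circular)
  expect_equal(tr$sequence, "ACGTTT")
  expect_equal(tr$overlap, 3L)
  set.seed(131)
  circ <- random_dna(291)
  contig <- paste0(circ, substr(circ, 1, 55))
  tr2 <- trim_terminal_overlap(contig)
  expect_true(tr2$circular)
  expect_equal(nchar(tr2$sequence), 291L)
  expect_equal(tr2$sequence, circ)
  expect_false(trim_terminal_overlap(random_dna(200))$circular)
  expect_false(trim_terminal_overlap("ACGT", min_k = 3)$circular)
})

test_that("canonical rotation is strand- and rotation-invariant", {
  expect_equal(canonical_rotation("CAB"), "ABC")
  set.seed(141)
  s <- random_dna(140)
  forms <- vapply(c(1, 20, 77, 139), function(k)
    canonical_rotation(paste0(substr(s, k + 1, 140), substr(s, 1, k))),
    "")
  expect_true(all(forms == canonical_rotation(s)))
  expect_equal(canonical_rotation(revcomp(s)), canonical_rotation(s))
  expect_equal(canonical_rotation(canonical_rotation(s)),
               canonical_rotation(s))  # idempotent
  for (i in 1:20) {
    z <- random_dna(sample(8:30, 1))
    expect_equal(canonical_rotation(z), oracle_canonical(z))
  }
})

test_that("reads map onto circles with wraparound coordinates", {
  set.seed(151)
  circ <- random_dna(291)
  rot <- paste0(substr(circ, 51, 291), substr(circ, 1, 50))
  aln <- map_reads(c(r = substr(rot, 1, 150)), circ)
  expect_equal(aln$start, 51L)
  expect_equal(aln$mismatches, 0L)
  # a read crossing the origin
  tail_read <- paste0(substr(circ, 200, 291), substr(circ, 1, 58))
  aln2 <- map_reads(c(r = tail_read), circ)
  expect_equal(aln2$start, 200L)
  expect_true(aln2$spans_origin)
  expect_equal(junction_support(aln2), 1L)
  # reverse-complement reads map on the minus strand
  aln3 <- map_reads(c(r = revcomp(substr(rot, 1, 150))), circ)
  expect_equal(aln3$strand, "-")
  expect_equal(aln3$start, 51L)
  # unrelated reads are unmapped
  aln4 <- map_reads(c(bad = random_dna(150)), circ)
  expect_equal(nrow(aln4), 0L)
  expect_equal(attr(aln4, "unmapped"), "bad")
})

test_that("mapped positions of a uniform error-free library are uniform", {
  set.seed(161)
  circ <- random_dna(291)
  cfg <- sim_config(seed = 161, error_rate = 0, read_length = 100,
                    insert_mean = 200, insert_sd = 10)
  rs <- simulate_reads(circular_chromosome("c", 291L, circ), cfg,
                       depth = 350)
  reads <- c(rs$read1, rs$read2)
  expect_gte(length(reads), 1000L)
  aln <- map_reads(reads, circ)
  expect_equal(nrow(aln), length(reads))  # 100% mapped
  bins <- cut(aln$start, breaks = seq(0, 291, length.out = 10))
  p <- chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("junction support behaves on circular, linear and empty input", {
  set.seed(171)
  circ <- random_dna(300)
  cfg <- sim_config(seed = 171, error_rate = 0)
  rs <- simulate_reads(circular_chromosome("c", 300L, circ), cfg,
                       depth = 50)
  aln <- map_reads(c(rs$read1, rs$read2), circ)
  js <- junction_support(aln)
  expect_gt(js, 0L)
  # expectation ~ depth * (readlen - 2*anchor) / readlen
  expected <- 50 * (150 - 40) / 150
  expect_gt(js, expected / 3)
  expect_lt(js, expected * 3)
  # reads from the linearized molecule never span
  rsl <- simulate_reads(circular_chromosome("c", 300L, circ), cfg,
                        depth = 50, circular = FALSE)
  alnl <- map_reads(c(rsl$read1, rsl$read2), circ)
  expect_equal(junction_support(alnl), 0L)
  # empty alignments and an over-long anchor
  empty <- aln[0, ]
  attr(empty, "L") <- 300L
  expect_equal(junction_support(empty), 0L)
  expect_warning(out <- junction_support(aln, anchor = 151L),
                 "anchor")
  expect_equal(out, 0L)
})

test_that("mean depth is total aligned bases over circle length", {
  aln <- data.frame(read = paste0("r", 1:10),
                    start = seq(1, 300, length.out = 10),
                    len = 150L, strand = "+", mismatches = 0L,
                    spans_origin = FALSE)
  attr(aln, "L") <- 300L
  d <- mean_depth(aln)
  expect_equal(d$mean, 5.0)  # 10 * 150 / 300
  empty <- aln[0, ]; attr(empty, "L") <- 300L
  expect_equal(mean_depth(empty)$mean, 0)
  # simulated library lands near its nominal depth
  set.seed(181)
  circ <- random_dna(400)
  cfg <- sim_config(seed = 181, error_rate = 0)
  rs <- simulate_reads(circular_chromosome("c", 400L, circ), cfg,
                       depth = 100)
  aln2 <- map_reads(c(rs$read1, rs$read2), circ)
  expect_equal(mean_depth(aln2)$mean, 100, tolerance = 0.1)
})

test_that("flank diversity separates circles from embedded tandem arrays", {
  set.seed(191)
  circ <- random_dna(291)
  contig <- paste0(circ, substr(circ, 1, 55))
  cfg <- sim_config(seed = 191, error_rate = 0)
  rs <- simulate_reads(circular_chromosome("c", 291L, circ), cfg,
                       depth = 80)
  fd <- flank_diversity(c(rs$read1, rs$read2), contig)
  expect_equal(as.integer(fd), 0L)
  expect_gt(attr(fd, "n_overhangs"), 0L)
  # three copies embedded in a 4 kb host: genomic flanks appear
  host <- paste0(random_dna(2000), strrep(circ, 3), random_dna(2000))
  rsh <- simulate_reads(circular_chromosome("h", nchar(host), host), cfg,
                        depth = 80)
  fdh <- flank_diversity(c(rsh$read1, rsh$read2), contig)
  expect_gte(as.integer(fdh), 1L)
  # no overhanging reads at all: zero with a low-evidence warning
  expect_warning(fd0 <- flank_diversity(c(r = substr(circ, 30, 120)),
                                        contig),
                 "low evidential")
  expect_equal(as.integer(fd0), 0L)
})

test_that("the verdict rule table is applied as specified", {
  ev <- function(js, fd) circle_evidence("x", 291L, js, fd, 100)
  expect_equal(call_circle(ev(40L, 0L))$verdict, "circular")
  expect_equal(call_circle(ev(40L, 2L))$verdict, "tandem_array")
  expect_equal(call_circle(ev(0L, 2L))$verdict, "linear")
  expect_equal(call_circle(ev(0L, 0L))$verdict, "ambiguous")
  expect_equal(call_circle(ev(2L, 0L))$verdict, "ambiguous")
  expect_equal(call_circle(ev(3L, 0L))$verdict, "circular")  # threshold
  expect_equal(call_circle(ev(5L, 0L), min_support = 10L)$verdict,
               "ambiguous")
})

test_that("NUMT discrimination follows coverage, frame and identity rules", {
  hits <- data.frame(
    query_id = c("nd4l_chr1", "mt_gene", "grey_zone"),
    identity = c(92, 100, 97),
    hit_length = c(74L, 291L, NA),
    coverage = c(NA, NA, 0.96),
    frameshift_or_internal_stop = c(FALSE, FALSE, FALSE))
  hits$coverage[1:2] <- hits$hit_length[1:2] / 291
  out <- numt_classify(hits, full_gene_length = 291L)
  expect_equal(out$label,
               c("numt_pseudogene", "organellar_candidate", "ambiguous"))
  # a frameshift forces the pseudogene label even at full coverage
  fs <- numt_classify(data.frame(identity = 99, coverage = 1,
                                 frameshift_or_internal_stop = TRUE),
                      291L)
  expect_equal(fs$label, "numt_pseudogene")
})

test_that("SAM alignments import as an alternative evidence source", {
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:circ\tLN:291",
           "r1\t0\tcirc\t51\t60\t150M\t*\t0\t0\t*\t*",
           "r2\t16\tcirc\t280\t60\t30M\t*\t0\t0\t*\t*",
           "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  aln <- read_sam_alignments(path, L = 291L)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$start, c(51L, 280L))
  expect_equal(aln$strand, c("+", "-"))
  expect_true(aln$spans_origin[2])  # 280 + 30 - 1 = 309 > 291
  expect_equal(attr(aln, "unmapped"), "r3")
  expect_equal(junction_support(aln, anchor = 10L), 1L)
})

test_that("the full evidence chain calls a synthetic microDNA circular", {
  set.seed(201)
  circ <- random_dna(291)
  contig <- paste0(circ, substr(circ, 1, 55))
  cfg <- sim_config(seed = 201, error_rate = 0)
  rs <- simulate_reads(circular_chromosome("m", 291L, circ), cfg,
                       depth = 100)
  ev <- evaluate_contig(contig, c(rs$read1, rs$read2), "m")
  expect_equal(ev$verdict, "circular")
  expect_equal(ev$circular_length, 291L)
  expect_equal(ev$mean_depth, 100, tolerance = 0.1)
  # with 1% read error the defaults still hold at 50x
  cfg2 <- sim_config(seed = 202, error_rate = 0.01)
  rs2 <- simulate_reads(circular_chromosome("m", 291L, circ), cfg2,
                        depth = 50)
  ev2 <- evaluate_contig(contig, c(rs2$read1, rs2$read2), "m")
  expect_equal(ev2$verdict, "circular")
})
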