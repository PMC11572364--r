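test_that("the generator is fully deterministic under its seed", {
  cfg <- sim_config(seed = 7, error_rate = 0.01,
                    microdna_lengths = c(m = 291L),
                    layout = list(genes = data.frame(
                      gene = c("g1", "g2"), class = c("protein", "tRNA"),
                      length = c(300L, 72L), start_codon = c("AUG", NA),
                      stop_codon = c("UAA", NA)),
                      igr_lengths = c(40L, 25L)))
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$chromosomes[[1]]$sequence,
                   b$chromosomes[[1]]$sequence)
  expect_identical(a$chromosomes[["m"]]$sequence,
                   b$chromosomes[["m"]]$sequence)
  ra <- simulate_reads(a$chromosomes[[1]], cfg, depth = 20)
  rb <- simulate_reads(b$chromosomes[[1]], cfg, depth = 20)
  expect_identical(ra$read1, rb$read1)
  expect_identical(ra$read2, rb$read2)
  # and FASTQ bytes round-trip identically
  p1 <- tempfile(fileext = ".fastq"); p2 <- tempfile(fileext = ".fastq")
  write_fastq(ra$read1, p1); write_fastq(rb$read1, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(read_fastq(p1), ra$read1)
})

test_that("the published-layout genome satisfies every structural contract", {
  cfg <- sim_config(seed = 13)
  sim <- simulate_genome(cfg)
  chrom <- sim$chromosomes[[1]]
  tab <- sim$tables[[1]]
  expect_equal(chrom$length, 31099L)
  expect_equal(nchar(chrom$sequence), 31099L)
  # conservation and the published gap multiset
  expect_equal(sum(feature_length(tab, 31099L)) +
                 sum(preceding_gaps(tab, 31099L)), 31099L)
  expect_identical(preceding_gaps(tab, 31099L), chrM1_igr_column())
  # every protein feature is a valid ORF under the mitochondrial code,
  # with the annotated start and stop codons
  prot <- tab[tab$class == "protein", ]
  for (i in seq_len(nrow(prot))) {
    cds <- extract_feature_sequence(chrom, prot[i, ])
    tr <- translate_cds(cds)
    expect_equal(tr$aa_length, prot$aa_length[i])
    expect_equal(tr$start_codon, prot$start_codon[i])
    expect_equal(tr$stop_codon, prot$stop_codon[i])
  }
  # overall composition lands near the configured skew targets
  cc <- composition(chrom$sequence)
  expect_equal(cc$at_skew, cfg$at_skew, tolerance = 0.15)
  expect_equal(cc$gc_skew, cfg$gc_skew, tolerance = 0.15)
  # microDNA circles carry what they should
  expect_equal(sim$chromosomes[["chrM2"]]$length, 291L)
  expect_equal(sim$chromosomes[["chrM3"]]$length, 140L)
  tr2 <- translate_cds(sim$chromosomes[["chrM2"]]$sequence)
  expect_equal(tr2$aa_length, 96L)
})

test_that("a minimal one-gene layout yields a gap-free circle", {
  cfg <- sim_config(seed = 3, microdna_lengths = integer(0),
                    layout = list(genes = data.frame(
                      gene = "solo", class = "protein", length = 300L,
                      start_codon = "AUG", stop_codon = "UAA"),
                      igr_lengths = 0L))
  sim <- simulate_genome(cfg)
  expect_equal(sim$chromosomes[[1]]$length, 300L)
  expect_equal(sum(preceding_gaps(sim$tables[[1]], 300L)), 0L)
})

test_that("read counts, depth and wraparound match the library contract", {
  cfg <- sim_config(seed = 23, error_rate = 0, insert_mean = 300,
                    insert_sd = 0)
  circ <- circular_chromosome("c", 300L,
                              simulate_genome(sim_config(
                                seed = 23, microdna_lengths = integer(0),
                                layout = list(genes = data.frame(
                                  gene = "g", class = "noncoding",
                                  length = 300L), igr_lengths = 0L)
                              ))$chromosomes[[1]]$sequence)
  rs <- simulate_reads(circ, cfg, depth = 10)
  expect_equal(length(rs$read1), 10L)  # 10 * 300 / (2 * 150)
  expect_true(all(nchar(c(rs$read1, rs$read2)) == 150L))
  aln <- map_reads(c(rs$read1, rs$read2), circ$sequence)
  expect_equal(mean_depth(aln)$mean, 10.0)
  # molecules shorter than the insert wrap repeatedly
  tiny <- circular_chromosome("t", 140L, paste(
    sample(c("A", "C", "G", "T"), 140, replace = TRUE), collapse = ""))
  rs2 <- simulate_reads(tiny, cfg, depth = 30)
  aln2 <- map_reads(c(rs2$read1, rs2$read2), tiny$sequence)
  expect_equal(nrow(aln2), length(rs2$read1) * 2L)
})

test_that("the realized substitution rate matches the configured error rate", {
  cfg <- sim_config(seed = 33, error_rate = 0.01, insert_mean = 300,
                    insert_sd = 10)
  set.seed(33)
  circ <- circular_chromosome("c", 1000L, paste(
    sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""))
  rs <- simulate_reads(circ, cfg, depth = 101)
  ext <- strrep(circ$sequence, 3)
  mm <- 0L; total <- 0L
  for (i in seq_along(rs$read1)) {
    u <- rs$truth$frag_start[i]; ins <- rs$truth$insert[i]
    true1 <- substr(ext, u, u + 150 - 1)
    true2 <- revcomp(substr(ext, u + ins - 150, u + ins - 1))
    mm <- mm + sum(utf8ToInt(rs$read1[[i]]) != utf8ToInt(true1)) +
      sum(utf8ToInt(rs$read2[[i]]) != utf8ToInt(true2))
    total <- total + 300L
  }
  expect_gte(total, 1e5)
  expect_gte(mm / total, 0.008)
  expect_lte(mm / total, 0.012)
})

test_that("planted artifacts round-trip through the detectors", {
  cfg <- sim_config(seed = 43, error_rate = 0, host_length = 6000L,
                    tandem_copies = 3L, microdna_lengths = c(m = 291L),
                    layout = list(genes = data.frame(
                      gene = c("a", "b", "c"), class = "tRNA",
                      length = c(72L, 72L, 72L)),
                      igr_lengths = c(700L, 650L, 900L)))
  sim <- plant_artifacts(simulate_genome(cfg), n_tdr_igrs = 2L,
                         n_tir_igrs = 1L, arm_len = 14L,
                         arm_mismatches = 1L)
  chrom <- sim$chromosomes[[1]]
  expect_equal(nrow(sim$truth$repeats), 3L)
  for (i in seq_len(nrow(sim$truth$repeats))) {
    tru <- sim$truth$repeats[i, ]
    igr_seq <- substr(chrom$sequence, tru$igr_start, tru$igr_end)
    mode <- if (tru$kind == "TDR") "direct" else "inverted"
    hits <- find_terminal_repeats(igr_seq, mode, min_len = 10,
                                  max_mismatch_frac = 0.1)
    expect_true(any(hits$a_start == 1L & hits$arm_len >= tru$arm_len &
                      hits$mismatches <= tru$mismatches),
                info = paste(tru$kind, i))
  }
  # the tandem decoy is never called circular
  rs <- simulate_reads(sim$chromosomes[["host"]], cfg, depth = 60)
  ev <- evaluate_contig(sim$truth$tandem_decoys$contig,
                        c(rs$read1, rs$read2), "decoy")
  expect_false(ev$verdict == "circular")
  # the NUMT copy classifies as a pseudogene from its recorded summary
  lab <- numt_classify(sim$truth$numts, full_gene_length = 291L)
  expect_equal(lab$label, "numt_pseudogene")
  # and the planted fragment really is in the host at the recorded spot
  frag <- substr(sim$chromosomes[["host"]]$sequence,
                 sim$truth$numts$host_pos,
                 sim$truth$numts$host_pos + sim$truth$numts$hit_length - 1)
  unit <- sim$chromosomes[["m"]]$sequence
  src <- substr(unit, sim$truth$numts$source_offset,
                sim$truth$numts$source_offset + nchar(frag) - 1)
  realized <- 1 - hamming_pub(frag, src) / nchar(frag)
  expect_equal(100 * realized, sim$truth$numts$identity)
})
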