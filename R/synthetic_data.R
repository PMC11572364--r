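# Seeded generator of ground-truthed inputs: circular chromosomes with a
# realistic feature layout, composition-targeted sequence, valid ORFs,
# planted terminal repeats, microDNA circles, tandem-array decoys, NUMT
# copies, and paired-end reads with wraparound across the circular origin.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator, with defaults
#' matching the study conditions the package models: a ~31 kb circular main
#' chromosome with the published 34-feature layout, microDNA circles of
#' 291 and 140 bp, 2 x 150 bp paired-end reads at several-hundred-fold
#' depth, and overall composition targeting the main chromosome's printed
#' skews (AT-skew -0.1677, GC-skew 0.2362, GC 38.2%).
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param layout \code{"published"} (the bundled 34-feature annotation of the
#'   31,099 bp chromosome) or a list with \code{genes} (data.frame:
#'   \code{gene}, \code{class}, \code{length}, optional
#'   \code{start_codon}/\code{stop_codon}) and \code{igr_lengths} (gap
#'   before each gene, recycled).
#' @param at_skew,gc_skew,gc_percent composition targets for generated
#'   non-coding sequence.
#' @param skew_tol acceptance tolerance on realized segment skews
#'   (default 0.02).
#' @param microdna_lengths lengths of generated microDNA circles.
#' @param read_length,insert_mean,insert_sd,error_rate,depth read-library
#'   parameters (2 x 150 bp paired, inward mates, substitution errors).
#' @param assembler_overlap terminal overlap length appended to contigs to
#'   emulate looped de novo assembly of circular molecules.
#' @param tandem_copies,host_length tandem-decoy construction: copies of a
#'   unit embedded in a random host of this length.
#' @param numt_fraction,numt_subst fraction of a gene copied into the host
#'   and its substitution rate, for NUMT emulation.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       layout = "published",
                       at_skew = -0.1677, gc_skew = 0.2362,
                       gc_percent = 38.2, skew_tol = 0.02,
                       microdna_lengths = c(chrM2 = 291L, chrM3 = 140L),
                       read_length = 150L, insert_mean = 350,
                       insert_sd = 35, error_rate = 0.01, depth = 400,
                       assembler_overlap = 55L,
                       tandem_copies = 3L, host_length = 10000L,
                       numt_fraction = 0.25, numt_subst = 0.08) {
  stopifnot(is.numeric(seed), seed == as.integer(seed),
            read_length > 0, depth > 0, host_length > 0)
  structure(as.list(environment()), class = "sim_config")
}

# base probabilities reproducing target skews and GC%
skew_base_probs <- function(at_skew, gc_skew, gc_percent) {
  gc <- gc_percent / 100
  c(A = (1 - gc) * (1 + at_skew) / 2,
    C = gc * (1 - gc_skew) / 2,
    G = gc * (1 + gc_skew) / 2,
    T = (1 - gc) * (1 - at_skew) / 2)
}

# sample a sequence of length n whose realized skews fall within tol of the
# targets (rejection with a retry cap; the closest draw wins if the cap is
# hit, which only happens for very short segments)
random_seq_skewed <- function(n, probs, at_target, gc_target, tol = 0.02,
                              max_tries = 200L) {
  best <- NULL; best_dev <- Inf
  for (k in seq_len(max_tries)) {
    v <- sample(names(probs), n, replace = TRUE, prob = probs)
    a <- sum(v == "A"); t <- sum(v == "T")
    g <- sum(v == "G"); c <- sum(v == "C")
    dev <- max(abs(at_skew(a, t) - at_target),
               abs(gc_skew(g, c) - gc_target), na.rm = TRUE)
    if (is.na(dev)) dev <- Inf
    if (dev < best_dev) { best <- v; best_dev <- dev }
    if (best_dev <= tol) break
  }
  paste(best, collapse = "")
}

# all 64 RNA codons and the sense subset under a code
codon_space <- function(code = mito_genetic_code()) {
  names(code)[code != "*"]
}

# generate a CDS of nt_len with given start/stop codons, internal codons
# drawn with per-base probabilities (stops excluded); always a valid ORF
random_cds <- function(nt_len, start_codon = "AUG", stop_codon = "UAA",
                       probs, code = mito_genetic_code()) {
  stopifnot(nt_len %% 3 == 0, nt_len >= 6)
  sense <- codon_space(code)
  rna_probs <- stats::setNames(probs, chartr("T", "U", names(probs)))
  w <- vapply(sense, function(cd) {
    b <- strsplit(cd, "")[[1]]
    prod(rna_probs[b])
  }, numeric(1))
  k <- nt_len / 3 - 2L
  internal <- if (k > 0) sample(sense, k, replace = TRUE, prob = w) else
    character(0)
  rna <- paste(c(start_codon, internal, stop_codon), collapse = "")
  chartr("U", "T", rna)
}

published_layout <- function() {
  path <- system.file("extdata", "lhypogea_chrM1_genes.tsv",
                      package = "mitosplit")
  read_gene_table(path, chromosome_id = "chrM1", L = 31099L)
}

#' Simulate a circular genome with a ground-truthed feature table
#'
#' Generates the main circular chromosome (and microDNA circles): each
#' protein feature becomes a valid ORF under the mitochondrial code (start
#' and stop codons as annotated, no internal stops), every other segment is
#' drawn to hit the configured composition targets within the skew
#' tolerance. The feature table satisfies the conservation invariant
#' (feature lengths + gaps = L) by construction.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{sim_genome}: \code{chromosomes} (named list
#'   of \code{circular_chromosome}), \code{tables} (named list of
#'   \code{feature_table}), \code{truth} (planted-element inventory,
#'   grown by \code{\link{plant_artifacts}}).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  probs <- skew_base_probs(config$at_skew, config$gc_skew,
                           config$gc_percent)

  if (identical(config$layout, "published")) {
    tab <- published_layout()
    L <- 31099L
  } else {
    genes <- config$layout$genes
    igr <- rep_len(as.integer(config$layout$igr_lengths),
                   nrow(genes))
    start <- integer(nrow(genes)); end <- integer(nrow(genes))
    pos <- 1L
    for (i in seq_len(nrow(genes))) {
      pos <- pos + igr[i]
      start[i] <- pos
      end[i] <- pos + genes$length[i] - 1L
      pos <- end[i] + 1L
    }
    L <- pos - 1L
    df <- data.frame(gene = genes$gene, class = genes$class,
                     start = start, end = end, strand = "H",
                     start_codon = genes$start_codon %||% NA_character_,
                     stop_codon = genes$stop_codon %||% NA_character_,
                     wraps = FALSE, stringsAsFactors = FALSE)
    tab <- feature_table(df, chromosome_id = "sim_chr", L = L)
  }

  seq_chars <- rep("N", L)
  fill <- function(start, end, s) {
    stopifnot(nchar(s) == end - start + 1L)
    seq_chars[start:end] <<- strsplit(s, "")[[1]]
  }
  for (i in seq_len(nrow(tab))) {
    len <- feature_length(tab[i, ], L)
    if (tab$class[i] == "protein") {
      s <- random_cds(len,
                      start_codon = tab$start_codon[i] %|NA|% "AUG",
                      stop_codon = tab$stop_codon[i] %|NA|% "UAA",
                      probs = probs)
    } else {
      s <- random_seq_skewed(len, probs, config$at_skew, config$gc_skew,
                             config$skew_tol)
    }
    fill(tab$start[i], tab$end[i], s)
  }
  # fill the gaps (IGRs)
  igrs <- extract_igrs(tab, L)
  for (i in which(igrs$length > 0L)) {
    s <- random_seq_skewed(igrs$length[i], probs, config$at_skew,
                           config$gc_skew, config$skew_tol)
    a <- igrs$start[i]; b <- igrs$end[i]
    if (a <= b) fill(a, b, s) else {
      fill(a, L, substr(s, 1L, L - a + 1L))
      fill(1L, b, substr(s, L - a + 2L, nchar(s)))
    }
  }
  main_id <- attr(tab, "chromosome_id")
  chroms <- list()
  chroms[[main_id]] <- circular_chromosome(
    main_id, L, paste(seq_chars, collapse = ""))
  tables <- stats::setNames(list(tab), main_id)

  # microDNA circles: an ORF filling the first, a tRNA-like gene plus a
  # short noncoding tract for subsequent ones (mirrors a 291 bp
  # single-ORF circle and a 140 bp tRNA + 67 bp spacer circle)
  md <- config$microdna_lengths
  truth_micro <- list()
  for (j in seq_along(md)) {
    id <- names(md)[j] %||% paste0("microdna", j)
    ml <- as.integer(md[[j]])
    if (ml %% 3 == 0 && ml >= 60) {
      s <- random_cds(ml, "AUG", "UAG", probs)
      gt <- feature_table(data.frame(gene = paste0("orf_", id),
                                     class = "protein", start = 1L,
                                     end = ml, strand = "H",
                                     start_codon = "AUG",
                                     stop_codon = "UAG", wraps = FALSE),
                          chromosome_id = id, L = ml)
    } else {
      gene_len <- min(73L, ml - 1L)
      s <- random_seq_skewed(ml, probs, config$at_skew, config$gc_skew,
                             config$skew_tol)
      gt <- feature_table(data.frame(gene = paste0("trn_", id),
                                     class = "tRNA", start = 1L,
                                     end = gene_len, strand = "H",
                                     wraps = FALSE),
                          chromosome_id = id, L = ml)
    }
    chroms[[id]] <- circular_chromosome(id, ml, s)
    tables[[id]] <- gt
    truth_micro[[id]] <- list(length = ml)
  }

  structure(list(chromosomes = chroms, tables = tables,
                 config = config,
                 truth = list(microdna = truth_micro, repeats = NULL,
                              tandem_decoys = NULL, numts = NULL)),
            class = "sim_genome")
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

# substitute m random positions (or apply a per-base rate) in a sequence
mutate_seq <- function(s, rate = NULL, n_subst = NULL) {
  v <- strsplit(s, "")[[1]]
  idx <- if (!is.null(n_subst)) {
    if (n_subst == 0) integer(0) else
      sample(base::length(v), min(n_subst, base::length(v)))
  } else {
    which(stats::runif(base::length(v)) < rate)
  }
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  list(seq = paste(v, collapse = ""), n = base::length(idx))
}

#' Plant repeats, tandem-array decoys and NUMT copies
#'
#' Adds ground-truthed artifacts to a simulated genome:
#' \itemize{
#'   \item imperfect terminal direct/inverted repeats written at the two
#'     termini of selected IGRs of the main chromosome (arm length and
#'     mismatch count recorded exactly);
#'   \item tandem-array decoys: a microDNA-sized unit repeated
#'     \code{tandem_copies} times inside a fresh random host chromosome --
#'     the negative control for circle calling;
#'   \item NUMT copies: a mutated fragment of a microDNA gene inserted into
#'     the host, with realized identity and coverage recorded.
#' }
#' Artifacts never overwrite annotated features: repeats go inside IGRs and
#' decoys/NUMTs live on a separate host chromosome.
#'
#' @param sim a \code{sim_genome} from \code{\link{simulate_genome}}.
#' @param n_tdr_igrs,n_tir_igrs how many of the largest IGRs receive a
#'   planted TDR / TIR (default 4 each).
#' @param arm_len planted arm length (default 14).
#' @param arm_mismatches substitutions introduced in the 3' arm copy
#'   (default 1).
#' @return The \code{sim_genome} with a \code{host} chromosome added and
#'   \code{truth$repeats}, \code{truth$tandem_decoys}, \code{truth$numts}
#'   filled; decoy contigs (with assembler-style terminal overlap) are in
#'   \code{truth$tandem_decoys$contig}.
#' @export
plant_artifacts <- function(sim, n_tdr_igrs = 4L, n_tir_igrs = 4L,
                            arm_len = 14L, arm_mismatches = 1L) {
  stopifnot(inherits(sim, "sim_genome"))
  config <- sim$config
  set.seed(config$seed + 1L)
  main_id <- names(sim$chromosomes)[1]
  chrom <- sim$chromosomes[[main_id]]
  tab <- sim$tables[[main_id]]
  L <- chrom$length
  v <- strsplit(chrom$sequence, "")[[1]]

  igrs <- extract_igrs(tab, chrom)
  igrs <- igrs[!is.na(igrs$start) & igrs$length >= 4L * arm_len &
                 igrs$start <= igrs$end, , drop = FALSE]
  igrs <- igrs[order(-igrs$length), , drop = FALSE]
  n_plant <- min(nrow(igrs), n_tdr_igrs + n_tir_igrs)
  rep_truth <- list()
  for (i in seq_len(n_plant)) {
    kind <- if (i <= n_tdr_igrs) "TDR" else "TIR"
    a <- igrs$start[i]; b <- igrs$end[i]
    arm <- paste(sample(c("A", "C", "G", "T"), arm_len, replace = TRUE),
                 collapse = "")
    mut <- mutate_seq(arm, n_subst = arm_mismatches)
    arm2 <- if (kind == "TDR") mut$seq else revcomp(mut$seq)
    v[a:(a + arm_len - 1L)] <- strsplit(arm, "")[[1]]
    v[(b - arm_len + 1L):b] <- strsplit(arm2, "")[[1]]
    rep_truth[[base::length(rep_truth) + 1L]] <- data.frame(
      kind = kind, igr_start = a, igr_end = b, arm_len = arm_len,
      mismatches = mut$n, upstream_gene = igrs$upstream_gene[i],
      stringsAsFactors = FALSE)
  }
  sim$chromosomes[[main_id]] <- circular_chromosome(
    main_id, L, paste(v, collapse = ""))
  sim$truth$repeats <- if (base::length(rep_truth))
    do.call(rbind, rep_truth) else NULL

  # host chromosome carrying a tandem-array decoy and a NUMT copy
  probs <- skew_base_probs(config$at_skew, config$gc_skew,
                           config$gc_percent)
  host <- strsplit(random_seq_skewed(config$host_length, probs,
                                     config$at_skew, config$gc_skew,
                                     config$skew_tol), "")[[1]]
  # The decoy unit is a fresh sequence (same size class as the first
  # microDNA, composition-matched), not a copy of it: the decoy is a
  # negative control and must not share reads with the genuine circle.
  gene_id <- names(sim$chromosomes)[2] %||% main_id
  gene_seq <- sim$chromosomes[[gene_id]]$sequence
  unit_len <- nchar(gene_seq)
  unit <- random_seq_skewed(unit_len, probs, config$at_skew,
                            config$gc_skew, config$skew_tol)
  array <- paste(rep(unit, config$tandem_copies), collapse = "")
  pos <- sample(seq(1000L, config$host_length - nchar(array) - 1000L), 1)
  host[pos:(pos + nchar(array) - 1L)] <- strsplit(array, "")[[1]]
  ov <- min(config$assembler_overlap, unit_len - 1L)
  decoy_contig <- paste0(unit, substr(unit, 1L, ov))
  sim$truth$tandem_decoys <- list(
    unit_id = "decoy_unit", unit_seq = unit, unit_length = unit_len,
    copies = config$tandem_copies, host_pos = pos, contig = decoy_contig)

  # NUMT: mutated internal fragment of the microDNA gene, inserted far
  # from the array; an internal fragment carries neither gene terminus,
  # so it cannot mimic junction evidence for the genuine circle
  frag_len <- max(30L, round(config$numt_fraction * unit_len))
  offset <- max(1L, floor((unit_len - frag_len) / 2))
  frag <- substr(gene_seq, offset, offset + frag_len - 1L)
  mut <- mutate_seq(frag, rate = config$numt_subst)
  npos <- if (pos > config$host_length / 2) 200L else
    config$host_length - frag_len - 200L
  host[npos:(npos + frag_len - 1L)] <- strsplit(mut$seq, "")[[1]]
  sim$truth$numts <- data.frame(
    source = gene_id, source_offset = offset, host_pos = npos,
    hit_length = frag_len,
    coverage = frag_len / unit_len,
    identity = 100 * (1 - mut$n / frag_len),
    frameshift_or_internal_stop = TRUE,  # fragment breaks the ORF frame
    stringsAsFactors = FALSE)

  sim$chromosomes[["host"]] <- circular_chromosome(
    "host", config$host_length, paste(host, collapse = ""))
  sim
}

#' Simulate a paired-end read library from circular molecules
#'
#' Fragments are drawn uniformly on each circle with wraparound across the
#' origin (fragments wrap repeatedly when the circle is shorter than the
#' insert); mates point inward; substitution errors are applied per base at
#' the configured rate. The pair count per molecule is
#' \code{round(depth * L / (2 * read_length))}.
#'
#' @param chromosomes named list of \code{circular_chromosome} (or a single
#'   one), or a named character vector of sequences.
#' @param config a \code{\link{sim_config}}; \code{depth},
#'   \code{read_length}, \code{insert_mean}, \code{insert_sd} and
#'   \code{error_rate} are used.
#' @param circular treat molecules as circular (default TRUE); FALSE
#'   simulates from the linear sequence with no wraparound.
#' @param depth override \code{config$depth}.
#' @return list of class \code{read_set}: \code{read1}, \code{read2}
#'   (named character vectors), \code{truth} (data.frame: read id, source
#'   molecule, fragment start, insert size).
#' @export
simulate_reads <- function(chromosomes, config, circular = TRUE,
                           depth = config$depth) {
  if (inherits(chromosomes, "circular_chromosome")) {
    chromosomes <- stats::setNames(list(chromosomes), chromosomes$id)
  }
  if (is.character(chromosomes)) {
    chromosomes <- lapply(seq_along(chromosomes), function(i)
      circular_chromosome(names(chromosomes)[i] %||% paste0("mol", i),
                          nchar(chromosomes[[i]]), chromosomes[[i]]))
    names(chromosomes) <- vapply(chromosomes, `[[`, "", "id")
  }
  set.seed(config$seed + 2L)
  rl <- config$read_length
  r1 <- character(0); r2 <- character(0)
  truth <- list()
  for (id in names(chromosomes)) {
    chrom <- chromosomes[[id]]
    L <- chrom$length
    n_pairs <- round(depth * L / (2 * rl))
    if (n_pairs == 0) next
    ins <- pmax(rl, round(stats::rnorm(n_pairs, config$insert_mean,
                                       config$insert_sd)))
    if (!circular) ins <- pmin(ins, L)
    u <- if (circular) sample.int(L, n_pairs, replace = TRUE) else
      vapply(ins, function(k) sample.int(max(1L, L - k + 1L), 1), 1L)
    copies <- ceiling((max(ins) + L) / L)
    ext <- paste(rep(chrom$sequence, copies), collapse = "")
    frag <- substring(ext, u, u + ins - 1L)
    m1 <- substring(frag, 1L, rl)
    m2 <- revcomp(substring(frag, ins - rl + 1L, ins))
    if (config$error_rate > 0) {
      m1 <- vapply(m1, function(s)
        mutate_seq(s, rate = config$error_rate)$seq, "", USE.NAMES = FALSE)
      m2 <- vapply(m2, function(s)
        mutate_seq(s, rate = config$error_rate)$seq, "", USE.NAMES = FALSE)
    }
    ids <- sprintf("%s_%06d", id, seq_len(n_pairs))
    names(m1) <- ids; names(m2) <- ids
    r1 <- c(r1, m1); r2 <- c(r2, m2)
    truth[[id]] <- data.frame(read = ids, molecule = id, frag_start = u,
                              insert = ins, stringsAsFactors = FALSE)
  }
  structure(list(read1 = r1, read2 = r2,
                 truth = do.call(rbind, truth)),
            class = "read_set")
}

#' Write / read paired FASTQ
#'
#' @param reads a \code{read_set} (or named character vector for single-end
#'   output).
#' @param path1,path2 output paths (\code{.gz} suffix enables gzip).
#' @return Invisibly, the path(s).
#' @export
write_fastq <- function(reads, path1, path2 = NULL) {
  dump <- function(v, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    q <- vapply(nchar(v), function(n)
      paste(rep("I", n), collapse = ""), "")
    writeLines(paste0("@", names(v), "\n", v, "\n+\n", q), con)
    invisible(path)
  }
  if (inherits(reads, "read_set")) {
    dump(reads$read1, path1)
    if (!is.null(path2)) dump(reads$read2, path2)
    invisible(c(path1, path2))
  } else {
    dump(reads, path1)
    invisible(path1)
  }
}

#' @rdname write_fastq
#' @param path FASTQ path (gzip accepted).
#' @return \code{read_fastq}: named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
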