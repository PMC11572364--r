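# Evidence chain for putative small extrachromosomal circular DNAs
# (microDNAs): terminal-overlap trimming of assembler contigs, wraparound
# read mapping, junction-spanning read support, flank diversity at contig
# termini, depth, and a circle / tandem-array / linear verdict.

#' Trim an assembler's terminal overlap from a circular contig
#'
#' De novo assemblers emit circular molecules as linear contigs whose start
#' is duplicated at the end ("looped" sequences). If the contig's prefix of
#' length >= \code{min_k} equals its suffix exactly, one copy is removed;
#' the longest qualifying overlap wins.
#'
#' @param contig nucleotide string.
#' @param min_k minimum overlap length considered evidence of circularity
#'   (default 20).
#' @return list with \code{circular} (logical); when TRUE also
#'   \code{sequence} (the trimmed circular sequence) and \code{overlap}
#'   (the removed length).
#' @export
trim_terminal_overlap <- function(contig, min_k = 20L) {
  n <- nchar(contig)
  if (n <= 2L * min_k) return(list(circular = FALSE))
  for (ov in seq(floor(n / 2), min_k)) {
    if (substr(contig, 1L, ov) == substr(contig, n - ov + 1L, n)) {
      return(list(circular = TRUE,
                  sequence = substr(contig, 1L, n - ov),
                  overlap = as.integer(ov)))
    }
  }
  list(circular = FALSE)
}

#' Canonical rotation of a circular sequence
#'
#' The lexicographically least rotation over both strands, so assemblies of
#' the same circle that start at arbitrary rotations (or on the opposite
#' strand) compare equal. Idempotent.
#'
#' @param circ nucleotide string (non-empty).
#' @return The canonical form.
#' @export
canonical_rotation <- function(circ) {
  stopifnot(nchar(circ) > 0)
  n <- nchar(circ)
  rots_of <- function(s) substring(paste0(s, s), 1:n, n:(2L * n - 1L))
  rc <- tryCatch(revcomp(circ), error = function(e) NULL)
  min(c(rots_of(circ), if (!is.null(rc)) rots_of(rc)))
}

hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

#' Map reads onto a circular sequence
#'
#' Exact-seed (k-mer) placement with Hamming-distance extension on the
#' doubled (or further repeated) sequence; coordinates are reported modulo
#' the circle length, so alignments may span the origin, and reads longer
#' than the circle wrap repeatedly. Substitution errors only -- this is a
#' deterministic toy mapper adequate for simulated libraries, not a general
#' read aligner; SAM alignments from an external mapper can be imported with
#' \code{\link{read_sam_alignments}} instead.
#'
#' @param reads named character vector of read sequences.
#' @param circ circular reference sequence (string).
#' @param seed_k exact seed length (default 15).
#' @param max_mismatch maximum substitutions over the full read (default 3).
#' @param seed_tries how many non-overlapping seed offsets to try per read
#'   (robustness to errors in the first seed; default 3).
#' @param both_strands also try the reverse complement of each read.
#' @return data.frame of class \code{circ_alignments} with columns
#'   \code{read}, \code{start} (1..L), \code{len}, \code{strand} (+/-),
#'   \code{mismatches}, \code{spans_origin}; attribute \code{unmapped}
#'   (read names). L is attached as attribute \code{L}.
#' @export
map_reads <- function(reads, circ, seed_k = 15L, max_mismatch = 3L,
                      seed_tries = 3L, both_strands = TRUE) {
  circ <- toupper(circ)
  L <- nchar(circ)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  max_rl <- max(nchar(reads), 0L)
  copies <- max(2L, ceiling((L + max_rl) / L) + 1L)
  ext <- paste(rep(circ, copies), collapse = "")
  k <- min(seed_k, L, if (max_rl > 0) max_rl else seed_k)
  # k-mer index over the first L start positions (all distinct placements)
  starts <- seq_len(min(L, nchar(ext) - k + 1L))
  kmers <- substring(ext, starts, starts + k - 1L)
  idx <- split(starts, kmers)

  rows <- list(); unmapped <- character(0)
  for (ri in seq_along(reads)) {
    r_fwd <- toupper(reads[[ri]])
    rl <- nchar(r_fwd)
    best <- NULL
    cands <- if (both_strands) c("+", "-") else "+"
    for (strand in cands) {
      r <- if (strand == "+") r_fwd else revcomp(r_fwd)
      offs <- unique(pmin(1L + (seq_len(seed_tries) - 1L) * k, rl - k + 1L))
      offs <- offs[offs >= 1L]
      places <- integer(0)
      for (o in offs) {
        hit <- idx[[substr(r, o, o + k - 1L)]]
        if (!is.null(hit)) {
          places <- c(places, ((hit - o) %% L) + 1L)
        }
      }
      for (p in sort(unique(places))) {
        ref <- substr(ext, p, p + rl - 1L)
        if (nchar(ref) < rl) next
        mm <- if (ref == r) 0L else hamming(ref, r)
        if (mm <= max_mismatch &&
            (is.null(best) || mm < best$mm)) {
          best <- list(p = p, mm = mm, strand = strand, len = rl)
          if (mm == 0L) break
        }
      }
      if (!is.null(best) && best$mm == 0L) break
    }
    if (is.null(best)) {
      unmapped <- c(unmapped, names(reads)[ri])
    } else {
      rows[[base::length(rows) + 1L]] <- data.frame(
        read = names(reads)[ri], start = best$p, len = best$len,
        strand = best$strand, mismatches = best$mm,
        spans_origin = best$p + best$len - 1L > L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (base::length(rows)) do.call(rbind, rows) else
    data.frame(read = character(), start = integer(), len = integer(),
               strand = character(), mismatches = integer(),
               spans_origin = logical())
  attr(out, "L") <- L
  attr(out, "unmapped") <- unmapped
  class(out) <- c("circ_alignments", "data.frame")
  out
}

#' Import alignments from a SAM file
#'
#' Minimal SAM text import as an alternative alignment source for the
#' evidence chain: uses POS, FLAG (strand, unmapped) and the aligned length
#' from the CIGAR M/=/X operations. Coordinates are folded onto 1..L.
#'
#' @param path SAM file path.
#' @param L circular reference length.
#' @return A \code{circ_alignments} data.frame (see \code{\link{map_reads}}).
#' @export
read_sam_alignments <- function(path, L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  rows <- list(); unmapped <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0) { unmapped <- c(unmapped, f[1]); next }
    cig <- gregexpr("[0-9]+[MIDNSHP=X]", f[6])[[1]]
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    len <- sum(as.integer(sub("[A-Z=]", "", ops[grepl("[M=X]$", ops)])))
    p <- ((as.integer(f[4]) - 1L) %% L) + 1L
    rows[[base::length(rows) + 1L]] <- data.frame(
      read = f[1], start = p, len = len,
      strand = if (bitwAnd(flag, 16L) > 0) "-" else "+",
      mismatches = NA_integer_,
      spans_origin = p + len - 1L > L, stringsAsFactors = FALSE)
  }
  out <- if (base::length(rows)) do.call(rbind, rows) else
    data.frame(read = character(), start = integer(), len = integer(),
               strand = character(), mismatches = integer(),
               spans_origin = logical())
  attr(out, "L") <- as.integer(L)
  attr(out, "unmapped") <- unmapped
  class(out) <- c("circ_alignments", "data.frame")
  out
}

#' Count junction-spanning reads
#'
#' The number of alignments crossing the circular origin (position L -> 1)
#' with at least \code{anchor} aligned bases on each side -- reads that can
#' only exist if the molecule is physically circular (or tandemly repeated).
#'
#' @param alignments a \code{circ_alignments} data.frame.
#' @param L circle length (default: taken from the alignments).
#' @param anchor minimum aligned bases required on each side of the
#'   junction (default 20).
#' @return Integer count.
#' @export
junction_support <- function(alignments, L = attr(alignments, "L"),
                             anchor = 20L) {
  if (nrow(alignments) == 0) return(0L)
  if (anchor >= max(alignments$len)) {
    warning("anchor >= read length; no read can qualify")
    return(0L)
  }
  left <- L - alignments$start + 1L
  right <- alignments$start + alignments$len - 1L - L
  sum(left >= anchor & right >= anchor)
}

#' Mean read depth over a circular sequence
#'
#' Per-base coverage averaged over all L positions, with its coefficient of
#' variation.
#'
#' @inheritParams junction_support
#' @return list with \code{mean} (fold coverage) and \code{cv}
#'   (sd/mean; NA when mean is 0).
#' @export
mean_depth <- function(alignments, L = attr(alignments, "L")) {
  if (nrow(alignments) == 0) return(list(mean = 0, cv = NA_real_))
  pos <- (rep(alignments$start - 1L, alignments$len) +
            sequence(alignments$len) - 1L) %% L + 1L
  cov <- tabulate(pos, nbins = L)
  m <- mean(cov)
  list(mean = m, cv = if (m > 0) stats::sd(cov) / m else NA_real_)
}

#' Flank diversity at contig termini
#'
#' For a true circle, every read overhanging an end of the (linear,
#' pre-trim) contig continues with the wraparound sequence from the other
#' end. Reads whose overhangs do \emph{not} match the wraparound
#' continuation betray flanking sequence -- a tandem array inside a longer
#' molecule, or a linear fragment. Overhangs are located by exact match of
#' a terminal anchor (a grep-like scan over raw reads), compared to the
#' wraparound expectation, and inconsistent ones are merged into classes;
#' the class count is returned. "Matches" tolerates sequencing error:
#' up to \code{max(1, ceiling(max_mismatch_frac * overhang length))}
#' substitutions, so a 1\% error library does not masquerade as flanking
#' diversity, while genuine genomic flanks (whose divergence from the
#' wraparound expectation is ~75\%) always register.
#'
#' The contig is supplied in linear (pre-trim) form; any assembler terminal
#' overlap is removed internally first, because the wraparound expectation
#' only makes sense on the circularized sequence.
#'
#' @param reads named character vector of read sequences.
#' @param contig contig string in linear (pre-trim) form.
#' @param anchor length of the terminal anchor matched exactly within reads
#'   (default 20).
#' @param both_strands also scan reverse complements.
#' @param trim_min_k minimum terminal overlap recognized when circularizing
#'   (as in \code{\link{trim_terminal_overlap}}).
#' @return Integer: number of distinct inconsistent extension classes, with
#'   attribute \code{n_overhangs} (total overhanging reads seen). Emits a
#'   low-evidence warning when no read overhangs a terminus.
#' @export
#' @param max_mismatch_frac substitution fraction tolerated when comparing
#'   an overhang to the wraparound expectation or to an existing class
#'   (default 0.05; at least 1 substitution is always allowed).
flank_diversity <- function(reads, contig, anchor = 20L,
                            both_strands = TRUE, trim_min_k = 20L,
                            max_mismatch_frac = 0.05) {
  contig <- toupper(contig)
  tr <- trim_terminal_overlap(contig, trim_min_k)
  if (tr$circular) contig <- tr$sequence
  L <- nchar(contig)
  stopifnot(L > anchor)
  P <- substr(contig, 1L, anchor)
  S <- substr(contig, L - anchor + 1L, L)
  n_overhangs <- 0L
  bad <- list()  # list of c(side, overhang)

  tol <- function(k) max(1L, ceiling(max_mismatch_frac * k))
  consistent <- function(overhang, side) {
    k <- min(nchar(overhang), L)
    if (side == "L") {
      ov <- substr(overhang, nchar(overhang) - k + 1L, nchar(overhang))
      exp <- substr(contig, L - k + 1L, L)
    } else {
      ov <- substr(overhang, 1L, k)
      exp <- substr(contig, 1L, k)
    }
    hamming(ov, exp) <= tol(k)
  }

  scan_read <- function(r) {
    i <- regexpr(P, r, fixed = TRUE)[1]
    if (i > 1L) {
      n_overhangs <<- n_overhangs + 1L
      ovh <- substr(r, 1L, i - 1L)
      if (!consistent(ovh, "L")) {
        bad[[base::length(bad) + 1L]] <<- c("L", ovh)
      }
    }
    j <- regexpr(S, r, fixed = TRUE)[1]
    if (j > 0L && j + anchor - 1L < nchar(r)) {
      n_overhangs <<- n_overhangs + 1L
      ovh <- substr(r, j + anchor, nchar(r))
      if (!consistent(ovh, "R")) {
        bad[[base::length(bad) + 1L]] <<- c("R", ovh)
      }
    }
  }
  for (r in reads) {
    r <- toupper(r)
    scan_read(r)
    if (both_strands) scan_read(revcomp(r))
  }
  if (n_overhangs == 0L) {
    warning("no read overhangs a contig terminus; flank diversity has ",
            "low evidential value")
  }
  # merge inconsistent overhangs into classes at <= 1 mismatch, aligned at
  # the terminus (left overhangs compare at their right end)
  classes <- list()
  for (b in bad) {
    side <- b[1]; ovh <- b[2]
    merged <- FALSE
    for (ci in seq_along(classes)) {
      cl <- classes[[ci]]
      if (cl[1] != side) next
      k <- min(nchar(ovh), nchar(cl[2]))
      if (k == 0L) next
      x <- if (side == "L") substr(ovh, nchar(ovh) - k + 1L, nchar(ovh)) else
        substr(ovh, 1L, k)
      y <- if (side == "L") substr(cl[2], nchar(cl[2]) - k + 1L,
                                   nchar(cl[2])) else substr(cl[2], 1L, k)
      if (hamming(x, y) <= tol(k)) {
        if (nchar(ovh) > nchar(cl[2])) classes[[ci]][2] <- ovh
        merged <- TRUE
        break
      }
    }
    if (!merged) classes[[base::length(classes) + 1L]] <- c(side, ovh)
  }
  structure(base::length(classes), n_overhangs = n_overhangs)
}

#' Circle evidence and verdict
#'
#' \code{circle_evidence} bundles the quantities the circularity decision
#' uses; \code{call_circle} applies the decision rule:
#' \itemize{
#'   \item \strong{circular}: junction support >= \code{min_support} and
#'     flank diversity 0 -- reads cross the origin and nothing flanks the
#'     sequence;
#'   \item \strong{tandem_array}: junction support >= \code{min_support}
#'     but flank diversity > 0 -- the unit repeats, yet genomic flanks
#'     appear;
#'   \item \strong{linear}: junction support < \code{min_support} and flank
#'     diversity > 0;
#'   \item \strong{ambiguous}: anything else (e.g. no junction reads and no
#'     flanks: not enough evidence either way).
#' }
#'
#' @param contig_id label.
#' @param circular_length trimmed circle length (bp).
#' @param junction_support integer junction-spanning read count.
#' @param flank_diversity integer inconsistent-extension class count.
#' @param mean_depth,depth_cv fold coverage and its CV.
#' @return \code{circle_evidence}: a list of class \code{circle_evidence}
#'   (verdict unset until \code{call_circle}).
#' @export
circle_evidence <- function(contig_id, circular_length, junction_support,
                            flank_diversity, mean_depth,
                            depth_cv = NA_real_) {
  stopifnot(junction_support >= 0, flank_diversity >= 0)
  structure(list(contig_id = contig_id,
                 circular_length = as.integer(circular_length),
                 junction_support = as.integer(junction_support),
                 flank_diversity = as.integer(flank_diversity),
                 mean_depth = mean_depth, depth_cv = depth_cv,
                 verdict = NA_character_),
            class = "circle_evidence")
}

#' @rdname circle_evidence
#' @param evidence a \code{circle_evidence} object.
#' @param min_support minimum junction-spanning reads (default 3).
#' @return \code{call_circle}: the evidence object with \code{verdict} set
#'   to one of circular / tandem_array / linear / ambiguous.
#' @export
call_circle <- function(evidence, min_support = 3L) {
  js <- evidence$junction_support
  fd <- evidence$flank_diversity
  evidence$verdict <-
    if (js >= min_support && fd == 0L) "circular"
    else if (js >= min_support && fd > 0L) "tandem_array"
    else if (js < min_support && fd > 0L) "linear"
    else "ambiguous"
  evidence
}

#' @export
print.circle_evidence <- function(x, ...) {
  cat(sprintf(
    "<circle_evidence> %s: %s bp | junction support %d | flank diversity %d | depth %.1fx | verdict: %s\n",
    x$contig_id, x$circular_length, x$junction_support, x$flank_diversity,
    x$mean_depth, ifelse(is.na(x$verdict), "(uncalled)", x$verdict)))
  invisible(x)
}

#' Run the full circularity evidence chain on one contig
#'
#' Trims the assembler terminal overlap, maps the reads onto the trimmed
#' circle, counts junction-spanning reads, measures flank diversity on the
#' pre-trim contig, estimates depth, and calls the verdict.
#'
#' @param contig assembled contig (linear string, possibly with terminal
#'   overlap).
#' @param reads named character vector of reads.
#' @param contig_id label.
#' @param min_k,anchor,min_support,seed_k,max_mismatch tuning knobs passed
#'   to the stages.
#' @return A called \code{circle_evidence}.
#' @export
evaluate_contig <- function(contig, reads, contig_id = "contig",
                            min_k = 20L, anchor = 20L, min_support = 3L,
                            seed_k = 15L, max_mismatch = 3L) {
  tr <- trim_terminal_overlap(contig, min_k)
  circ <- if (tr$circular) tr$sequence else contig
  aln <- map_reads(reads, circ, seed_k = seed_k, max_mismatch = max_mismatch)
  js <- junction_support(aln, anchor = anchor)
  dep <- mean_depth(aln)
  fd <- suppressWarnings(flank_diversity(reads, contig, anchor = anchor))
  ev <- circle_evidence(contig_id, nchar(circ), js, as.integer(fd),
                        dep$mean, dep$cv)
  call_circle(ev, min_support = min_support)
}

#' Discriminate organellar genes from nuclear mitochondrial insertions
#'
#' Applies rule-of-thumb thresholds to externally computed hit summaries
#' (e.g. BLAST results of a mitochondrial gene against a nuclear assembly):
#' a hit covering less than \code{min_coverage} of the gene, or carrying a
#' frameshift/internal stop, is a degenerate nuclear copy
#' (\code{numt_pseudogene}); a full-coverage, frame-intact hit at >=
#' \code{min_identity}\% identity is an \code{organellar_candidate};
#' anything else (e.g. near-full coverage with intermediate identity) is
#' \code{ambiguous}. The thresholds are heuristics, configurable per call.
#'
#' @param hits data.frame with columns \code{identity} (percent, 0--100)
#'   and either \code{coverage} (fraction of the gene, 0--1) or
#'   \code{hit_length} (bp, converted using \code{full_gene_length}); and
#'   optionally \code{frameshift_or_internal_stop} (logical, default FALSE).
#' @param full_gene_length length of the intact gene (bp).
#' @param min_coverage coverage below which a hit is pseudogenized
#'   (default 0.95).
#' @param min_identity identity required for an organellar candidate
#'   (default 98).
#' @return The hits data.frame with an added \code{label} column.
#' @export
numt_classify <- function(hits, full_gene_length, min_coverage = 0.95,
                          min_identity = 98) {
  if (is.null(hits$coverage)) {
    if (is.null(hits$hit_length)) stop("need coverage or hit_length")
    hits$coverage <- hits$hit_length / full_gene_length
  }
  if (is.null(hits$frameshift_or_internal_stop)) {
    hits$frameshift_or_internal_stop <- FALSE
  }
  stopifnot(all(hits$identity >= 0 & hits$identity <= 100),
            all(hits$coverage >= 0 & hits$coverage <= 1))
  hits$label <- ifelse(
    hits$coverage < min_coverage | hits$frameshift_or_internal_stop,
    "numt_pseudogene",
    ifelse(hits$identity >= min_identity, "organellar_candidate",
           "ambiguous"))
  hits
}
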