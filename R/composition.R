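#' Strand-asymmetry skews from base counts
#'
#' AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C). A zero
#' denominator yields \code{NA} (an explicit "undefined" marker, never 0);
#' aggregate statistics should skip it.
#'
#' @param a,c,g,t integer base counts (vectorized).
#' @return Numeric vector of skews in [-1, 1], or \code{NA} where undefined.
#' @export
at_skew <- function(a, t) ifelse(a + t == 0, NA_real_, (a - t) / (a + t))

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) ifelse(g + c == 0, NA_real_, (g - c) / (g + c))

#' Base composition and skew statistics of a sequence
#'
#' Counts bases, computes percentages, GC%, and AT/GC skews from the raw
#' counts (never from rounded percentages). \code{N} and other ambiguity
#' symbols count toward the length but are excluded from skew numerators and
#' denominators, and from GC%.
#'
#' @param seq nucleotide string (non-empty).
#' @return An object of class \code{composition_stats}: list with
#'   \code{counts} (named A,C,G,T,N), \code{pct} (percent of total length),
#'   \code{gc_percent}, \code{at_skew}, \code{gc_skew}, \code{length}.
#' @export
composition <- function(seq) {
  seq <- normalize_dna(seq)
  if (nchar(seq) == 0) stop("empty sequence")
  v <- strsplit(seq, "")[[1]]
  cnt <- c(A = sum(v == "A"), C = sum(v == "C"), G = sum(v == "G"),
           T = sum(v == "T"), N = sum(v == "N"))
  L <- length(v)
  structure(list(
    counts = cnt,
    pct = 100 * cnt / L,
    gc_percent = 100 * (cnt[["G"]] + cnt[["C"]]) / L,
    at_skew = at_skew(cnt[["A"]], cnt[["T"]]),
    gc_skew = gc_skew(cnt[["G"]], cnt[["C"]]),
    length = L), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "<composition_stats> %d bp | G %.1f%% A %.1f%% T %.1f%% C %.1f%% | GC %.1f%% | AT-skew %s GC-skew %s\n",
    x$length, x$pct[["G"]], x$pct[["A"]], x$pct[["T"]], x$pct[["C"]],
    x$gc_percent,
    if (is.na(x$at_skew)) "undef" else sprintf("%.4f", x$at_skew),
    if (is.na(x$gc_skew)) "undef" else sprintf("%.4f", x$gc_skew)))
  invisible(x)
}

#' Round half away from zero
#'
#' Report-style rounding (0.05 -> 0.1, -0.05 -> -0.1), as used in the printed
#' tables this package mirrors; R's \code{round()} rounds half to even.
#'
#' @param x numeric vector. @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Recover integer base counts from printed percentages
#'
#' Published composition tables print per-base percentages to one decimal.
#' For a known sequence length this inverts the rounding: it finds the
#' integer counts (G, A, T, C) that sum to the length while deviating least
#' from the printed percentages. Candidates for each base are the integers
#' within \code{tol} percentage points of the printed value, which also
#' absorbs tables whose printed percentage is off by one rounding unit (a
#' real occurrence in published tables); the count-sum constraint then
#' usually pins the combination down. An error is raised if no combination
#' sums to the length or the best-scoring combination is not unique.
#'
#' @param pct named numeric vector with elements \code{G,A,T,C} in percent.
#' @param length sequence length in bp.
#' @param tol per-base candidate window in percentage points (default 0.15,
#'   i.e. the rounding half-width plus one rounding unit).
#' @return Named integer vector of counts (G, A, T, C).
#' @export
counts_from_percentages <- function(pct, length, tol = 0.15) {
  stopifnot(all(c("G", "A", "T", "C") %in% names(pct)))
  length <- as.integer(length)
  cand <- lapply(pct[c("G", "A", "T", "C")], function(p) {
    k <- 0:length
    k[abs(100 * k / length - p) <= tol]
  })
  if (any(vapply(cand, base::length, 1L) == 0)) {
    stop("no integer count consistent with a printed percentage")
  }
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[rowSums(grid) == length, , drop = FALSE]
  if (nrow(grid) == 0) stop("no count combination sums to the length")
  dev <- rowSums(abs(100 * t(t(as.matrix(grid))) / length -
                       matrix(pct[c("G", "A", "T", "C")],
                              nrow(grid), 4, byrow = TRUE)))
  best <- which(dev == min(dev))
  if (base::length(best) > 1) stop("count combination is not unique")
  out <- as.integer(grid[best, ])
  names(out) <- c("G", "A", "T", "C")
  out
}

#' Build a sequence with prescribed base counts
#'
#' @param counts named integer vector with any of A, C, G, T (and N).
#' @return A single string with exactly those counts (bases in blocks; the
#'   order is irrelevant for count-based statistics).
#' @export
sequence_from_counts <- function(counts) {
  paste(rep(names(counts), counts), collapse = "")
}

# ---- genetic code and translation ------------------------------------------

#' Mitochondrial genetic code as a data table
#'
#' The mold/protozoan/coelenterate mitochondrial code (NCBI translation
#' table 4), the minimally derived code used for sponge mitochondria: UGA
#' encodes tryptophan; UAA/UAG are the stops. Exposed as a named character
#' vector keyed by RNA codons so alternative codes can be swapped in as data.
#'
#' @param id NCBI genetic-code id (default \code{"4"}).
#' @return Named character vector: 64 RNA codons to one-letter amino acids,
#'   with \code{"*"} for stops.
#' @export
mito_genetic_code <- function(id = "4") {
  code <- Biostrings::getGeneticCode(id)
  names(code) <- chartr("T", "U", names(code))
  code
}

dna_to_rna <- function(x) chartr("T", "U", normalize_dna(x))

#' Translate a mitochondrial CDS
#'
#' Translates a coding sequence under a mitochondrial genetic code
#' (default: table 4, where UGA = Trp). The sequence must be a whole ORF:
#' length divisible by 3, terminal codon a stop (UAA/UAG under table 4),
#' and no internal stop codons (the position of any internal stop is
#' reported in the error). GUG is accepted alongside AUG as an initiation
#' codon when \code{allow_alt_start} is set; the first residue is reported
#' as encoded (no Met override). Codons are reported in the RNA alphabet.
#'
#' @param cds nucleotide string (DNA or RNA alphabet).
#' @param allow_alt_start accept GUG (and AUA/UUG) initiation in addition to
#'   AUG.
#' @param code genetic code table from \code{\link{mito_genetic_code}}.
#' @return list with \code{protein} (stop excluded), \code{start_codon},
#'   \code{stop_codon} (RNA), \code{aa_length}.
#' @export
translate_cds <- function(cds, allow_alt_start = TRUE,
                          code = mito_genetic_code()) {
  rna <- dna_to_rna(cds)
  n <- nchar(rna)
  if (n %% 3 != 0) stop("CDS length ", n, " not divisible by 3")
  codons <- substring(rna, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(code[codons])
  if (anyNA(aa)) stop("codon with ambiguity symbol cannot be translated")
  k <- length(codons)
  if (aa[k] != "*") stop("missing terminal stop codon (saw ", codons[k], ")")
  internal <- which(aa[-k] == "*")
  if (length(internal)) {
    stop("internal stop codon ", codons[internal[1]], " at codon position ",
         internal[1], " (nt ", (internal[1] - 1) * 3 + 1, ")")
  }
  starts <- if (allow_alt_start) c("AUG", "GUG", "AUA", "UUG") else "AUG"
  if (!codons[1] %in% starts) {
    stop("unexpected initiation codon ", codons[1])
  }
  list(protein = paste(aa[-k], collapse = ""),
       start_codon = codons[1], stop_codon = codons[k],
       aa_length = k - 1L)
}

#' Codon usage over a set of coding sequences
#'
#' @param cds_set list or character vector of CDS strings; each must pass
#'   \code{\link{translate_cds}}.
#' @param allow_alt_start,code passed to \code{\link{translate_cds}}.
#' @return list of class \code{codon_usage}: \code{codon_counts} (named over
#'   the 64 RNA codons), \code{aa_counts}, \code{stop_counts}, and
#'   \code{aa_percent} (stops excluded from the denominator).
#' @export
codon_usage <- function(cds_set, allow_alt_start = TRUE,
                        code = mito_genetic_code()) {
  cds_set <- as.character(cds_set)
  counts <- stats::setNames(integer(length(code)), names(code))
  for (cds in cds_set) {
    translate_cds(cds, allow_alt_start, code)  # validation
    rna <- dna_to_rna(cds)
    n <- nchar(rna)
    codons <- substring(rna, seq(1, n, 3), seq(3, n, 3))
    tb <- table(codons)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  aa <- code[names(counts)]
  aa_counts <- c(tapply(counts, aa, sum))  # plain named vector
  stop_counts <- counts[aa == "*"]
  sense <- aa_counts[names(aa_counts) != "*"]
  structure(list(codon_counts = counts,
                 aa_counts = aa_counts,
                 stop_counts = stop_counts,
                 aa_percent = 100 * sense / sum(sense)),
            class = "codon_usage")
}

#' Amino-acid frequencies of translated proteins
#'
#' @param proteins character vector of one-letter protein strings (no stops).
#' @return Named numeric vector: percent usage per amino acid over all
#'   residues.
#' @export
aa_frequencies <- function(proteins) {
  v <- strsplit(paste(proteins, collapse = ""), "")[[1]]
  if (length(v) == 0) stop("no residues")
  tb <- table(v)
  stats::setNames(100 * as.numeric(tb) / length(v), names(tb))
}

#' Per-codon-position base composition
#'
#' For each CDS, the percentage of each base at codon positions 1, 2 and 3;
#' plus the across-gene mean and sample standard deviation per base and
#' position. The across-gene mean is unweighted (each gene contributes one
#' observation), matching the "mean +/- sd across genes" framing of
#' mitogenome reports; set \code{weighted = TRUE} for a codon-count-weighted
#' pool instead.
#'
#' @param cds_set character vector of CDSs (lengths divisible by 3).
#' @param weighted pool codons across genes instead of averaging per-gene
#'   percentages.
#' @return list of class \code{position_composition}: \code{per_gene} (array
#'   gene x position x base, percent), \code{mean} and \code{sd} (position x
#'   base matrices).
#' @export
codon_position_composition <- function(cds_set, weighted = FALSE) {
  cds_set <- as.character(cds_set)
  if (length(cds_set) == 0) stop("empty CDS set")
  bases <- c("A", "C", "G", "T")
  per_gene <- array(NA_real_, dim = c(length(cds_set), 3, 4),
                    dimnames = list(names(cds_set) %||%
                                      paste0("cds", seq_along(cds_set)),
                                    paste0("pos", 1:3), bases))
  pooled <- matrix(0, 3, 4, dimnames = list(paste0("pos", 1:3), bases))
  for (i in seq_along(cds_set)) {
    s <- normalize_dna(cds_set[i])
    n <- nchar(s)
    if (n %% 3 != 0) stop("CDS length not divisible by 3")
    v <- strsplit(s, "")[[1]]
    pos <- rep(1:3, length.out = n)
    for (p in 1:3) {
      vp <- v[pos == p]
      cnt <- vapply(bases, function(b) sum(vp == b), 0L)
      per_gene[i, p, ] <- 100 * cnt / length(vp)
      pooled[p, ] <- pooled[p, ] + cnt
    }
  }
  if (weighted) {
    mean_mat <- 100 * pooled / rowSums(pooled)
    sd_mat <- matrix(NA_real_, 3, 4, dimnames = dimnames(pooled))
  } else {
    mean_mat <- apply(per_gene, c(2, 3), mean)
    sd_mat <- apply(per_gene, c(2, 3), stats::sd)
  }
  structure(list(per_gene = per_gene, mean = mean_mat, sd = sd_mat),
            class = "position_composition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
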