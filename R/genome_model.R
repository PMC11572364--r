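#' Circular chromosome
#'
#' Container for a circular nucleotide molecule. Coordinates everywhere in the
#' package are 1-based inclusive on the heavy (H) strand, as in GenBank flat
#' files and published mitogenome annotation tables.
#'
#' @param id character label (e.g. \code{"chrM1"}).
#' @param length integer number of nucleotides (L).
#' @param sequence optional nucleotide string over \code{A,C,G,T,N}; \code{U}
#'   is mapped to \code{T} on input. When present its number of characters
#'   must equal \code{length}.
#' @return An object of class \code{circular_chromosome}: a list with fields
#'   \code{id}, \code{length}, \code{sequence} (or \code{NULL}) and
#'   \code{topology = "circular"}.
#' @export
circular_chromosome <- function(id, length, sequence = NULL) {
  length <- as.integer(length)
  stopifnot(is.character(id), length(id) == 1L, length >= 1L)
  if (!is.null(sequence)) {
    sequence <- normalize_dna(sequence)
    if (nchar(sequence) != length) {
      stop("sequence length (", nchar(sequence),
           ") does not match declared length (", length, ")")
    }
  }
  structure(list(id = id, length = length, sequence = sequence,
                 topology = "circular"),
            class = "circular_chromosome")
}

#' @export
print.circular_chromosome <- function(x, ...) {
  cat("<circular_chromosome> ", x$id, ": ", x$length, " bp",
      if (is.null(x$sequence)) " (no sequence)" else "", "\n", sep = "")
  invisible(x)
}

# Uppercase, U -> T, validate alphabet.
normalize_dna <- function(seq) {
  seq <- chartr("u", "U", toupper(seq))
  seq <- chartr("U", "T", seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (any(nzchar(bad))) {
    stop("non-IUPAC symbol(s) in sequence: ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
               collapse = ", "))
  }
  seq
}

#' Reverse complement of a DNA string
#'
#' @param seq nucleotide string (\code{A,C,G,T,N}; \code{U} accepted).
#' @return The reverse complement, uppercase DNA.
#' @export
revcomp <- function(seq) {
  seq <- normalize_dna(seq)
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a feature table
#'
#' An ordered table of gene annotations on one circular chromosome.
#' Internally a \code{data.frame} of class \code{feature_table} with columns
#' \code{gene}, \code{class} (one of protein/tRNA/rRNA/noncoding),
#' \code{start}, \code{end}, \code{strand} (H or L), \code{aa_length},
#' \code{start_codon}, \code{stop_codon} (RNA alphabet) and \code{wraps}
#' (does the feature cross the circular origin). Rows are kept sorted by
#' \code{start}.
#'
#' @param df data.frame with at least \code{gene}, \code{start}, \code{end};
#'   missing optional columns are filled with defaults (\code{class} inferred
#'   from the gene name, strand H, no wrap).
#' @param chromosome_id label of the chromosome the features live on.
#' @param L chromosome length; when supplied, coordinates are validated
#'   against it.
#' @param allow_overlap if \code{FALSE} (default) overlapping features are an
#'   error.
#' @return A \code{feature_table}.
#' @export
feature_table <- function(df, chromosome_id = "chr", L = NULL,
                          allow_overlap = FALSE) {
  stopifnot(is.data.frame(df), all(c("gene", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  n <- nrow(df)
  if (is.null(df$class)) df$class <- infer_gene_class(df$gene)
  if (is.null(df$strand)) df$strand <- rep("H", n)
  if (is.null(df$aa_length)) df$aa_length <- rep(NA_integer_, n)
  if (is.null(df$start_codon)) df$start_codon <- rep(NA_character_, n)
  if (is.null(df$stop_codon)) df$stop_codon <- rep(NA_character_, n)
  if (is.null(df$wraps)) df$wraps <- rep(FALSE, n)
  if (!all(df$strand %in% c("H", "L"))) {
    stop("unknown strand symbol: ",
         paste(setdiff(unique(df$strand), c("H", "L")), collapse = ", "))
  }
  if (!all(df$class %in% c("protein", "tRNA", "rRNA", "noncoding"))) {
    stop("unknown gene class")
  }
  if (anyDuplicated(df$start)) stop("duplicate gene start coordinate")
  bad <- !df$wraps & df$start > df$end
  if (any(bad)) {
    stop("start > end without wrap flag for: ",
         paste(df$gene[bad], collapse = ", "))
  }
  if (!is.null(L)) {
    L <- as.integer(L)
    if (any(df$start < 1L | df$start > L | df$end < 1L | df$end > L)) {
      stop("coordinates outside 1..", L)
    }
  }
  df <- df[order(df$start),
           c("gene", "class", "start", "end", "strand", "aa_length",
             "start_codon", "stop_codon", "wraps")]
  rownames(df) <- NULL
  tab <- structure(df, class = c("feature_table", "data.frame"),
                   chromosome_id = chromosome_id)
  if (!allow_overlap && !is.null(L)) {
    ov <- find_overlaps(tab, L)
    if (nrow(ov) > 0) {
      stop("overlapping features (use allow_overlap = TRUE to permit): ",
           paste(ov$gene_a, "/", ov$gene_b, collapse = "; "))
    }
  }
  tab
}

infer_gene_class <- function(gene) {
  ifelse(grepl("^trn", gene, ignore.case = TRUE), "tRNA",
         ifelse(tolower(gene) %in% c("rnl", "rns", "12s", "16s"), "rRNA",
                "protein"))
}

# Pairwise overlaps between circular features; returns zero-row data.frame
# when the table is non-overlapping.
find_overlaps <- function(table, L) {
  n <- nrow(table)
  cover <- function(i) {
    s <- table$start[i]; e <- table$end[i]
    if (!table$wraps[i]) s:e else c(s:L, 1:e)
  }
  out <- list()
  if (n >= 2) {
    occ <- lapply(seq_len(n), cover)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- length(intersect(occ[[i]], occ[[j]]))
        if (shared > 0) {
          out[[length(out) + 1L]] <- data.frame(
            gene_a = table$gene[i], gene_b = table$gene[j],
            overlap_bp = shared)
        }
      }
    }
  }
  if (length(out) == 0) {
    data.frame(gene_a = character(), gene_b = character(),
               overlap_bp = integer())
  } else {
    do.call(rbind, out)
  }
}

#' Length of a feature on a circular chromosome
#'
#' For a non-wrapping feature this is \code{end - start + 1}; a feature that
#' crosses the origin (\code{wraps = TRUE}, \code{start > end}) has length
#' \code{L - start + 1 + end}.
#'
#' @param f a one-row \code{feature_table} slice, or a list with
#'   \code{start}, \code{end}, \code{wraps}. Vectorized over rows.
#' @param L chromosome length.
#' @return Integer vector of lengths in bp.
#' @export
feature_length <- function(f, L) {
  L <- as.integer(L)
  start <- as.integer(f$start); end <- as.integer(f$end)
  wraps <- if (is.null(f$wraps)) rep(FALSE, length(start)) else f$wraps
  if (any(start < 1L | start > L | end < 1L | end > L)) {
    stop("coordinates outside 1..", L)
  }
  as.integer(ifelse(wraps, L - start + 1L + end, end - start + 1L))
}

#' Circular gap preceding each feature
#'
#' The number of unannotated positions strictly between the end of the
#' previous feature and the start of each feature, computed modulo L. The
#' first feature's gap reaches back across the circular origin to the last
#' feature; on a single-feature circle the gap is the whole unannotated
#' remainder.
#'
#' Published annotation tables for this kind of genome print this quantity as
#' the "intergenic region (bp)" column of each gene row; the semantics
#' (gap \emph{before} the gene) are inferred from the printed coordinates,
#' which they reproduce exactly.
#'
#' @param table a sorted, non-overlapping \code{feature_table}.
#' @param L chromosome length.
#' @return Integer vector of preceding gaps, one per feature (in table
#'   order). Overlapping features raise an error carrying the per-pair
#'   overlap report rather than returning negative gaps.
#' @export
preceding_gaps <- function(table, L) {
  L <- as.integer(L)
  n <- nrow(table)
  if (n == 0) return(integer(0))
  ov <- find_overlaps(table, L)
  if (nrow(ov) > 0) {
    cond <- structure(
      class = c("mitosplit_overlap_error", "error", "condition"),
      list(message = paste0("features overlap; gaps undefined (",
                            nrow(ov), " overlapping pair(s))"),
           call = sys.call(-1), overlaps = ov))
    stop(cond)
  }
  prev_end <- table$end[c(n, seq_len(n - 1L))]
  prev_end[1L] <- if (table$wraps[n]) table$end[n] else table$end[n]
  gap <- (table$start - prev_end - 1L) %% L
  # A single feature covering the full circle leaves no gap.
  if (n == 1L && feature_length(table[1L, ], L) == L) gap <- 0L
  as.integer(gap)
}

#' @rdname preceding_gaps
#' @param f a single feature (one-row slice) present in \code{table}.
#' @export
preceding_gap <- function(f, table, L) {
  gaps <- preceding_gaps(table, L)
  i <- match(f$start, table$start)
  if (is.na(i)) stop("feature not found in table")
  gaps[i]
}

#' Extract the sequence of a feature from a circular chromosome
#'
#' H-strand features are returned as-is; L-strand features are
#' reverse-complemented; features wrapping the origin concatenate the suffix
#' and prefix of the chromosome.
#'
#' @param chrom \code{circular_chromosome} with a sequence.
#' @param f one-row feature (list or data.frame row).
#' @return Nucleotide string.
#' @export
extract_feature_sequence <- function(chrom, f) {
  if (is.null(chrom$sequence)) stop("chromosome has no sequence")
  L <- chrom$length
  s <- as.integer(f$start); e <- as.integer(f$end)
  wraps <- isTRUE(f$wraps) || (s > e)
  if (s < 1 || s > L || e < 1 || e > L) stop("coordinates outside 1..", L)
  seq <- if (!wraps) {
    substr(chrom$sequence, s, e)
  } else {
    paste0(substr(chrom$sequence, s, L), substr(chrom$sequence, 1, e))
  }
  if (identical(f$strand, "L")) revcomp(seq) else seq
}

# ---- gene-table TSV I/O -----------------------------------------------------

CANONICAL_HEADER <- c("gene", "class", "start", "end", "strand",
                      "start_codon", "stop_codon", "wraps")

strip_thousands <- function(x) as.integer(gsub(",", "", x))

#' Read a gene annotation table
#'
#' Accepts either the package's canonical TSV schema
#' (\code{gene class start end strand start_codon stop_codon wraps}) or the
#' published-table schema
#' (\code{Gene Start End Length (bp) Aminoacid Start/Stop codon Intergenic
#' region (bp) Strand}). Thousands separators in coordinates are tolerated on
#' input and never emitted on output.
#'
#' @param path TSV file path.
#' @param chromosome_id label for the resulting table.
#' @param L optional chromosome length for coordinate validation.
#' @return A \code{feature_table}.
#' @export
read_gene_table <- function(path, chromosome_id = "chr", L = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  nm <- tolower(names(raw))
  if (all(CANONICAL_HEADER %in% nm)) {
    names(raw) <- nm
    df <- raw[, CANONICAL_HEADER]
    df$start <- strip_thousands(df$start)
    df$end <- strip_thousands(df$end)
    df$wraps <- as.logical(df$wraps)
    df$start_codon[df$start_codon %in% c("", "-", "–")] <- NA
    df$stop_codon[df$stop_codon %in% c("", "-", "–")] <- NA
    # amino-acid counts are not part of the canonical schema; for a valid
    # CDS they are determined by the length law aa = nt/3 - 1
    nt <- df$end - df$start + 1L
    nt[df$wraps] <- if (!is.null(L)) {
      L - df$start[df$wraps] + 1L + df$end[df$wraps]
    } else NA_integer_
    df$aa_length <- ifelse(df$class == "protein" & !is.na(nt) &
                             nt %% 3 == 0,
                           as.integer(nt / 3 - 1L), NA_integer_)
  } else if (any(grepl("^gene$", nm)) && any(grepl("strand", nm))) {
    df <- data.frame(gene = raw[[which(nm == "gene")[1]]],
                     start = strip_thousands(raw[[grep("^start$", nm)[1]]]),
                     end = strip_thousands(raw[[grep("^end$", nm)[1]]]),
                     strand = raw[[grep("strand", nm)[1]]],
                     stringsAsFactors = FALSE)
    aa_col <- grep("amino", nm)
    if (length(aa_col)) {
      aa <- gsub(",", "", raw[[aa_col[1]]])
      df$aa_length <- suppressWarnings(as.integer(aa))
    }
    cod_col <- grep("codon", nm)
    if (length(cod_col)) {
      cod <- raw[[cod_col[1]]]
      parts <- strsplit(cod, "/", fixed = TRUE)
      df$start_codon <- vapply(parts, function(p)
        if (length(p) == 2 && p[1] %in% c("AUG", "GUG", "AUA", "UUG"))
          p[1] else NA_character_, character(1))
      df$stop_codon <- vapply(parts, function(p)
        if (length(p) == 2) p[2] else NA_character_, character(1))
    }
    df$wraps <- df$start > df$end
  } else {
    stop("unrecognized gene-table header: ", paste(names(raw), collapse = ", "))
  }
  feature_table(df, chromosome_id = chromosome_id, L = L)
}

#' @rdname read_gene_table
#' @param table a \code{feature_table} to write.
#' @export
write_gene_table <- function(table, path) {
  df <- as.data.frame(table)[, CANONICAL_HEADER]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# ---- FASTA I/O (Biostrings-backed) -----------------------------------------

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings, returning plain named character vectors so
#' downstream string code stays simple. Output is wrapped at 70 columns.
#'
#' @param path FASTA file path.
#' @return \code{read_fasta}: named character vector of uppercase DNA.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  vapply(out, normalize_dna, character(1))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# ---- minimal GenBank flat-file reader --------------------------------------

#' Read a minimal GenBank flat file
#'
#' Parses only what circular mitogenome records need: the LOCUS line (length
#' and topology), CDS/tRNA/rRNA features with simple \code{start..end} or
#' \code{complement(start..end)} locations, the \code{/gene} (or
#' \code{/product}) qualifier, and the ORIGIN sequence block. Joins and fuzzy
#' ends are out of scope and raise an error.
#'
#' @param path GenBank flat-file path.
#' @return list with \code{chromosome} (a \code{circular_chromosome}) and
#'   \code{features} (a \code{feature_table}).
#' @export
read_genbank_minimal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) != 1) stop("expected exactly one LOCUS line")
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  len <- as.integer(toks[which(toks == "bp") - 1L])
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (length(feat_start) == 0) stop("no FEATURES block")

  fend <- if (length(origin_start)) origin_start[1] - 1L else length(lines)
  flines <- lines[(feat_start[1] + 1L):fend]
  keys <- grepl("^     \\S", flines)
  idx <- which(keys)
  feats <- list()
  for (k in seq_along(idx)) {
    first <- trimws(flines[idx[k]])
    parts <- strsplit(first, "\\s+")[[1]]
    key <- parts[1]
    if (!key %in% c("CDS", "tRNA", "rRNA")) next
    loc <- parts[2]
    last <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
    quals <- trimws(flines[(idx[k] + 1L):last])
    if (grepl("join|order|<|>", loc)) {
      stop("unsupported location (joins/fuzzy ends): ", loc)
    }
    strand <- "H"
    if (grepl("^complement\\(", loc)) {
      strand <- "L"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
    gq <- grep('^/gene="', quals, value = TRUE)
    if (!length(gq)) gq <- grep('^/product="', quals, value = TRUE)
    gene <- if (length(gq)) sub('^/[a-z]+="(.*)"$', "\\1", gq[1]) else
      paste0(key, "_", se[1])
    feats[[length(feats) + 1L]] <- data.frame(
      gene = gene,
      class = c(CDS = "protein", tRNA = "tRNA", rRNA = "rRNA")[[key]],
      start = se[1], end = se[2], strand = strand,
      wraps = se[1] > se[2], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)

  sequence <- NULL
  if (length(origin_start)) {
    send <- grep("^//", lines)
    send <- if (length(send)) send[1] - 1L else length(lines)
    seqlines <- lines[(origin_start[1] + 1L):send]
    sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seqlines, collapse = "")))
  }
  chrom <- circular_chromosome(id, len, sequence)
  if (topology != "circular") chrom$topology <- topology
  list(chromosome = chrom,
       features = feature_table(df, chromosome_id = id, L = len))
}
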