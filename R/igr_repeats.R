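#' Intergenic-region size classes
#'
#' The five observed size categories of mitogenomic IGRs: I (very short,
#' 1--20 bp), II (short, 66--109 bp), III (intermediate, 198--426 bp),
#' IV (long, 592--1,108 bp), V (very long, 1,496--1,791 bp). The classes are
#' the observed ranges and leave gaps between them; lengths falling in a gap
#' (or beyond class V) are reported as \code{"unbinned"} rather than snapped
#' to the nearest class, so published per-class counts remain exactly
#' reproducible and novel data are never silently misbinned. Length 0 is
#' \code{"zero"}.
#'
#' @param length integer vector of IGR lengths (>= 0).
#' @return Character vector of classes in
#'   \code{\{I, II, III, IV, V, unbinned, zero\}}.
#' @export
classify_igr <- function(length) {
  length <- as.integer(length)
  if (any(length < 0)) stop("negative IGR length")
  lo <- c(1L, 66L, 198L, 592L, 1496L)
  hi <- c(20L, 109L, 426L, 1108L, 1791L)
  cls <- c("I", "II", "III", "IV", "V")
  out <- rep("unbinned", base::length(length))
  out[length == 0L] <- "zero"
  for (k in seq_along(cls)) {
    out[length >= lo[k] & length <= hi[k]] <- cls[k]
  }
  out
}

#' Extract intergenic regions from a feature table
#'
#' One record per inter-feature gap (including explicit zero-length
#' records), with circular coordinates: the IGR preceding the first feature
#' wraps across the origin. The total IGR length equals
#' \code{L - sum(feature lengths)} for a non-overlapping table.
#'
#' @param table sorted non-overlapping \code{feature_table}.
#' @param chrom \code{circular_chromosome}, or an integer length L. When a
#'   chromosome with sequence is supplied the IGR sequences are attached.
#' @return data.frame with columns \code{chromosome_id}, \code{start},
#'   \code{end}, \code{length}, \code{upstream_gene}, \code{downstream_gene},
#'   \code{size_class}, and \code{sequence} (NA when no sequence available).
#'   Zero-length gaps carry \code{start = end = NA}.
#' @export
extract_igrs <- function(table, chrom) {
  if (inherits(chrom, "circular_chromosome")) {
    L <- chrom$length
  } else {
    L <- as.integer(chrom)
    chrom <- NULL
  }
  gaps <- preceding_gaps(table, L)
  n <- nrow(table)
  prev <- c(n, seq_len(n - 1L))
  start <- ifelse(gaps > 0L, (table$end[prev] %% L) + 1L, NA_integer_)
  end <- ifelse(gaps > 0L, (table$start - 2L) %% L + 1L, NA_integer_)
  out <- data.frame(
    chromosome_id = attr(table, "chromosome_id") %||% "chr",
    start = as.integer(start), end = as.integer(end),
    length = gaps,
    upstream_gene = table$gene[prev],
    downstream_gene = table$gene,
    size_class = classify_igr(gaps),
    sequence = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(chrom) && !is.null(chrom$sequence)) {
    for (i in which(out$length > 0L)) {
      f <- list(start = out$start[i], end = out$end[i],
                wraps = out$start[i] > out$end[i], strand = "H")
      out$sequence[i] <- extract_feature_sequence(chrom, f)
    }
  }
  out
}

# ---- terminal repeat finder -------------------------------------------------

#' Find imperfect terminal direct or inverted repeats
#'
#' Searches for pairs of similar arms near the two termini of a sequence:
#' direct repeats (TDRs; the 3' arm repeats the 5' arm) or inverted repeats
#' (TIRs; the 3' arm is the reverse complement of the 5' arm). Arms must be
#' at least \code{min_len} long (default 10 bp); "imperfect" means up to
#' \code{floor(max_mismatch_frac * arm_length)} substitutions under Hamming
#' distance (no indels), which keeps the detector deterministic and
#' exactly checkable against a brute-force enumeration. The 5' arm must start
#' within \code{terminal_window} of the 5' terminus and the 3' arm must end
#' within \code{terminal_window} of the 3' terminus; arms may not overlap.
#' Only maximal-extension arms are reported: a valid arm pair is suppressed
#' when its span is contained in a longer valid arm pair on the same
#' alignment diagonal. Hits are ordered by 5' arm position (left to right),
#' longest first on ties.
#'
#' @param seq nucleotide string; sequences shorter than \code{2 * min_len}
#'   return an empty hit table.
#' @param mode \code{"direct"} or \code{"inverted"}.
#' @param min_len minimum arm length (bp).
#' @param max_mismatch_frac maximum substitution fraction per arm
#'   (default 0.1).
#' @param terminal_window fraction of the sequence length each arm may sit
#'   from its terminus (default 0.25).
#' @return data.frame of class \code{repeat_hits}: columns \code{kind}
#'   (TDR/TIR), \code{a_start}, \code{a_end}, \code{b_start}, \code{b_end}
#'   (both arms in forward coordinates), \code{arm_len},
#'   \code{mismatches}.
#' @export
find_terminal_repeats <- function(seq, mode = c("direct", "inverted"),
                                  min_len = 10L, max_mismatch_frac = 0.1,
                                  terminal_window = 0.25) {
  mode <- match.arg(mode)
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  empty <- data.frame(kind = character(), a_start = integer(),
                      a_end = integer(), b_start = integer(),
                      b_end = integer(), arm_len = integer(),
                      mismatches = integer())
  class(empty) <- c("repeat_hits", "data.frame")
  if (n < 2L * min_len) return(empty)
  x <- strsplit(seq, "")[[1]]
  y <- if (mode == "inverted") strsplit(revcomp(seq), "")[[1]] else x
  w <- max(ceiling(n * terminal_window), min_len)
  budget <- function(len) floor(max_mismatch_frac * len)
  hits <- list()
  # Enumerate diagonals: the y-arm starts at i + s for 5' arm start i.
  # Direct mode needs only s >= 1 (the match matrix is symmetric under
  # transposition and s = 0 is the trivial self-match); against the reverse
  # complement the matrix is instead symmetric under reflection within each
  # diagonal, so inverted mode must walk negative diagonals too.
  s_range <- if (mode == "direct") seq_len(n - min_len) else
    (1L - w):(n - min_len)
  for (s in s_range) {
    k0 <- max(1L, 1L - s)           # first x position on this diagonal
    k1 <- min(n, n - s)             # last x position on this diagonal
    if (k1 - k0 + 1L < min_len) next
    m <- x[k0:k1] != y[(k0 + s):(k1 + s)]
    mm_pos <- which(m) + k0 - 1L    # absolute x coordinates
    n_mm <- base::length(mm_pos)
    i_hi <- min(w, k1 - min_len + 1L)
    if (i_hi < k0) next
    for (i in k0:i_hi) {
      # maximal arm starting at (i, i+s): grow through mismatches while the
      # running budget allows, then check left/right maximality
      before <- findInterval(i - 0.5, mm_pos)  # mismatches strictly left of i
      limit <- k1 - i + 1L             # longest arm fitting the diagonal
      best_len <- 0L; best_mm <- 0L
      t <- 0L
      repeat {
        # with t mismatches allowed, the arm extends to just before the
        # (t+1)-th mismatch at/after i (or to the sequence end)
        reach <- if (n_mm - before > t) mm_pos[before + t + 1L] - i else limit
        reach <- min(reach, limit)
        if (reach >= min_len && t <= budget(reach)) {
          best_len <- reach
          best_mm <- findInterval(i + reach - 0.5, mm_pos) - before
        }
        if (n_mm - before <= t || mm_pos[before + t + 1L] - i >= limit) break
        t <- t + 1L
        if (t > budget(limit)) break
      }
      if (best_len == 0L) next
      hits[[base::length(hits) + 1L]] <-
        c(i = i, s = s, len = best_len, mm = best_mm)
    }
  }
  # each stored arm is the longest valid arm at its start; drop arms whose
  # interval is contained in another arm on the same diagonal, leaving only
  # maximal-extension arms
  if (base::length(hits)) {
    h0 <- as.data.frame(do.call(rbind, hits))
    keep <- rep(TRUE, nrow(h0))
    for (sv in unique(h0$s)) {
      rows <- which(h0$s == sv)
      if (base::length(rows) < 2) next
      st <- h0$i[rows]; en <- h0$i[rows] + h0$len[rows] - 1L
      for (a in seq_along(rows)) {
        contained <- any(st <= st[a] & en >= en[a] &
                           !(st == st[a] & en == en[a]))
        if (contained) keep[rows[a]] <- FALSE
      }
    }
    hits <- hits[keep]
  }
  if (!base::length(hits)) return(empty)
  h <- as.data.frame(do.call(rbind, hits))
  a_start <- h$i; a_end <- h$i + h$len - 1L
  if (mode == "direct") {
    b_start <- h$i + h$s
    b_end <- b_start + h$len - 1L
  } else {
    # y position j maps to forward position n - j + 1
    b_end <- n - (h$i + h$s) + 1L
    b_start <- b_end - h$len + 1L
  }
  out <- data.frame(kind = if (mode == "direct") "TDR" else "TIR",
                    a_start = as.integer(a_start), a_end = as.integer(a_end),
                    b_start = as.integer(b_start), b_end = as.integer(b_end),
                    arm_len = as.integer(h$len),
                    mismatches = as.integer(h$mm))
  keep <- out$b_end >= n - w + 1L &          # 3' arm ends near the terminus
    out$b_start > out$a_end                  # arms must not overlap
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$a_start, -out$arm_len, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_hits", "data.frame")
  out
}

#' Flag MITE-like candidates among terminal inverted repeats
#'
#' A miniature inverted-repeat transposable element candidate is a TIR pair
#' whose arms lie at the very termini of the element, flanked in the host
#' context by a short (2--10 bp) target-site duplication (TSD). Candidates
#' are reported separately and never counted as plain TDR/TIR hits.
#'
#' @param element sequence of the putative element.
#' @param left_flank,right_flank host context immediately outside the
#'   element (>= 10 bp each side recommended).
#' @param min_len,max_mismatch_frac arm parameters as in
#'   \code{\link{find_terminal_repeats}}.
#' @return data.frame of TIR hits restricted to terminal arms, with an
#'   added \code{tsd} column (the duplicated site, or NA).
#' @export
mite_candidates <- function(element, left_flank, right_flank,
                            min_len = 10L, max_mismatch_frac = 0.1) {
  tirs <- find_terminal_repeats(element, "inverted", min_len,
                                max_mismatch_frac)
  n <- nchar(element)
  tirs <- tirs[tirs$a_start == 1L & tirs$b_end == n, , drop = FALSE]
  tsd <- NA_character_
  if (nrow(tirs) > 0) {
    for (k in 10:2) {
      lf <- substr(left_flank, nchar(left_flank) - k + 1L, nchar(left_flank))
      rf <- substr(right_flank, 1L, k)
      if (nchar(lf) == k && nchar(rf) == k && lf == rf) { tsd <- lf; break }
    }
  }
  tirs$tsd <- if (nrow(tirs)) tsd else character(0)
  tirs
}

# ---- tandem motifs ----------------------------------------------------------

#' Canonical (lexicographically least) rotation of a tandem motif
#'
#' @param m motif string.
#' @return The smallest rotation, so e.g. CCAA, CAAC and AACC all report as
#'   AACC.
#' @export
canonical_motif <- function(m) {
  n <- nchar(m)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(m, i, n), substr(m, 1, i - 1L)), character(1))
  min(rots)
}

# is the motif a whole power of a shorter motif?
is_primitive <- function(m) {
  n <- nchar(m)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0 &&
        paste(rep(substr(m, 1, d), n / d), collapse = "") == m) return(FALSE)
  }
  TRUE
}

#' Find maximal perfect tandem repeats
#'
#' Scans for maximal arrays of a short motif repeated in perfect tandem
#' (homopolymers are motif length 1). Each array is reported once, with the
#' motif in canonical rotation, the full copy number, and the array span.
#' Only primitive motifs are reported (an (AT)x6 array is not also reported
#' as (ATAT)x3), and an array is maximal: it is not preceded or followed by
#' another full motif copy.
#'
#' @param seq nucleotide string.
#' @param motif_len_range integer vector of motif lengths to scan (1--6).
#' @param min_copies minimum number of full tandem copies (default 3; use a
#'   larger value for homopolymers if desired).
#' @return data.frame of class \code{repeat_hits}: \code{kind}
#'   (\code{homopolymer} or \code{tandem_motif}), \code{start}, \code{end},
#'   \code{motif} (canonical rotation), \code{copies}.
#' @export
find_tandem_motifs <- function(seq, motif_len_range = 1:6, min_copies = 3L) {
  stopifnot(all(motif_len_range >= 1), all(motif_len_range <= 6))
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  x <- strsplit(seq, "")[[1]]
  out <- list()
  for (ml in sort(unique(as.integer(motif_len_range)))) {
    if (n < ml * 2L) next
    # run[i]: does the motif starting at i repeat at i+ml?
    same <- x[seq_len(n - ml)] == x[(1L + ml):n]
    i <- 1L
    while (i + 2L * ml - 1L <= n) {
      # count consecutive full copies starting at i
      j <- i
      while (j + 2L * ml - 1L <= n && all(same[j:(j + ml - 1L)])) j <- j + ml
      copies <- (j - i) / ml + 1L
      if (copies >= min_copies) {
        motif <- substr(seq, i, i + ml - 1L)
        if (is_primitive(motif)) {
          out[[base::length(out) + 1L]] <- data.frame(
            kind = if (ml == 1L) "homopolymer" else "tandem_motif",
            start = i, end = i + copies * ml - 1L,
            motif = canonical_motif(motif), copies = as.integer(copies),
            stringsAsFactors = FALSE)
        }
        i <- i + copies * ml          # jump past the array (maximality)
      } else {
        i <- i + 1L
      }
    }
  }
  if (!base::length(out)) {
    res <- data.frame(kind = character(), start = integer(),
                      end = integer(), motif = character(),
                      copies = integer())
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$start, res$end), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("repeat_hits", "data.frame")
  res
}

# ---- regression of repeat counts on IGR length ------------------------------

#' Regress repeat counts on IGR length
#'
#' Simple ordinary least squares of per-IGR repeat counts on IGR length,
#' the test used to ask whether IGR size explains the number of terminal
#' repeats it carries. Returns the slope, intercept, R-squared, the
#' F statistic on (1, n-2) degrees of freedom, and its upper-tail p value.
#'
#' @param lengths numeric vector of IGR lengths (not all equal).
#' @param counts numeric vector of repeat counts, same length.
#' @return list of class \code{regression_result}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{f_statistic}, \code{p_value},
#'   \code{n}.
#' @export
regress_counts_on_length <- function(lengths, counts) {
  stopifnot(base::length(lengths) == base::length(counts))
  n <- base::length(lengths)
  if (n < 3) stop("need at least 3 observations")
  if (stats::var(lengths) == 0) stop("degenerate predictor: zero variance")
  fit <- stats::lm(counts ~ lengths)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic[1])
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    f_statistic = fstat,
    p_value = stats::pf(fstat, 1, n - 2, lower.tail = FALSE),
    n = n), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> n=%d slope=%.4g R2=%.4f F=%.1f p=%.3g\n",
    x$n, x$slope, x$r_squared, x$f_statistic, x$p_value))
  invisible(x)
}
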