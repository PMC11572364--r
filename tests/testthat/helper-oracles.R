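# Independent oracles used to cross-check the package implementations on
# small inputs. These are deliberately written with different mechanics
# than the production code (exhaustive enumeration, closed forms).

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# count-and-divide skew oracle
oracle_skews <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  a <- sum(v == "A"); t <- sum(v == "T")
  g <- sum(v == "G"); c <- sum(v == "C")
  list(at = if (a + t == 0) NA_real_ else (a - t) / (a + t),
       gc = if (g + c == 0) NA_real_ else (g - c) / (g + c))
}

# exhaustive terminal-repeat oracle: enumerate every (i, j, len) triple,
# keep valid ones (Hamming mismatches within the length-dependent budget),
# suppress triples contained in a longer valid triple on the same diagonal,
# then apply the terminal-window and non-overlap filters.
oracle_terminal_repeats <- function(seq, mode, min_len = 10L,
                                    max_mismatch_frac = 0,
                                    terminal_window = 0.25) {
  n <- nchar(seq)
  x <- strsplit(seq, "")[[1]]
  y <- if (mode == "inverted") strsplit(revcomp(seq), "")[[1]] else x
  w <- max(ceiling(n * terminal_window), min_len)
  triples <- list()
  for (i in seq_len(n - min_len + 1L)) {
    for (j in seq_len(n - min_len + 1L)) {
      if (mode == "direct" && j == i) next
      maxlen <- min(n - i, n - j) + 1L
      mm <- cumsum(x[i:(i + maxlen - 1L)] != y[j:(j + maxlen - 1L)])
      lens <- which(seq_len(maxlen) >= min_len &
                      mm <= floor(max_mismatch_frac * seq_len(maxlen)))
      if (length(lens)) {
        triples[[length(triples) + 1L]] <- data.frame(
          i = i, j = j, len = lens, mm = mm[lens])
      }
    }
  }
  cols <- c("kind", "a_start", "a_end", "b_start", "b_end", "arm_len",
            "mismatches")
  if (!length(triples)) {
    out <- data.frame(kind = character(), a_start = integer(),
                      a_end = integer(), b_start = integer(),
                      b_end = integer(), arm_len = integer(),
                      mismatches = integer())
    return(out)
  }
  tr <- do.call(rbind, triples)
  tr$diag <- tr$j - tr$i
  keep <- rep(TRUE, nrow(tr))
  for (d in unique(tr$diag)) {
    rows <- which(tr$diag == d)
    st <- tr$i[rows]; en <- tr$i[rows] + tr$len[rows] - 1L
    for (a in seq_along(rows)) {
      if (any(st <= st[a] & en >= en[a] & !(st == st[a] & en == en[a]))) {
        keep[rows[a]] <- FALSE
      }
    }
  }
  tr <- tr[keep, , drop = FALSE]
  a_start <- tr$i; a_end <- tr$i + tr$len - 1L
  if (mode == "direct") {
    b_start <- tr$j; b_end <- tr$j + tr$len - 1L
  } else {
    b_end <- n - tr$j + 1L
    b_start <- b_end - tr$len + 1L
  }
  out <- data.frame(kind = if (mode == "direct") "TDR" else "TIR",
                    a_start = a_start, a_end = a_end,
                    b_start = b_start, b_end = b_end,
                    arm_len = tr$len, mismatches = tr$mm)
  out <- out[out$a_start <= w & out$b_end >= n - w + 1L &
               out$b_start > out$a_end, , drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  out <- out[order(out$a_start, -out$arm_len, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force maximal perfect tandem arrays, via block substring comparison
oracle_tandem_motifs <- function(seq, motif_len_range = 1:6,
                                 min_copies = 3L) {
  n <- nchar(seq)
  out <- list()
  for (ml in sort(unique(motif_len_range))) {
    i <- 1L
    while (i + 2L * ml - 1L <= n) {
      motif <- substr(seq, i, i + ml - 1L)
      copies <- 1L
      while (i + (copies + 1L) * ml - 1L <= n &&
             substr(seq, i + copies * ml, i + (copies + 1L) * ml - 1L) ==
             motif) {
        copies <- copies + 1L
      }
      if (copies >= min_copies && is_primitive_oracle(motif)) {
        out[[length(out) + 1L]] <- data.frame(
          kind = if (ml == 1L) "homopolymer" else "tandem_motif",
          start = i, end = i + copies * ml - 1L,
          motif = min(vapply(seq_len(ml), function(k)
            paste0(substr(motif, k, ml), substr(motif, 1, k - 1L)), "")),
          copies = copies, stringsAsFactors = FALSE)
        i <- i + copies * ml
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), motif = character(),
                      copies = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

is_primitive_oracle <- function(m) {
  n <- nchar(m)
  !any(vapply(seq_len(n - 1L), function(d)
    n %% d == 0 && strrep(substr(m, 1, d), n / d) == m, TRUE))
}

# closed-form simple-OLS oracle from the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ssres <- syy - slope * sxy
  r2 <- 1 - ssres / syy
  f <- (syy - ssres) / (ssres / (n - 2))
  list(slope = slope, intercept = intercept, r_squared = r2,
       f_statistic = f, p_value = pf(f, 1, n - 2, lower.tail = FALSE))
}

# naive all-rotations canonical form
oracle_canonical <- function(s) {
  n <- nchar(s)
  rots <- function(z) vapply(seq_len(n), function(i)
    paste0(substr(z, i, n), substr(z, 1, i - 1L)), "")
  min(c(rots(s), rots(revcomp(s))))
}

# bundled published annotation of the 31,099 bp main chromosome
chrM1_table <- function() {
  read_gene_table(system.file("extdata", "lhypogea_chrM1_genes.tsv",
                              package = "mitosplit"),
                  chromosome_id = "chrM1", L = 31099L)
}

chrM1_igr_column <- function() {
  # the printed per-gene "intergenic region (bp)" values, in table order
  c(223L, 597L, 198L, 80L, 987L, 1108L, 426L, 592L, 1791L, 1L, 66L, 103L,
    220L, 1580L, 4L, 1L, 109L, 9L, 20L, 11L, 929L, 1496L, 2L, 1L, 2L, 1L,
    67L, 9L, 359L, 0L, 231L, 371L, 1709L, 761L)
}

hamming_pub <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))
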