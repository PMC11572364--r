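#' Summarize a circular mitochondrial chromosome
#'
#' All the headline accounting of a mitogenome report, computable from the
#' feature table alone (composition fields are added when a sequence is
#' supplied): per-class gene counts and nucleotide totals, coding fractions
#' of the circle, total encoded amino acids, IGR totals, extremes and size
#' classes, and overall/per-gene composition. Percentages are rounded half
#' away from zero to 1 decimal in the printed report; stored values are
#' exact.
#'
#' @param table a \code{feature_table}.
#' @param L chromosome length.
#' @param chrom optional \code{circular_chromosome} with sequence.
#' @return list of class \code{genome_summary}.
#' @export
genome_summary <- function(table, L, chrom = NULL) {
  L <- as.integer(L)
  lens <- feature_length(table, L)
  gaps <- preceding_gaps(table, L)
  cls <- table$class
  nt_by_class <- vapply(c("protein", "tRNA", "rRNA"), function(k)
    sum(lens[cls == k]), 0L)
  aa <- table$aa_length
  prot <- which(cls == "protein")
  aa[prot][is.na(aa[prot])] <- lens[prot][is.na(aa[prot])] / 3 - 1
  igr_nonzero <- gaps[gaps > 0L]
  # with no annotated features the whole circle is one intergenic region
  if (nrow(table) == 0L) igr_nonzero <- L

  out <- list(
    chromosome_id = attr(table, "chromosome_id") %||% "chr",
    length = L,
    gene_counts = table(factor(cls, c("protein", "tRNA", "rRNA",
                                      "noncoding"))),
    protein_nt = unname(nt_by_class[["protein"]]),
    protein_fraction_pct = 100 * nt_by_class[["protein"]] / L,
    total_aa = sum(aa[prot]),
    trna_nt = unname(nt_by_class[["tRNA"]]),
    trna_fraction_pct = 100 * nt_by_class[["tRNA"]] / L,
    rrna_nt = unname(nt_by_class[["rRNA"]]),
    gene_nt_total = sum(lens),
    igr_total = sum(igr_nonzero),
    igr_fraction_pct = 100 * sum(igr_nonzero) / L,
    igr_count = base::length(igr_nonzero),
    igr_max = if (base::length(igr_nonzero)) max(igr_nonzero) else 0L,
    igr_min = if (base::length(igr_nonzero)) min(igr_nonzero) else 0L,
    igr_class_counts = table(factor(classify_igr(igr_nonzero),
                                    c("I", "II", "III", "IV", "V",
                                      "unbinned"))),
    conservation_ok = sum(lens) + sum(igr_nonzero) == L)
  if (!is.null(chrom) && !is.null(chrom$sequence)) {
    out$composition <- composition(chrom$sequence)
    out$per_gene_composition <- lapply(seq_len(nrow(table)), function(i)
      composition(extract_feature_sequence(chrom, table[i, ])))
    names(out$per_gene_composition) <- table$gene
  }
  structure(out, class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  pc <- function(v) sprintf("%.1f%%", round_half_up(v, 1))
  cat("<genome_summary> ", x$chromosome_id, ": ", x$length, " bp circular\n",
      "  genes: ", x$gene_counts[["protein"]], " protein, ",
      x$gene_counts[["tRNA"]], " tRNA, ", x$gene_counts[["rRNA"]],
      " rRNA\n",
      "  protein: ", x$protein_nt, " bp (", pc(x$protein_fraction_pct),
      "), ", x$total_aa, " aa total\n",
      "  tRNA: ", x$trna_nt, " bp (", pc(x$trna_fraction_pct), ")",
      "  rRNA: ", x$rrna_nt, " bp\n",
      "  IGRs: ", x$igr_count, " totalling ", x$igr_total, " bp (",
      pc(x$igr_fraction_pct), "), range ",
      x$igr_min, "-", x$igr_max, " bp\n",
      "  IGR classes I-V: ",
      paste(x$igr_class_counts[c("I", "II", "III", "IV", "V")],
            collapse = "/"),
      if (x$igr_class_counts[["unbinned"]] > 0)
        paste0(" (+", x$igr_class_counts[["unbinned"]], " unbinned)"), "\n",
      "  conservation (genes + IGRs = L): ",
      if (x$conservation_ok) "ok" else "VIOLATED", "\n", sep = "")
  if (!is.null(x$composition)) print(x$composition)
  invisible(x)
}

# serialize a genome_summary to plain lists for JSON
summary_to_list <- function(s) {
  out <- list(
    chromosome_id = s$chromosome_id, length = s$length,
    gene_counts = as.list(s$gene_counts),
    protein_nt = s$protein_nt,
    protein_fraction_pct = round_half_up(s$protein_fraction_pct, 1),
    total_aa = s$total_aa,
    trna_nt = s$trna_nt,
    trna_fraction_pct = round_half_up(s$trna_fraction_pct, 1),
    rrna_nt = s$rrna_nt,
    igr_total = s$igr_total,
    igr_fraction_pct = round_half_up(s$igr_fraction_pct, 1),
    igr_max = s$igr_max,
    igr_class_counts = as.list(s$igr_class_counts),
    conservation_ok = s$conservation_ok)
  if (!is.null(s$composition)) {
    cm <- s$composition
    out$composition <- list(
      pct = as.list(round_half_up(cm$pct, 1)),
      gc_percent = round_half_up(cm$gc_percent, 1),
      at_skew = round_half_up(cm$at_skew, 4),
      gc_skew = round_half_up(cm$gc_skew, 4))
  }
  out
}

#' Run the characterization pipeline
#'
#' Orchestrates the stages over a configuration list and writes a
#' machine-readable report: per-chromosome summaries, IGR tables, terminal
#' repeat scans with the count-vs-length regression, circle evidence for
#' supplied contigs, and pairwise gene-order distances. Re-running on
#' identical inputs and seed yields byte-identical outputs (no timestamps).
#'
#' Recognized configuration keys: \code{gene_tables} (named list of
#' \code{feature_table} or TSV paths), \code{lengths} (named integer vector,
#' required per table unless a sequence is given), \code{sequences} (named
#' list of \code{circular_chromosome} or FASTA path), \code{reads}
#' (\code{read_set}, named character vector, or FASTQ path), \code{contigs}
#' (named character vector or FASTA path), \code{out_dir}, \code{seed},
#' \code{min_arm} (repeat arm minimum, default 10), \code{min_support}.
#' Unknown keys are an error (naming the key); a missing reads/contigs pair
#' skips the circle stage with a warning.
#'
#' @param config configuration list (see Details).
#' @return Invisibly, the report list (also written to
#'   \code{out_dir/report.json} plus TSV tables when \code{out_dir} is set).
#' @export
run_pipeline <- function(config) {
  known <- c("gene_tables", "lengths", "sequences", "reads", "contigs",
             "out_dir", "seed", "min_arm", "min_support")
  bad <- setdiff(names(config), known)
  if (base::length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  min_arm <- config$min_arm %||% 10L
  min_support <- config$min_support %||% 3L

  tables <- stage("inputs", {
    lapply(stats::setNames(nm = names(config$gene_tables)), function(id) {
      tb <- config$gene_tables[[id]]
      if (is.character(tb)) read_gene_table(tb, chromosome_id = id) else tb
    })
  })
  seqs <- stage("inputs", {
    sq <- config$sequences
    if (is.character(sq) && base::length(sq) == 1 && file.exists(sq)) {
      sq <- read_fasta(sq)
    }
    if (is.character(sq)) {
      sq <- lapply(stats::setNames(nm = names(sq)), function(id)
        circular_chromosome(id, nchar(sq[[id]]), sq[[id]]))
    }
    sq
  })
  get_L <- function(id) {
    if (!is.null(seqs[[id]])) return(seqs[[id]]$length)
    if (!is.null(config$lengths[[id]])) return(as.integer(config$lengths[[id]]))
    stop("no length known for ", id)
  }

  report <- list(seed = config$seed %||% NA)

  report$summaries <- stage("summarize", {
    lapply(stats::setNames(nm = names(tables)), function(id)
      summary_to_list(genome_summary(tables[[id]], get_L(id), seqs[[id]])))
  })

  igr_tabs <- stage("igr", {
    lapply(stats::setNames(nm = names(tables)), function(id)
      extract_igrs(tables[[id]], seqs[[id]] %||% get_L(id)))
  })

  report$repeats <- stage("repeats", {
    main <- names(tables)[1]
    igr <- igr_tabs[[main]]
    igr <- igr[!is.na(igr$sequence), , drop = FALSE]
    if (nrow(igr) == 0) return(NULL)
    scans <- lapply(seq_len(nrow(igr)), function(i) {
      s <- igr$sequence[i]
      list(tdr = find_terminal_repeats(s, "direct", min_len = min_arm),
           tir = find_terminal_repeats(s, "inverted", min_len = min_arm))
    })
    tdr_n <- vapply(scans, function(x) nrow(x$tdr), 0L)
    tir_n <- vapply(scans, function(x) nrow(x$tir), 0L)
    reg <- function(counts) {
      if (base::length(counts) >= 3 && stats::var(igr$length) > 0) {
        r <- regress_counts_on_length(igr$length, counts)
        list(slope = r$slope, r_squared = r$r_squared,
             f_statistic = r$f_statistic, p_value = r$p_value, n = r$n)
      }
    }
    list(per_igr = data.frame(igr_start = igr$start, igr_end = igr$end,
                              length = igr$length, tdr = tdr_n,
                              tir = tir_n),
         tdr_regression = reg(tdr_n), tir_regression = reg(tir_n))
  })

  report$circles <- stage("circles", {
    if (is.null(config$contigs) || is.null(config$reads)) {
      if (!is.null(config$contigs) || !is.null(config$reads)) {
        warning("circle stage skipped: need both contigs and reads")
      }
      return(NULL)
    }
    contigs <- config$contigs
    if (base::length(contigs) == 1 && file.exists(contigs[1])) {
      contigs <- read_fasta(contigs[1])
    }
    reads <- config$reads
    if (inherits(reads, "read_set")) reads <- c(reads$read1, reads$read2)
    if (base::length(reads) == 1 && file.exists(reads[1])) {
      reads <- read_fastq(reads[1])
    }
    lapply(stats::setNames(nm = names(contigs)), function(id) {
      ev <- evaluate_contig(contigs[[id]], reads, contig_id = id,
                            min_support = min_support)
      list(circular_length = ev$circular_length,
           junction_support = ev$junction_support,
           flank_diversity = ev$flank_diversity,
           mean_depth = ev$mean_depth, verdict = ev$verdict)
    })
  })

  report$gene_order <- stage("geneorder", {
    if (base::length(tables) < 2) return(NULL)
    sigs <- lapply(tables, order_signature)
    ids <- names(tables)
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    lapply(pairs, function(p) {
      common <- intersect(sigs[[p[1]]]$gene, sigs[[p[2]]]$gene)
      if (base::length(common) == 0) {
        return(list(a = p[1], b = p[2], shared = NA, breakpoints = NA))
      }
      list(a = p[1], b = p[2],
           shared = suppressMessages(
             shared_adjacencies(sigs[[p[1]]], sigs[[p[2]]])),
           breakpoints = suppressMessages(
             breakpoint_distance(sigs[[p[1]]], sigs[[p[2]]])))
    })
  })

  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null")
      for (id in names(igr_tabs)) {
        utils::write.table(
          igr_tabs[[id]][, setdiff(names(igr_tabs[[id]]), "sequence")],
          file.path(config$out_dir, paste0("igr_", id, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }
  invisible(report)
}
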