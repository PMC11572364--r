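#' Normalize mitochondrial gene names
#'
#' Cross-study annotation tables name the same genes differently (nad4l vs
#' ND4L, cob vs CYTB, rrnL vs rnl). A bundled synonym map brings them to one
#' canonical form: upper case for proteins (ND1..ND6, ND4L, COX1..3, ATP6,
#' ATP8, ATP9, CYTB), lower case rnl/rns for rRNAs, and tRNAs as
#' \code{trnX(anticodon)} with the anticodon retained in lower case.
#'
#' @param gene character vector of gene names.
#' @return Character vector of canonical names.
#' @export
normalize_gene_name <- function(gene) {
  syn <- c(
    nad1 = "ND1", nad2 = "ND2", nad3 = "ND3", nad4 = "ND4", nad5 = "ND5",
    nad6 = "ND6", nad4l = "ND4L", nd1 = "ND1", nd2 = "ND2", nd3 = "ND3",
    nd4 = "ND4", nd5 = "ND5", nd6 = "ND6", nd4l = "ND4L",
    cox1 = "COX1", cox2 = "COX2", cox3 = "COX3", co1 = "COX1",
    co2 = "COX2", co3 = "COX3", coi = "COX1", coii = "COX2", coiii = "COX3",
    atp6 = "ATP6", atp8 = "ATP8", atp9 = "ATP9",
    cytb = "CYTB", cob = "CYTB", cb = "CYTB",
    rnl = "rnl", rns = "rns", `16s` = "rnl", `12s` = "rns",
    rrnl = "rnl", rrns = "rns")
  vapply(gene, function(g) {
    low <- tolower(g)
    if (grepl("^trn", low)) {
      # keep the anticodon: trnI(CAU) -> trnI(cau)
      m <- regmatches(low, regexec("^trn([a-z])\\(([a-z]{3})\\)$", low))[[1]]
      if (base::length(m) == 3) {
        return(paste0("trn", toupper(m[2]), "(", m[3], ")"))
      }
      return(low)
    }
    if (low %in% names(syn)) unname(syn[[low]]) else g
  }, character(1), USE.NAMES = FALSE)
}

#' Circular gene-order signature
#'
#' The ordered, circular list of (normalized) gene labels with their strand
#' signs, the representation used to compare gene arrangements between
#' mitogenomes. IGRs are dropped; duplicate normalized names are an error.
#'
#' @param table a sorted \code{feature_table}.
#' @param include_classes gene classes to keep (default protein, rRNA,
#'   tRNA).
#' @return data.frame of class \code{order_signature} with columns
#'   \code{gene} (canonical name) and \code{strand}; attribute
#'   \code{chromosome_id}.
#' @export
order_signature <- function(table,
                            include_classes = c("protein", "rRNA", "tRNA")) {
  keep <- table$class %in% include_classes
  g <- normalize_gene_name(table$gene[keep])
  if (anyDuplicated(g)) {
    stop("duplicate normalized gene name: ",
         paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  structure(data.frame(gene = g, strand = table$strand[keep],
                       stringsAsFactors = FALSE),
            class = c("order_signature", "data.frame"),
            chromosome_id = attr(table, "chromosome_id") %||% "chr")
}

# circular adjacency set of a signature; unsigned adjacencies are unordered
# gene pairs, signed adjacencies keep orientation with (-b,-a) == (a,b)
adjacency_keys <- function(sig, signed = FALSE) {
  n <- nrow(sig)
  if (n < 2) return(character(0))
  nxt <- c(2:n, 1L)
  if (!signed) {
    vapply(seq_len(n), function(i) {
      paste(sort(c(sig$gene[i], sig$gene[nxt[i]])), collapse = "|")
    }, character(1))
  } else {
    sgn <- ifelse(sig$strand == "H", "+", "-")
    vapply(seq_len(n), function(i) {
      a <- paste0(sgn[i], sig$gene[i])
      b <- paste0(sgn[nxt[i]], sig$gene[nxt[i]])
      flip <- function(x) paste0(chartr("+-", "-+", substr(x, 1, 1)),
                                 substr(x, 2, nchar(x)))
      min(paste(a, b, sep = "|"), paste(flip(b), flip(a), sep = "|"))
    }, character(1))
  }
}

restrict_to <- function(sig, genes) {
  out <- sig[sig$gene %in% genes, , drop = FALSE]
  attr(out, "chromosome_id") <- attr(sig, "chromosome_id")
  class(out) <- class(sig)
  out
}

#' Shared adjacencies and breakpoint distance between circular gene orders
#'
#' Counts gene adjacencies (circular neighbor pairs) present in both
#' signatures; the breakpoint distance is \code{n - shared}, where n is the
#' number of genes compared. Both quantities are invariant to rotation of
#' either signature. When the gene sets differ the comparison is restricted
#' to the intersection (with a message). By default adjacencies are
#' unsigned, appropriate when all genes lie on one strand; set
#' \code{signed = TRUE} to require matching orientation. With
#' \code{reflection = TRUE} the reflected (reverse-complement) order of
#' \code{b} is also tried and the more similar orientation is used.
#'
#' @param a,b \code{order_signature} objects.
#' @param signed compare strand signs as well as neighbors.
#' @param reflection also try b reversed (strands flipped).
#' @return \code{shared_adjacencies}: integer count.
#' @export
shared_adjacencies <- function(a, b, signed = FALSE, reflection = FALSE) {
  common <- intersect(a$gene, b$gene)
  if (base::length(common) == 0) stop("empty gene-set intersection")
  if (base::length(common) < nrow(a) || base::length(common) < nrow(b)) {
    message("restricting comparison to ", base::length(common),
            " shared genes")
  }
  a <- restrict_to(a, common); b <- restrict_to(b, common)
  ka <- adjacency_keys(a, signed)
  kb <- adjacency_keys(b, signed)
  shared <- sum(ka %in% kb)
  if (reflection) {
    br <- b[rev(seq_len(nrow(b))), , drop = FALSE]
    br$strand <- chartr("HL", "LH", br$strand)
    shared <- max(shared, sum(ka %in% adjacency_keys(br, signed)))
  }
  shared
}

#' @rdname shared_adjacencies
#' @return \code{breakpoint_distance}: integer, 0 for identical circular
#'   orders, bounded by the number of shared genes.
#' @export
breakpoint_distance <- function(a, b, signed = FALSE, reflection = FALSE) {
  common <- intersect(a$gene, b$gene)
  if (base::length(common) == 0) stop("empty gene-set intersection")
  base::length(common) -
    shared_adjacencies(a, b, signed = signed, reflection = reflection)
}

#' Render gene orders as aligned text lines
#'
#' One line per genome listing the circular gene order linearized at a
#' shared anchor gene when possible, for eyeballing rearrangements.
#'
#' @param sigs list of \code{order_signature} objects.
#' @param anchor gene to rotate each order to start at (default: first gene
#'   of the first signature, if shared).
#' @return Character vector, one line per signature.
#' @export
render_gene_orders <- function(sigs, anchor = NULL) {
  if (is.null(anchor)) anchor <- sigs[[1]]$gene[1]
  vapply(sigs, function(s) {
    i <- match(anchor, s$gene)
    ord <- if (is.na(i)) seq_len(nrow(s)) else
      c(i:nrow(s), if (i > 1) 1:(i - 1))
    sgn <- ifelse(s$strand[ord] == "H", "", "-")
    paste0(attr(s, "chromosome_id"), ": ",
           paste0(sgn, s$gene[ord], collapse = " "))
  }, character(1))
}
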