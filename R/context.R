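# Insertion-site analysis: intron phase, tandem-site-duplication scan,
# seamless-integration check against an intron-less orthologue, and the
# junction position-frequency matrix behind a splice-junction logo.

#' Intron phase from the CDS offset of the insertion point
#'
#' Phase is the number of nucleotides the intron sits into a codon: 0 between
#' codons, 1 after the first, 2 after the second base. For a stwintron the
#' insertion point is the nucleotide 5' of G1 (G1 itself is intronic).
#'
#' @param cds_offset nt from the CDS start (first base of ATG) to the
#'   insertion point; vectorised.
#' @return integer phase(s) in `{0, 1, 2}`.
#' @export
intron_phase <- function(cds_offset) {
  cds_offset <- as.integer(cds_offset)
  if (any(is.na(cds_offset)) || any(cds_offset < 0L)) {
    stop("cds_offset must be non-negative")
  }
  cds_offset %% 3L
}

#' Scan for a tandem site duplication at an insertion point
#'
#' DNA transposition duplicates its target site, leaving an exact direct
#' repeat that ends at the 3' end of the upstream flank and begins at the 5'
#' start of the downstream flank. The scan is exact-match only: duplications
#' are created identical at insertion time.
#'
#' @param flank5,flank3 exonic flanks (upstream / downstream of the element),
#'   each at least `max_len` nt.
#' @param min_len,max_len length window of the repeat (defaults 2-10).
#' @return list `present` (logical), `length`, `sequence` (the longest
#'   qualifying repeat, or 0/"" when absent).
#' @export
tsd_scan <- function(flank5, flank3, min_len = 2L, max_len = 10L) {
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  if (nchar(flank5) < max_len || nchar(flank3) < max_len) {
    stop("flanks must be at least max_len (", max_len, ") nt")
  }
  n5 <- nchar(flank5)
  for (k in seq(max_len, min_len)) {
    if (substr(flank5, n5 - k + 1L, n5) == substr(flank3, 1L, k)) {
      return(list(present = TRUE, length = k,
                  sequence = substr(flank3, 1L, k)))
    }
  }
  list(present = FALSE, length = 0L, sequence = "")
}

#' Seamless-integration check against an intron-less orthologue window
#'
#' Globally aligns the host's exon-fusion sequence (upstream flank +
#' downstream flank, the sequence restored by perfect excision) to the
#' corresponding orthologue CDS window. The insertion is `seamless` when the
#' alignment has no indel at the junction column; otherwise a `replacement`
#' is reported with the number of orthologue nt lost (present in the
#' orthologue, absent at the host junction) and host nt gained. Windows that
#' are too short or align below 50% identity are `indeterminate`.
#'
#' @param flank5,flank3 host exonic flanks (>= 30 nt each for a determinate
#'   call).
#' @param orthologue_cds_window orthologue sequence spanning the insertion
#'   point.
#' @param scoring see [alignment_scoring()].
#' @return list `status` (`"seamless"`, `"replacement"`, `"indeterminate"`),
#'   `n_lost`, `n_gained`, `identity`.
#' @export
seamless_check <- function(flank5, flank3, orthologue_cds_window,
                           scoring = alignment_scoring()) {
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  orth <- toupper(orthologue_cds_window)
  if (nchar(flank5) < 30L || nchar(flank3) < 30L || nchar(orth) < 60L) {
    return(list(status = "indeterminate", n_lost = NA_integer_,
                n_gained = NA_integer_, identity = NA_real_))
  }
  fusion <- paste0(flank5, flank3)
  aln <- global_align(fusion, orth, scoring)
  if (aln$percent_identity < 50) {
    return(list(status = "indeterminate", n_lost = NA_integer_,
                n_gained = NA_integer_, identity = aln$percent_identity))
  }
  cols <- .aln_columns(aln)
  j5 <- nchar(flank5)
  # columns between the last flank5 base and the first flank3 base
  c5 <- max(which(cols$pos_a == j5))
  c3 <- min(which(cols$pos_a == j5 + 1L))
  between <- if (c3 > c5 + 1L) (c5 + 1L):(c3 - 1L) else integer(0)
  n_lost <- sum(cols$pos_a[between] == 0L)   # orthologue nt with no host base
  # host nt unmatched right at the junction: fusion bases in the junction gap
  n_gained <- sum(cols$pos_b[between] == 0L)
  # host bases adjacent to the junction aligned to orthologue gaps
  adj <- c(c5, c3)
  n_gained <- n_gained + sum(cols$pos_b[adj] == 0L)
  if (n_lost == 0L && n_gained == 0L) {
    list(status = "seamless", n_lost = 0L, n_gained = 0L,
         identity = aln$percent_identity)
  } else {
    list(status = "replacement", n_lost = n_lost, n_gained = n_gained,
         identity = aln$percent_identity)
  }
}

#' Build junction-aligned rows for the logo matrix
#'
#' Rows are `flank5` (15 nt) + a G1 column + the first `intron_width` nt of
#' the element's donor side. Elements that start with the external G1
#' (stwintrons) occupy the G1 column; cropped canonical introns, whose first
#' base is already the donor G, leave it unfilled (`-`), so the G1 column's
#' occupancy is the stwintron fraction of the set.
#'
#' @param flank5s character vector of 15-nt upstream exonic flanks.
#' @param elements character vector of intervening sequences (same length).
#' @param leading_g logical vector: does the element carry the exonisable G1?
#' @param intron_width intronic columns to include after the G1 column.
#' @return character vector of equally wide rows over `{A,C,G,T,-}`.
#' @export
junction_rows <- function(flank5s, elements, leading_g, intron_width = 6L) {
  stopifnot(length(flank5s) == length(elements),
            length(elements) == length(leading_g))
  vapply(seq_along(elements), function(i) {
    el <- toupper(elements[i])
    g1 <- if (leading_g[i]) substr(el, 1L, 1L) else "-"
    body_from <- if (leading_g[i]) 2L else 1L
    body <- substr(el, body_from, body_from + intron_width - 1L)
    paste0(toupper(flank5s[i]), g1, body)
  }, character(1))
}

#' Position-frequency matrix and information content of junction rows
#'
#' Counts observed bases per column (no pseudocounts), computes frequencies
#' among filled rows, per-column information content `IC = 2 - H` in bits
#' (with `0 * log2(0) = 0`), and occupancy (filled rows / total rows) for
#' partially filled columns such as the G1 column.
#'
#' @param rows character vector of equal-width strings over `{A,C,G,T,-}`
#'   (see [junction_rows()]).
#' @return list of class `"junction_matrix"`: `counts` (4 x W), `frequencies`,
#'   `information_content` (bits per column), `occupancy`, `n_rows`.
#' @export
junction_matrix <- function(rows) {
  if (!length(rows)) stop("no rows")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) stop("inconsistent row widths")
  W <- widths[1]
  n <- length(rows)
  mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  counts <- sapply(seq_len(W), function(j) {
    col <- mat[, j]
    vapply(bases, function(b) sum(col == b), integer(1))
  })
  rownames(counts) <- bases
  filled <- colSums(counts)
  freq <- sweep(counts, 2, pmax(filled, 1L), "/")
  ic <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  ic[filled == 0] <- 0
  structure(list(counts = counts, frequencies = freq,
                 information_content = ic, occupancy = filled / n,
                 n_rows = n), class = "junction_matrix")
}

#' @export
print.junction_matrix <- function(x, ...) {
  cat(sprintf("junction matrix: %d rows x %d columns; IC range %.2f-%.2f bits\n",
              x$n_rows, ncol(x$counts), min(x$information_content),
              max(x$information_content)))
  invisible(x)
}
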