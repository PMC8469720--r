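# Two-step stwintron excision, the splinter intermediate, the alternative
# one-step product with an exonised G1, and 60-nt junction queries.

.cut <- function(s, from, to) {
  # remove s[from..to] (1-based inclusive)
  paste0(substr(s, 1L, from - 1L), substr(s, to + 1L, nchar(s)))
}

#' Simulate stwintron excision from a pre-mRNA
#'
#' The internal intron is removed first, yielding the splinter intermediate
#' (external intron retained, its donor now functional); the second U2
#' reaction removes the external intron, yielding the mature product. The
#' alternative one-step product removes the stwintron minus its leading G1,
#' which stays exonic and shifts the reading frame by +1.
#'
#' @param pre_mrna pre-mRNA (DNA alphabet) string.
#' @param stw a `"stwintron"` object located within `pre_mrna` (coordinates as
#'   from [find_d12_stwintrons()] run on `pre_mrna` or a region of it).
#' @param frame_offset optional nt offset from the CDS start to the first base
#'   of `pre_mrna`; when supplied the `frameshift` flag is computed.
#' @return list of class `"splice_products"` with `pre_mrna`, `splinter`,
#'   `mature`, `alt_mature`, `frameshift`. Length identities:
#'   `nchar(splinter) == nchar(pre_mrna) - internal length`,
#'   `nchar(mature) == nchar(pre_mrna) - stwintron length`,
#'   `nchar(alt_mature) == nchar(mature) + 1`.
#' @export
splice_stwintron <- function(pre_mrna, stw, frame_offset = NULL) {
  n <- nchar(pre_mrna)
  st <- stw$location$start; en <- stw$location$end
  if (st < 1L || en > n) stop("stwintron coordinates out of range")
  splinter <- .cut(pre_mrna, stw$internal$start, stw$internal$end)
  mature <- .cut(pre_mrna, st, en)
  alt_mature <- .cut(pre_mrna, st + 1L, en)
  frameshift <- if (is.null(frame_offset)) NA else
    ((nchar(alt_mature) - nchar(mature)) %% 3L) != 0L
  structure(list(pre_mrna = pre_mrna, splinter = splinter, mature = mature,
                 alt_mature = alt_mature, frameshift = frameshift),
            class = "splice_products")
}

#' Junction verification queries for read-archive screening
#'
#' Emits fixed-width probes with the biological junction exactly at the
#' centre: the mature-junction query fuses the last `width/2` nt of the
#' upstream exon to the first `width/2` nt of the downstream exon; the
#' splinter-junction query fuses the upstream exon to the reconstructed
#' external intron, which begins G1 followed by the donor continuation. Where
#' exonic context is shorter than `width/2`, the query is truncated with a
#' warning rather than dropped, so elements near sequence ends (e.g., in a
#' 5'-UTR) remain analysable.
#'
#' @param gene_seq gene/pre-mRNA string containing the stwintron.
#' @param stw located `"stwintron"` object.
#' @param width total query width in nt (even; default 60).
#' @return data.frame with columns `name`, `kind`
#'   (`mature_junction`/`splinter_junction`), `sequence`, `truncated`.
#' @export
make_junction_queries <- function(gene_seq, stw, width = 60L) {
  width <- as.integer(width)
  if (width < 2L || width %% 2L != 0L) stop("width must be a positive even number")
  half <- width %/% 2L
  n <- nchar(gene_seq)
  st <- stw$location$start; en <- stw$location$end
  if (st < 1L || en > n) stop("stwintron coordinates out of range")

  up_from <- max(1L, st - half)
  up <- substr(gene_seq, up_from, st - 1L)
  down <- substr(gene_seq, en + 1L, min(n, en + half))
  # reconstructed external intron 5' part: G1 then everything after the
  # internal acceptor
  ext5 <- paste0(substr(gene_seq, st, st),
                 substr(gene_seq, stw$internal$end + 1L,
                        min(n, stw$internal$end + half - 1L)))
  truncated_m <- nchar(up) < half || nchar(down) < half
  truncated_s <- nchar(up) < half || nchar(ext5) < half
  if (truncated_m || truncated_s) {
    warning("junction query truncated: insufficient flanking context")
  }
  base <- sprintf("%s_%d_%d", stw$location$seq_id, st, en)
  out <- data.frame(
    name = paste0(base, c("_mature", "_splinter")),
    kind = c("mature_junction", "splinter_junction"),
    sequence = c(paste0(up, down), paste0(up, ext5)),
    truncated = c(truncated_m, truncated_s),
    stringsAsFactors = FALSE
  )
  out
}
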