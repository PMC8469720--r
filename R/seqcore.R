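#' @useDynLib stwinscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames rbinom runif chisq.test cor
#' @importFrom utils write.table read.table
NULL

# --- IUPAC machinery ---------------------------------------------------------

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

.check_iupac <- function(s, what = "sequence") {
  if (length(s) != 1L || !is.character(s)) {
    stop(what, " must be a single character string")
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% names(.IUPAC_COMPLEMENT))
  if (length(bad)) {
    stop("non-IUPAC character '", ch[bad[1]], "' in ", what,
         " at position ", bad[1])
  }
  invisible(ch)
}

#' Reverse complement of a (possibly degenerate) DNA string
#'
#' Complements every IUPAC code (W<->W, R<->Y, N<->N, ...) and reverses the
#' string. RNA input should be converted U->T beforehand (the loaders do this).
#'
#' @param s DNA string over the IUPAC alphabet (uppercase).
#' @return The reverse complement string. `reverse_complement` is an
#'   involution: `reverse_complement(reverse_complement(s)) == s`.
#' @examples
#' reverse_complement("TTTCTAGAAA") # the 10-nt palindrome equals itself
#' reverse_complement("GGTAAG")
#' @export
reverse_complement <- function(s) {
  if (identical(s, "")) return("")
  ch <- .check_iupac(s)
  paste(rev(unname(.IUPAC_COMPLEMENT[ch])), collapse = "")
}

#' Match a DNA window against a degenerate IUPAC pattern
#'
#' Each window base must fall in the degeneracy set of the corresponding
#' pattern symbol. An N in the *window* is treated conservatively: it matches
#' nothing except a pattern N, so ambiguous genomic bases never create motif
#' calls.
#'
#' @param pattern IUPAC pattern string.
#' @param window DNA window of the same length.
#' @return `TRUE` or `FALSE`.
#' @examples
#' iupac_match("WTTCTAGAAA", "ATTCTAGAAA")
#' iupac_match("GTRWGY", "GTAAGT")
#' @export
iupac_match <- function(pattern, window) {
  pc <- .check_iupac(pattern, "pattern")
  wc <- .check_iupac(window, "window")
  if (length(pc) != length(wc)) {
    stop("pattern and window lengths differ (", length(pc), " vs ",
         length(wc), ")")
  }
  all(vapply(seq_along(pc), function(i) {
    if (wc[i] == "N") return(pc[i] == "N")
    wc[i] %in% .IUPAC_SETS[[pc[i]]]
  }, logical(1)))
}

#' Count matching positions of a window against an IUPAC pattern
#'
#' Per-position version of [iupac_match()], used for degenerate palindrome
#' scoring where a hit requires >7 of 10 conserved positions.
#'
#' @inheritParams iupac_match
#' @return Integer count of positions whose window base lies in the pattern
#'   symbol's degeneracy set.
#' @export
iupac_match_count <- function(pattern, window) {
  pc <- .check_iupac(pattern, "pattern")
  wc <- .check_iupac(window, "window")
  if (length(pc) != length(wc)) stop("length mismatch")
  sum(vapply(seq_along(pc), function(i) {
    if (wc[i] == "N") return(pc[i] == "N")
    wc[i] %in% .IUPAC_SETS[[pc[i]]]
  }, logical(1)))
}

# Vectorised motif scan: start positions (1-based) of windows matching an
# IUPAC pattern. N in the sequence matches only pattern N.
.scan_pattern <- function(seq_chars, pattern) {
  k <- nchar(pattern)
  n <- length(seq_chars)
  if (n < k) return(integer(0))
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, n - k + 1L)
  for (i in seq_len(k)) {
    allowed <- .IUPAC_SETS[[pc[i]]]
    if (pc[i] == "N") allowed <- c(allowed, "N")
    ok <- ok & (seq_chars[i:(n - k + i)] %in% allowed)
  }
  which(ok)
}

# --- intervals ---------------------------------------------------------------

#' Construct a located interval
#'
#' Coordinates are 1-based and inclusive on both ends (the GFF3 / IRanges
#' convention), so emission to GFF3 is the identity on coordinates.
#'
#' @param seq_id reference sequence identifier.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A list of class `"interval"`.
#' @export
interval <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("invalid interval: start=", start, " end=", end)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "interval")
}

iv_len <- function(iv) iv$end - iv$start + 1L

# --- intron model ------------------------------------------------------------

#' Canonical fungal U2 intron motif grammar
#'
#' Bundles the degenerate splice-element patterns and length windows used by
#' the scanner. The canonical elements are the 6-nt 5'-donor, the 6-nt
#' branch-point (BP) element with the lariat branch A at its fifth position,
#' and the 3-nt 3'-acceptor. Defaults follow the consensus for fungal U2
#' introns: donor GTRWGY (DNA form of GURWGY), BP RCTRAC, acceptor YAG. The
#' BP consensus is configurable because published predictors differ.
#'
#' @param donor_pattern 6-nt IUPAC donor pattern.
#' @param bp_pattern 6-nt IUPAC branch-point element pattern.
#' @param acceptor_pattern 3-nt IUPAC acceptor pattern.
#' @param min_intron_len,max_intron_len intron length window (nt). The default
#'   40-600 admits both typical short fungal introns (< 100 nt) and the
#'   ~200-280 nt complex intervening sequences analysed here; it is applied
#'   independently to the internal and external intron of a stwintron.
#' @param bp_to_acceptor_min,bp_to_acceptor_max allowed number of nt between
#'   the end of the BP element and the start of the acceptor.
#' @param allow_gc_internal_donor accept 5'-GC in place of 5'-GT for the
#'   *internal* donor of a stwintron (features starting GGC).
#' @return An object of class `"intron_model"`.
#' @export
intron_model <- function(donor_pattern = "GTRWGY",
                         bp_pattern = "RCTRAC",
                         acceptor_pattern = "YAG",
                         min_intron_len = 40L,
                         max_intron_len = 600L,
                         bp_to_acceptor_min = 4L,
                         bp_to_acceptor_max = 60L,
                         allow_gc_internal_donor = TRUE) {
  .check_iupac(donor_pattern, "donor_pattern")
  .check_iupac(bp_pattern, "bp_pattern")
  .check_iupac(acceptor_pattern, "acceptor_pattern")
  if (nchar(donor_pattern) != 6L) stop("donor pattern must be 6 nt")
  if (nchar(bp_pattern) != 6L) stop("BP pattern must be 6 nt")
  if (nchar(acceptor_pattern) != 3L) stop("acceptor pattern must be 3 nt")
  min_intron_len <- as.integer(min_intron_len)
  max_intron_len <- as.integer(max_intron_len)
  if (min_intron_len < nchar(donor_pattern) + nchar(bp_pattern) +
      nchar(acceptor_pattern)) {
    stop("min_intron_len smaller than the combined motif lengths")
  }
  if (max_intron_len < min_intron_len) stop("max_intron_len < min_intron_len")
  structure(list(
    donor_pattern = donor_pattern,
    bp_pattern = bp_pattern,
    acceptor_pattern = acceptor_pattern,
    min_intron_len = min_intron_len,
    max_intron_len = max_intron_len,
    bp_to_acceptor_min = as.integer(bp_to_acceptor_min),
    bp_to_acceptor_max = as.integer(bp_to_acceptor_max),
    allow_gc_internal_donor = isTRUE(allow_gc_internal_donor)
  ), class = "intron_model")
}

# --- genomic sequences -------------------------------------------------------

#' Construct a genomic sequence record
#'
#' @param id sequence identifier.
#' @param residues DNA string; lowercase is uppercased, RNA U converted to T.
#' @param description optional free-text description.
#' @return list of class `"genomic_sequence"`.
#' @export
genomic_sequence <- function(id, residues, description = "") {
  residues <- chartr("u", "t", residues)
  residues <- toupper(residues)
  residues <- chartr("U", "T", residues)
  if (!nzchar(residues)) stop("empty residues for sequence '", id, "'")
  .check_iupac(residues, paste0("sequence '", id, "'"))
  structure(list(id = id, residues = residues, description = description),
            class = "genomic_sequence")
}

#' Read a (multi-)FASTA file
#'
#' Thin wrapper around `Biostrings::readDNAStringSet`; records are uppercased
#' and U is converted to T so that downstream motif logic sees a canonical
#' DNA alphabet. Softmasking (lowercase) is not used as a filter.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names are the first
#'   whitespace-delimited token of each header; full headers kept in the
#'   `"description"` attribute).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  seqs <- toupper(as.character(ss))
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  out <- setNames(unname(seqs), ids)
  attr(out, "description") <- setNames(headers, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

# --- GFF3 --------------------------------------------------------------------

#' Write a feature table to GFF3
#'
#' `features` is a data.frame with columns `seq_id`, `start`, `end`, `strand`,
#' `type`, and optionally `ID`, `Parent`, plus any further columns, which are
#' carried as GFF3 attributes. Coordinates are 1-based inclusive, identical in
#' the internal representation and on disk.
#'
#' @param features feature data.frame (see details).
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "stwinscan") {
  required <- c("seq_id", "start", "end", "strand", "type")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$seq_id,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$source <- source
  extra <- setdiff(names(features), c(required))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- features[[col]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file back into a feature table
#'
#' @param path GFF3 file path.
#' @return data.frame with `seq_id`, `start`, `end`, `strand`, `type` and any
#'   attribute columns.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  mc$source <- NULL
  mc$phase <- NULL
  mc$score <- NULL
  for (j in seq_along(mc)) if (is.factor(mc[[j]])) mc[[j]] <- as.character(mc[[j]])
  cbind(df, mc)
}

#' Write a report table as TSV or JSON
#'
#' @param rows data.frame of report rows.
#' @param path output path.
#' @param format `"tsv"` (tab-separated with header) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
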