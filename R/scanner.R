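# Nested-motif detection of canonical U2 introns and donor-disrupted (D1,2)
# stwintrons. All coordinates 1-based inclusive on the forward axis.

.as_residues <- function(seq) {
  if (inherits(seq, "genomic_sequence")) seq$residues else {
    stopifnot(is.character(seq), length(seq) == 1L)
    toupper(seq)
  }
}

.seq_id_of <- function(seq, default = "seq") {
  if (inherits(seq, "genomic_sequence")) seq$id else default
}

# Leftmost BP start satisfying the distance window for intron [d, e], or NA.
.leftmost_bp <- function(d, e, bp_starts, model) {
  lo <- e - 8L - model$bp_to_acceptor_max
  hi <- e - 8L - model$bp_to_acceptor_min
  lo <- max(lo, d + 6L)
  cand <- bp_starts[bp_starts >= lo & bp_starts <= hi]
  if (length(cand)) cand[1L] else NA_integer_
}

#' Find canonical U2 introns by motif grammar
#'
#' An intron is a window that starts with a donor-pattern match, ends with an
#' acceptor-pattern match, contains a BP-element match whose end lies within
#' the configured distance of the acceptor, and whose length falls in the
#' model's window. In `"intron_definition"` mode (the default, reflecting the
#' splice-site pairing mode of short-intron fungi, which excises the smallest
#' intron possible) only the minimal-length satisfying intron is reported per
#' donor position; `"exhaustive"` mode reports every satisfying (donor,
#' acceptor) pair. Ties are broken towards the leftmost BP.
#'
#' @param seq a DNA string or [genomic_sequence()].
#' @param model an [intron_model()].
#' @param region optional [interval()] restricting the scan (introns must lie
#'   entirely within it).
#' @param mode `"intron_definition"` or `"exhaustive"`.
#' @return data.frame with one row per intron: `start`, `end`, `length`,
#'   `donor_seq`, `bp_start`, `bp_end`, `acceptor_seq`, `phase` (always
#'   `"unknown"` here; phase requires CDS context, see [intron_phase()]).
#' @export
find_canonical_introns <- function(seq, model = intron_model(), region = NULL,
                                   mode = c("intron_definition", "exhaustive")) {
  mode <- match.arg(mode)
  s <- .as_residues(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  lo <- 1L; hi <- n
  if (!is.null(region)) {
    if (region$start < 1L || region$end > n) stop("region outside sequence")
    lo <- region$start; hi <- region$end
  }
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      donor_seq = character(0), bp_start = integer(0),
                      bp_end = integer(0), acceptor_seq = character(0),
                      phase = character(0), stringsAsFactors = FALSE)
  if (hi - lo + 1L < model$min_intron_len) return(empty)

  donors <- .scan_pattern(ch, model$donor_pattern)
  donors <- donors[donors >= lo & donors <= hi - model$min_intron_len + 1L]
  acc_starts <- .scan_pattern(ch, model$acceptor_pattern)
  acc_ends <- acc_starts + 2L
  acc_ends <- acc_ends[acc_ends <= hi]
  bp_starts <- .scan_pattern(ch, model$bp_pattern)
  if (!length(donors) || !length(acc_ends) || !length(bp_starts)) return(empty)

  rows <- vector("list", 0L)
  for (d in donors) {
    e_lo <- d + model$min_intron_len - 1L
    e_hi <- min(d + model$max_intron_len - 1L, hi)
    ends <- acc_ends[acc_ends >= e_lo & acc_ends <= e_hi]
    if (!length(ends)) next
    ends <- sort(ends)
    for (e in ends) {
      b <- .leftmost_bp(d, e, bp_starts, model)
      if (is.na(b)) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = d, end = e, length = e - d + 1L,
        donor_seq = substr(s, d, d + 5L),
        bp_start = b, bp_end = b + 5L,
        acceptor_seq = substr(s, e - 2L, e),
        phase = "unknown", stringsAsFactors = FALSE
      )
      if (mode == "intron_definition") break
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

# Internal donor check at position p+1 for a feature starting at G1 = p.
# Returns TRUE if ch[p+1 .. p+6] matches the donor pattern, optionally with a
# C at position 2 (GGC-starting stwintrons).
.internal_donor_ok <- function(ch, p, model) {
  n <- length(ch)
  if (p + 6L > n) return(FALSE)
  w <- paste(ch[(p + 1L):(p + 6L)], collapse = "")
  if (iupac_match(model$donor_pattern, w)) return(TRUE)
  if (model$allow_gc_internal_donor && ch[p + 2L] == "C") {
    w2 <- paste(c(ch[p + 1L], "T", ch[(p + 3L):(p + 6L)]), collapse = "")
    return(iupac_match(model$donor_pattern, w2))
  }
  FALSE
}

#' Detect (D1,2) stwintron candidates
#'
#' A (D1,2) stwintron is an intervening sequence whose internal intron splits
#' the external intron's 6-nt donor between its first and second nucleotide:
#' the feature begins `G1` + internal donor (so 5'-GGT, occasionally 5'-GGC
#' when `allow_gc_internal_donor`). A hit requires (i) a valid internal
#' canonical intron starting at position 2 of the feature, (ii) that `G1`
#' followed by the 5 nt after the internal acceptor reconstitutes a valid
#' donor, and (iii) that the reconstructed external intron (G1 + the remainder
#' after internal excision) is itself a valid canonical intron. Per G1
#' position the shortest internal intron admitting a valid external intron is
#' chosen (ties to the leftmost BP), then the shortest external intron.
#'
#' @inheritParams find_canonical_introns
#' @return list of `"stwintron"` objects; see [stwintron_table()] for a
#'   flat data.frame view.
#' @export
find_d12_stwintrons <- function(seq, model = intron_model()) {
  s <- .as_residues(seq)
  id <- .seq_id_of(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2L * model$min_intron_len) return(list())

  acc_starts <- .scan_pattern(ch, model$acceptor_pattern)
  acc_ends <- acc_starts + 2L
  bp_starts <- .scan_pattern(ch, model$bp_pattern)
  if (!length(acc_ends) || !length(bp_starts)) return(list())

  hits <- list()
  # candidate G1 positions: G followed by a valid internal donor
  gpos <- which(ch == "G")
  gpos <- gpos[gpos + 6L <= n]
  for (p in gpos) {
    if (!.internal_donor_ok(ch, p, model)) next
    i_s <- p + 1L
    e_lo <- i_s + model$min_intron_len - 1L
    e_hi <- min(i_s + model$max_intron_len - 1L, n - 5L)
    if (e_hi < e_lo) next
    ends_i <- sort(acc_ends[acc_ends >= e_lo & acc_ends <= e_hi])
    found <- NULL
    for (e_i in ends_i) {
      b_i <- .leftmost_bp(i_s, e_i, bp_starts, model)
      if (is.na(b_i)) next
      # reconstructed external donor: G1 + 5 nt following the internal acceptor
      w <- paste(c(ch[p], ch[(e_i + 1L):(e_i + 5L)]), collapse = "")
      if (!iupac_match(model$donor_pattern, w)) next
      # external intron: G1 + remainder; length 1 + (E - e_i)
      E_lo <- e_i + model$min_intron_len - 1L  # 1 + E - e_i >= min
      E_hi <- min(e_i + model$max_intron_len - 1L, n)
      ends_e <- sort(acc_ends[acc_ends >= E_lo & acc_ends <= E_hi])
      for (E in ends_e) {
        # BP of external intron must lie after the reconstructed donor
        b_e <- .leftmost_bp(e_i, E, bp_starts, model)
        if (is.na(b_e)) next
        found <- list(e_i = e_i, b_i = b_i, E = E, b_e = b_e)
        break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) next
    e_i <- found$e_i; E <- found$E
    hits[[length(hits) + 1L]] <- structure(list(
      location = interval(id, p, E),
      seq = substr(s, p, E),
      g1 = p,
      internal = list(start = i_s, end = e_i, bp_start = found$b_i,
                      bp_end = found$b_i + 5L,
                      donor_seq = substr(s, i_s, i_s + 5L),
                      acceptor_seq = substr(s, e_i - 2L, e_i)),
      external = list(g1 = p, cont_start = e_i + 1L, end = E,
                      bp_start = found$b_e, bp_end = found$b_e + 5L,
                      donor_seq = paste0(ch[p], substr(s, e_i + 1L, e_i + 4L + 1L)),
                      acceptor_seq = substr(s, E - 2L, E)),
      central_signature = substr(s, e_i - 1L, e_i + 1L),
      a23_alternative = (E < n && ch[E + 1L] == "G")
    ), class = "stwintron")
  }
  hits
}

#' @export
print.stwintron <- function(x, ...) {
  cat(sprintf(
    "(D1,2) stwintron %s:%d-%d (%s)  internal %d-%d  external G1=%d + %d-%d  centre %s%s\n",
    x$location$seq_id, x$location$start, x$location$end, x$location$strand,
    x$internal$start, x$internal$end, x$g1, x$external$cont_start,
    x$external$end, x$central_signature,
    if (x$a23_alternative) "  [alt (A2,3)]" else ""))
  invisible(x)
}

#' Flatten a list of stwintron objects into a feature table
#'
#' @param stws list returned by [find_d12_stwintrons()] or [scan_genome()].
#' @return data.frame with per-feature coordinates on the forward axis.
#' @export
stwintron_table <- function(stws) {
  if (!length(stws)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      internal_start = integer(0), internal_end = integer(0),
                      central_signature = character(0),
                      a23_alternative = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(stws, function(x) data.frame(
    seq_id = x$location$seq_id, start = x$location$start,
    end = x$location$end, strand = x$location$strand,
    internal_start = x$internal$start, internal_end = x$internal$end,
    central_signature = x$central_signature,
    a23_alternative = x$a23_alternative, stringsAsFactors = FALSE
  )))
}

# Map an interval on the reverse-complement of a sequence of length n back to
# forward-axis coordinates.
.rc_coord <- function(start, end, n) {
  c(start = n - end + 1L, end = n - start + 1L)
}

#' Scan one or more sequences for stwintrons (and canonical introns)
#'
#' Batch driver over a named set of sequences, optionally on both strands.
#' Reverse-strand hits are reported with strand `"-"` and coordinates on the
#' forward axis. Overlapping hits on opposite strands are both reported: a
#' genuine (stw)intron is only functional on the coding strand, but without
#' annotation the coding strand is unknown.
#'
#' @param sequences named character vector of DNA strings (or a single
#'   string / [genomic_sequence()]).
#' @param model an [intron_model()].
#' @param both_strands scan the reverse complement too?
#' @param what `"stwintrons"`, `"introns"` or both.
#' @return list with elements `stwintrons` (data.frame, ordered by seq_id and
#'   start; attribute `"objects"` holds the stwintron objects with their
#'   strand-local coordinates) and `introns` (data.frame) as requested.
#' @export
scan_genome <- function(sequences, model = intron_model(), both_strands = TRUE,
                        what = c("stwintrons", "introns")) {
  what <- match.arg(what, several.ok = TRUE)
  if (inherits(sequences, "genomic_sequence")) {
    sequences <- setNames(sequences$residues, sequences$id)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  stw_rows <- list(); stw_objs <- list(); int_rows <- list()
  for (sid in names(sequences)) {
    s <- toupper(sequences[[sid]])
    n <- nchar(s)
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      scan_s <- if (strand == "+") s else reverse_complement(s)
      if ("stwintrons" %in% what) {
        hits <- find_d12_stwintrons(genomic_sequence(sid, scan_s), model)
        for (h in hits) {
          h$location$strand <- strand
          fwd <- if (strand == "+") {
            c(start = h$location$start, end = h$location$end,
              istart = h$internal$start, iend = h$internal$end)
          } else {
            loc <- .rc_coord(h$location$start, h$location$end, n)
            ic <- .rc_coord(h$internal$start, h$internal$end, n)
            c(start = loc[["start"]], end = loc[["end"]],
              istart = ic[["start"]], iend = ic[["end"]])
          }
          stw_rows[[length(stw_rows) + 1L]] <- data.frame(
            seq_id = sid, start = fwd[["start"]], end = fwd[["end"]],
            strand = strand, internal_start = fwd[["istart"]],
            internal_end = fwd[["iend"]],
            central_signature = h$central_signature,
            a23_alternative = h$a23_alternative, stringsAsFactors = FALSE)
          stw_objs[[length(stw_objs) + 1L]] <- h
        }
      }
      if ("introns" %in% what) {
        ins <- find_canonical_introns(genomic_sequence(sid, scan_s), model)
        if (nrow(ins)) {
          if (strand == "-") {
            tmp_start <- n - ins$end + 1L
            tmp_end <- n - ins$start + 1L
            bp_s <- n - ins$bp_end + 1L
            bp_e <- n - ins$bp_start + 1L
            ins$start <- tmp_start; ins$end <- tmp_end
            ins$bp_start <- bp_s; ins$bp_end <- bp_e
          }
          ins$seq_id <- sid; ins$strand <- strand
          int_rows[[length(int_rows) + 1L]] <- ins
        }
      }
    }
  }
  out <- list()
  if ("stwintrons" %in% what) {
    df <- if (length(stw_rows)) do.call(rbind, stw_rows) else
      stwintron_table(list())
    if (nrow(df)) {
      o <- order(df$seq_id, df$start, df$end, df$strand)
      df <- df[o, , drop = FALSE]
      stw_objs <- stw_objs[o]
      rownames(df) <- NULL
    }
    attr(df, "objects") <- stw_objs
    out$stwintrons <- df
  }
  if ("introns" %in% what) {
    df <- if (length(int_rows)) do.call(rbind, int_rows) else
      data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    if (nrow(df)) {
      df <- df[order(df$seq_id, df$start, df$end, df$strand), , drop = FALSE]
      rownames(df) <- NULL
    }
    out$introns <- df
  }
  out
}
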