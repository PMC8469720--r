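# Terminal-inverted-repeat detection by self-reverse-complement alignment,
# degenerate 10-nt palindrome scanning, and a simplified two-molecule duplex
# complementarity score.

#' The 10-nt palindrome carried by sister (stw)introns
#' @export
PALINDROME_PATTERN <- "WTTCTAGAAA"

#' Detect a terminal inverted repeat by self-reverse-complement alignment
#'
#' Globally aligns `s` with its own reverse complement. By construction that
#' alignment is symmetric: matching columns near the start correspond to
#' positions near the 5' end pairing (as reverse complements) with positions
#' near the 3' end. The TIR arm is extracted as the maximal prefix run of
#' aligned columns whose every covering 10-column window has identity >=
#' `min_identity`, trimmed back to the last matching column; the mirror-image
#' 3' arm is implied. For fully self-symmetric sequences (type-2 cropped
#' introns are essentially one overlapping TIR) the arms are capped so they
#' overlap by at most the 10-nt palindrome.
#'
#' @param s DNA string, `nchar(s) >= 2 * min_arm`.
#' @param min_arm minimal arm length (nt) to call a TIR present (default 30).
#' @param min_identity windowed identity threshold in percent (default 60).
#' @param scoring see [alignment_scoring()].
#' @return list of class `"symmetry_report"`: `tir_present`, `arm5`, `arm3`
#'   ([interval()]s on `s`), `arm_length`, `arm_identity`, `spacer_length`
#'   (0 for overlapping arms), `palindrome_hits` (see
#'   [find_palindrome_hits()]), `duplex_score`, `duplex_score_normalised`.
#' @export
find_tir <- function(s, min_arm = 30L, min_identity = 60,
                     scoring = alignment_scoring()) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < 2L * min_arm) {
    stop("sequence shorter than 2 * min_arm (", 2L * min_arm, " nt)")
  }
  aln <- global_align(s, reverse_complement(s), scoring)
  cols <- .aln_columns(aln)
  C <- nrow(cols)
  m <- as.numeric(cols$match)
  w <- 10L
  win <- as.numeric(stats::filter(m, rep(1 / w, w), sides = 1))
  # win[i] covers columns (i-9)..i, defined for i >= 10
  ok <- !is.na(win) & win >= min_identity / 100
  # maximal prefix run: largest j such that every window fully inside
  # columns 1..j passes
  first_fail <- which(seq_len(C) >= w & !ok)
  run <- if (!length(first_fail)) C else {
    j <- first_fail[1]
    if (j == w) 0L else j - 1L  # last passing column index
  }
  arm_len <- 0L; arm_id <- NA_real_
  if (run > 0L) {
    run <- min(run, (C + w) %/% 2L)  # arms overlap by at most the palindrome
    # refine the arm end within the run: the prefix maximising the excess of
    # matches over the identity threshold, so chance matches in the spacer do
    # not drag the arm outward
    excess <- cumsum(m[seq_len(run)] - min_identity / 100)
    if (max(excess) > 0) {
      run <- which.max(excess)
      arm_len <- max(cols$pos_a[seq_len(run)])
      arm_id <- 100 * mean(cols$match[seq_len(run)])
    }
  }
  hits <- find_palindrome_hits(s)
  dup <- duplex_score(s)
  tir <- arm_len >= min_arm
  structure(list(
    tir_present = tir,
    arm5 = if (tir) interval("self", 1L, arm_len) else NULL,
    arm3 = if (tir) interval("self", n - arm_len + 1L, n) else NULL,
    arm_length = arm_len,
    arm_identity = arm_id,
    spacer_length = if (tir) max(0L, n - 2L * arm_len) else NA_integer_,
    palindrome_hits = hits,
    duplex_score = dup$score,
    duplex_score_normalised = dup$normalised
  ), class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  if (x$tir_present) {
    cat(sprintf("TIR: arm %d nt at %.1f%% identity, spacer %d nt; %d palindrome hit(s); duplex %.2f\n",
                x$arm_length, x$arm_identity, x$spacer_length,
                nrow(x$palindrome_hits), x$duplex_score_normalised))
  } else {
    cat("no TIR detected\n")
  }
  invisible(x)
}

#' Scan for degenerate copies of the 10-nt palindrome
#'
#' Every window of length 10 is scored against the pattern (default
#' `WTTCTAGAAA`); windows conserving at least `min_matches` positions are
#' hits (the >7-of-10 presence criterion). Overlapping hits are allowed.
#'
#' @param s DNA string.
#' @param pattern IUPAC pattern (default the sister-intron palindrome).
#' @param min_matches minimal conserved positions (default 8).
#' @return data.frame `start`, `end`, `matches`, `observed`, `w_base`
#'   (the base at the degenerate W position: `"A"`, `"T"` or `"other"`).
#' @export
find_palindrome_hits <- function(s, pattern = PALINDROME_PATTERN,
                                 min_matches = 8L) {
  s <- toupper(s)
  k <- nchar(pattern)
  n <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      matches = integer(0), observed = character(0),
                      w_base = character(0), stringsAsFactors = FALSE)
  if (n < k) return(empty)
  starts <- seq_len(n - k + 1L)
  wins <- substring(s, starts, starts + k - 1L)
  matches <- vapply(wins, iupac_match_count, integer(1), pattern = pattern,
                    USE.NAMES = FALSE)
  keep <- which(matches >= min_matches)
  if (!length(keep)) return(empty)
  wb <- substr(wins[keep], 1L, 1L)
  wb[!wb %in% c("A", "T")] <- "other"
  data.frame(start = starts[keep], end = starts[keep] + k - 1L,
             matches = matches[keep], observed = wins[keep], w_base = wb,
             stringsAsFactors = FALSE)
}

#' Two-molecule duplex complementarity score
#'
#' Simplified surrogate for co-folding two debranched intron molecules: the
#' best gapless antiparallel register of `s` against a second copy of itself.
#' Paired positions score +2 for Watson-Crick, +1 for G.T (G.U on RNA), 0
#' otherwise; no thermodynamics. The normalised score divides by `2 * nchar(s)`
#' (a perfect self-complementary duplex scores 1).
#'
#' @param s DNA string.
#' @return list `score`, `normalised`, `offset` (register shift of the best
#'   pairing).
#' @export
duplex_score <- function(s) {
  s <- toupper(s)
  if (!nzchar(s)) return(list(score = 0, normalised = 0, offset = 0L))
  res <- .duplex_best_cpp(s)
  list(score = res$score, normalised = res$score / (2 * nchar(s)),
       offset = res$offset)
}
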