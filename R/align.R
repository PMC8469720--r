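# Global pairwise alignment (affine gaps) and alignment bookkeeping shared by
# the family, symmetry and crop modules.

#' Default alignment scoring
#'
#' Match +2, mismatch -1, gap open -4, gap extend -1; a gap of length k costs
#' `gap_open + k * gap_extend`. Identity is matches / aligned columns (gaps
#' count as columns).
#' @return named list of scoring parameters.
#' @export
alignment_scoring <- function() {
  list(match = 2, mismatch = -1, gap_open = 4, gap_extend = 1)
}

#' Global alignment of two DNA strings
#'
#' Needleman-Wunsch with affine gap penalties and a fixed, deterministic
#' traceback (diagonal preferred over up over left at score ties), so the same
#' inputs always give byte-identical alignments.
#'
#' @param a,b non-empty DNA strings.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (penalties given as positive numbers for the gap terms).
#' @return list of class `"pairwise_alignment"`: `aligned_a`, `aligned_b`
#'   (gapped strings of equal length), `score`, `percent_identity`
#'   (matches / columns x 100), `n_columns`, `n_matches`.
#' @export
global_align <- function(a, b, scoring = alignment_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("global_align: empty input sequence")
  res <- .nw_align_cpp(toupper(a), toupper(b),
                       scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  ca <- strsplit(res$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(res$aligned_b, "", fixed = TRUE)[[1]]
  m <- ca == cb & ca != "-"
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score,
                 percent_identity = 100 * sum(m) / length(m),
                 n_columns = length(m), n_matches = sum(m)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("global alignment: %d columns, %d matches (%.1f%%), score %.1f\n",
              x$n_columns, x$n_matches, x$percent_identity, x$score))
  invisible(x)
}

# Per-column bookkeeping of an alignment: for each column, the coordinate in a
# (0 if gap), coordinate in b (0 if gap), and match flag.
.aln_columns <- function(aln) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  pos_a <- cumsum(ca != "-") * (ca != "-")
  pos_b <- cumsum(cb != "-") * (cb != "-")
  data.frame(pos_a = pos_a, pos_b = pos_b, match = (ca == cb & ca != "-"))
}

# High-identity local blocks of an alignment of `a` against template `b`.
# Columns are marked when any covering window of `window` columns has
# identity >= min_identity; adjacent marked columns merge into blocks.
# Returns data.frame(a_start, a_end, b_start, b_end, columns, identity).
.local_blocks <- function(aln, window = 20L, min_identity = 60) {
  cols <- .aln_columns(aln)
  C <- nrow(cols)
  if (C < window) return(NULL)
  m <- as.numeric(cols$match)
  # win[i] = identity over columns (i-window+1)..i; NA before the first window
  win <- as.numeric(stats::filter(m, rep(1 / window, window), sides = 1))
  marked <- rep(FALSE, C)
  pass <- which(!is.na(win) & win >= min_identity / 100)
  for (i in pass) marked[(i - window + 1L):i] <- TRUE
  if (!any(marked)) return(NULL)
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  blocks <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    # trim leading/trailing mismatch columns
    while (i0 < i1 && !cols$match[i0]) i0 <- i0 + 1L
    while (i1 > i0 && !cols$match[i1]) i1 <- i1 - 1L
    sub <- cols[i0:i1, ]
    ba <- sub$pos_a[sub$pos_a > 0]; bb <- sub$pos_b[sub$pos_b > 0]
    data.frame(a_start = min(ba), a_end = max(ba),
               b_start = min(bb), b_end = max(bb),
               columns = i1 - i0 + 1L,
               identity = 100 * mean(sub$match))
  })
  do.call(rbind, blocks)
}
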