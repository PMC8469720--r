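# The three documented stwintron -> canonical-intron derivation paths and
# breakpoint inference for observed parent/derivative pairs.
#
# Type-2 products follow the MMEJ central-deletion model: a double-stranded
# break between the two 10-nt palindrome copies is repaired using the
# palindromes as microhomologies, deleting everything from the end of the 5'
# copy through the end of the 3' copy and leaving a single retained copy. The
# retained copy is emitted at the 5' copy's position with the perfect sequence
# TTTCTAGAAA (the data cannot distinguish which copy physically survives;
# this convention is fixed). The parental G1 becomes exonic on every path
# that removes the internal splice sites, so those products carry a frame
# note: secondary mutations are required to restore the reading frame, and
# are context-dependent, so they are reported, never auto-applied.

.perfect_palindrome <- "TTTCTAGAAA"

# Palindrome copies used for a type-2 crop: the best hit inside the internal
# section and the best hit inside the external section (max matches, then
# leftmost). Returns list(p5, p3) of hit rows or NULL.
.crop_palindromes <- function(template) {
  sec <- .template_sections(template)
  hits <- find_palindrome_hits(template$seq)
  if (nrow(hits) < 2L) return(NULL)
  in_int <- hits[hits$end <= sec$internal[2] & hits$start >= sec$internal[1], ,
                 drop = FALSE]
  in_ext <- hits[hits$start >= sec$external[1], , drop = FALSE]
  if (!nrow(in_int) || !nrow(in_ext)) return(NULL)
  pick <- function(h) h[order(-h$matches, h$start), , drop = FALSE][1L, ]
  list(p5 = pick(in_int), p3 = pick(in_ext))
}

# Full-length canonical-intron validity of a product string.
.valid_full_intron <- function(s, model) {
  if (nchar(s) < model$min_intron_len || nchar(s) > model$max_intron_len) {
    return(FALSE)
  }
  ins <- find_canonical_introns(s, model, mode = "exhaustive")
  nrow(ins) > 0 && any(ins$start == 1L & ins$end == nchar(s))
}

.crop_event <- function(parent_id, path, bp5, bp3, retained, product, model,
                        frame_note) {
  structure(list(
    parent_id = parent_id, path = path,
    breakpoint5 = bp5, breakpoint3 = bp3,
    retained_palindrome = retained,
    product = product,
    product_valid_intron = .valid_full_intron(product, model),
    frame_note = frame_note
  ), class = "crop_event")
}

#' @export
print.crop_event <- function(x, ...) {
  cat(sprintf("crop event [%s]: breakpoints %s..%s, product %d nt (%svalid intron)%s\n",
              x$path, x$breakpoint5, x$breakpoint3, nchar(x$product),
              if (x$product_valid_intron) "" else "NOT ",
              if (x$frame_note != "none") paste0("  [", x$frame_note, "]") else ""))
  invisible(x)
}

#' Predict the type-2 (MMEJ central deletion) crop product of a stwintron
#'
#' Deletes from the end of the 5' palindrome copy (in the internal intron)
#' through the end of the 3' copy (in the external intron) and drops the
#' leading G1, fusing the internal intron's 5' part to the external intron's
#' 3' part: the product begins with the internal donor and ends with the
#' external acceptor, i.e. it is a canonical intron carrying exactly one,
#' perfect, palindrome copy.
#'
#' @param template a full-span `"stwintron"` object whose sequence carries a
#'   palindrome copy in each section.
#' @param model an [intron_model()] used to validate the product.
#' @return a `"crop_event"`; breakpoints are positions in the parent sequence
#'   (first and last deleted nucleotide).
#' @export
predict_type2_crop <- function(template, model = intron_model()) {
  pp <- .crop_palindromes(template)
  if (is.null(pp)) {
    stop("type-2 crop needs a palindrome copy in each of the internal and external sections")
  }
  s <- template$seq
  del_from <- pp$p5$end + 1L
  del_to <- pp$p3$end
  product <- paste0(substr(s, 2L, pp$p5$end), substr(s, del_to + 1L, nchar(s)))
  # canonical breakpoints: maximal right-shift within the microhomology
  # (identical product; same convention as infer_crop_breakpoints)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  while (del_to < length(ch) && ch[del_from] == ch[del_to + 1L]) {
    del_from <- del_from + 1L; del_to <- del_to + 1L
  }
  # normalise the retained copy to the perfect palindrome
  r_start <- pp$p5$start - 1L  # shifted left by the dropped G1
  substr(product, r_start, r_start + 9L) <- .perfect_palindrome
  .crop_event(
    parent_id = template$location$seq_id, path = "type2",
    bp5 = del_from, bp3 = del_to,
    retained = interval("product", r_start, r_start + 9L),
    product = product, model = model,
    frame_note = "g1_exonised_requires_compensation"
  )
}

# String-only view used by the family classifier; NULL when the template has
# no usable palindrome pair.
predict_type2_crop_seq <- function(template, model = intron_model()) {
  pp <- .crop_palindromes(template)
  if (is.null(pp)) return(NULL)
  predict_type2_crop(template, model)$product
}

#' Predict the type-1 crop product (external intron loss)
#'
#' The product is the internal intron verbatim; the external intron
#' (including G1) is deleted, so no frame compensation is needed.
#'
#' @inheritParams predict_type2_crop
#' @return a `"crop_event"`.
#' @export
predict_type1_crop <- function(template, model = intron_model()) {
  sec <- .template_sections(template)
  s <- template$seq
  product <- substr(s, sec$internal[1], sec$internal[2])
  .crop_event(
    parent_id = template$location$seq_id, path = "type1",
    bp5 = NA_integer_, bp3 = NA_integer_,
    retained = NULL, product = product, model = model,
    frame_note = "none"
  )
}

#' Predict the long-intron derivation product
#'
#' One-step excision product: the whole stwintron minus the leading G1,
#' validated as a single canonical intron (internal donor, external BP and
#' acceptor); the internal BP is free to degenerate afterwards. G1 becomes
#' exonic, so the frame note is set.
#'
#' @inheritParams predict_type2_crop
#' @return a `"crop_event"`.
#' @export
predict_long_intron <- function(template, model = intron_model()) {
  s <- template$seq
  product <- substr(s, 2L, nchar(s))
  .crop_event(
    parent_id = template$location$seq_id, path = "long_intron",
    bp5 = NA_integer_, bp3 = NA_integer_,
    retained = NULL, product = product, model = model,
    frame_note = "g1_exonised_requires_compensation"
  )
}

#' Infer crop breakpoints from an observed parent/derivative pair
#'
#' Globally aligns the derivative to the parent and reports the single largest
#' internal deletion (a gap run in the derivative row) as the crop. The path
#' is classified from the deleted span: a deletion reaching the parent's 3'
#' terminus is a type-1 crop (external intron loss); an interior deletion is a
#' type-2 crop.
#'
#' @param parent parent (stwintron) sequence string.
#' @param derivative candidate derived intron sequence string.
#' @param min_deletion smallest deletion accepted as a crop (default 20 nt).
#' @param scoring see [alignment_scoring()].
#' @return a `"crop_event"` whose `breakpoint5`/`breakpoint3` are the first
#'   and last deleted parent positions, or `NULL` ("not a crop pair") when no
#'   deletion of at least `min_deletion` nt is found.
#' @export
infer_crop_breakpoints <- function(parent, derivative, min_deletion = 20L,
                                   scoring = alignment_scoring()) {
  if (!nzchar(parent) || !nzchar(derivative)) stop("empty input sequence")
  aln <- global_align(derivative, parent, scoring)
  cols <- .aln_columns(aln)
  gap <- cols$pos_a == 0  # derivative gap = deleted parent positions
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_deletion)
  # interior runs only: a run touching column 1 or C is terminal context
  if (!length(keep)) return(NULL)
  widths <- r$lengths[keep]
  k <- keep[which.max(widths)]
  del_cols <- starts[k]:ends[k]
  parent_pos <- cols$pos_b[del_cols]
  parent_pos <- parent_pos[parent_pos > 0]
  if (!length(parent_pos)) return(NULL)
  bp5 <- min(parent_pos); bp3 <- max(parent_pos)
  # canonicalise a deletion inside a repeat: slide it as far 3' as the
  # microhomology allows, so the retained copy sits at the 5' position
  # (the MMEJ convention used by predict_type2_crop)
  pch <- strsplit(toupper(parent), "", fixed = TRUE)[[1]]
  while (bp3 < length(pch) && pch[bp5] == pch[bp3 + 1L]) {
    bp5 <- bp5 + 1L; bp3 <- bp3 + 1L
  }
  path <- if (bp3 >= nchar(parent) - 3L) "type1" else "type2"
  ev <- .crop_event(
    parent_id = NA_character_, path = path,
    bp5 = bp5, bp3 = bp3, retained = NULL,
    product = derivative, model = intron_model(),
    frame_note = if (path == "type2") "g1_exonised_requires_compensation"
    else "none"
  )
  ev
}
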