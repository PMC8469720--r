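# SYNTHETIC stand-ins for two published reference elements whose primary
# sequences are not redistributable here. Each is constructed to the
# *published geometry* of its namesake and is used to check that the
# symmetry detector recovers that geometry:
#
# - standin_hco096a: a 93-nt type-2-cropped-style intron that is one
#   overlapping terminal inverted repeat: 49-nt arms sharing the central
#   perfect 10-nt palindrome, with 13/49 arm mismatches (~73.5% identity).
# - standin_hco066a: a 207-nt stwintron-style element with 48-nt terminal
#   arms at 35/48 matches (~72.9% identity) and 102 nt between the end of
#   the 5' palindrome copy and the start of the 3' copy.
#
# Constructions are deterministic (fixed seeds); mismatch positions are
# spread evenly so no 10-nt window drops below the 60% detector floor.

.standin_mutate <- function(chars, k, protect) {
  # substitute k evenly spread positions outside `protect`
  cand <- setdiff(seq_along(chars), protect)
  pos <- cand[round(seq(1, length(cand), length.out = k))]
  for (i in pos) {
    chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  }
  chars
}

standin_hco096a <- function() {
  set.seed(960L)
  # left half (41 nt) + central perfect palindrome (10 nt) + right half
  # (42 nt) = 93 nt; right half is the mutated reverse complement of
  # (1 random nt + left half)
  left <- sample(c("A", "C", "G", "T"), 41, replace = TRUE)
  pal <- strsplit("TTTCTAGAAA", "")[[1]]
  pad <- sample(c("A", "C", "G", "T"), 1)
  right <- strsplit(reverse_complement(paste(c(pad, left), collapse = "")),
                    "")[[1]]
  right <- .standin_mutate(right, 13L, integer(0))
  paste(c(left, pal, right), collapse = "")
}

.IUPAC_COMP_STANDIN <- c(A = "T", C = "G", G = "C", T = "A")

standin_hco066a <- function() {
  set.seed(660L)
  N <- 207L
  ch <- sample(c("A", "C", "G", "T"), N, replace = TRUE)
  # 5' arm 1..48 ends with the perfect 10-nt palindrome
  ch[39:48] <- strsplit("TTTCTAGAAA", "")[[1]]
  # 3' arm 160..207 starts as the exact reverse complement of the 5' arm
  for (k in 0:47) ch[160L + k] <- .IUPAC_COMP_STANDIN[[ch[48L - k]]]
  # ... which would place a third palindrome copy at 160..169 (the mirror of
  # the 5' copy); degrade it below the >7/10 hit threshold. These three
  # substitutions hit arm columns 45, 42 and 39, keeping the arm's outer
  # end (columns 46-47) matching so trailing-trim does not shorten the arm.
  for (p in c(163L, 166L, 169L)) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  # actual 3' copy (W = A), 102 nt downstream of the 5' copy's end; its last
  # base occupies position 160, which unavoidably mismatches arm column 48
  ch[151:160] <- strsplit("ATTCTAGAAA", "")[[1]]
  # top up arm mismatches to 13/47 (~72% arm identity over the trimmed
  # 47-column arm), spread over the deep 3' arm (affecting arm columns
  # 1..38); arm column i pairs with position N+1-i
  mism <- function() sum(vapply(1:47, function(i) {
    ch[i] != .IUPAC_COMP_STANDIN[[ch[N + 1L - i]]]
  }, logical(1)))
  k <- max(0L, 13L - mism())
  if (k > 0L) {
    for (p in round(seq(171, 206, length.out = k))) {
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    }
  }
  paste(ch, collapse = "")
}
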