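# Independent brute-force oracles. These deliberately avoid the package's
# vectorised scanning / DP code paths: plain nested loops and hardcoded
# IUPAC sets, so they can stand as ground truth for the implementation.

OR_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

or_match <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  if (length(p) != length(w)) return(FALSE)
  for (i in seq_along(p)) {
    if (w[i] == "N") {
      if (p[i] != "N") return(FALSE)
    } else if (!(w[i] %in% OR_SETS[[p[i]]])) return(FALSE)
  }
  TRUE
}

or_match_count <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  sum(vapply(seq_along(p), function(i) {
    if (w[i] == "N") p[i] == "N" else w[i] %in% OR_SETS[[p[i]]]
  }, logical(1)))
}

sseq <- function(a, b) if (a > b) integer(0) else seq(a, b)

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force canonical-intron enumeration: every (donor, BP, acceptor)
# index triple satisfying the grammar. Returns df(start, end, bp_start),
# minimal mode keeps the shortest intron (leftmost BP) per donor.
or_find_introns <- function(s, model = intron_model(),
                            mode = c("intron_definition", "exhaustive")) {
  mode <- match.arg(mode)
  n <- nchar(s)
  sub <- function(i, j) substr(s, i, j)
  rows <- list()
  for (d in seq_len(max(0, n - 5))) {
    if (!or_match(model$donor_pattern, sub(d, d + 5))) next
    hits_d <- list()
    for (e in sseq(d + model$min_intron_len - 1, min(n, d + model$max_intron_len - 1))) {
      if (e < d + 8) next
      if (!or_match(model$acceptor_pattern, sub(e - 2, e))) next
      bps <- integer(0)
      for (b in sseq(d + 6, e - 11)) {
        if (b + 5 > n) break
        if (!or_match(model$bp_pattern, sub(b, b + 5))) next
        gap <- e - b - 8
        if (gap >= model$bp_to_acceptor_min && gap <= model$bp_to_acceptor_max) {
          bps <- c(bps, b)
        }
      }
      if (length(bps)) {
        hits_d[[length(hits_d) + 1L]] <-
          data.frame(start = d, end = e, bp_start = min(bps))
        if (mode == "intron_definition") break
      }
    }
    rows <- c(rows, hits_d)
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      bp_start = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

# Brute-force (D1,2) enumeration for small sequences: for each candidate G1,
# all internal intron placements (shortest first, leftmost BP), checking the
# reconstructed external donor and the minimal valid external intron.
or_find_d12 <- function(s, model = intron_model()) {
  n <- nchar(s)
  sub <- function(i, j) substr(s, i, j)
  donor_ok <- function(w, allow_gc) {
    if (or_match(model$donor_pattern, w)) return(TRUE)
    allow_gc && substr(w, 2, 2) == "C" &&
      or_match(model$donor_pattern, paste0(substr(w, 1, 1), "T", substr(w, 3, 6)))
  }
  res <- list()
  for (p in seq_len(max(0, n - 12))) {
    if (substr(s, p, p) != "G") next
    if (p + 6 > n) next
    if (!donor_ok(sub(p + 1, p + 6), model$allow_gc_internal_donor)) next
    found <- NULL
    # enumerate internal introns starting at p+1 by increasing length
    for (L in sseq(model$min_intron_len, model$max_intron_len)) {
      e_i <- p + L
      if (e_i + 5 > n) break
      if (!or_match(model$acceptor_pattern, sub(e_i - 2, e_i))) next
      has_bp <- FALSE
      for (b in sseq(p + 7, e_i - 11)) {
        if (!or_match(model$bp_pattern, sub(b, b + 5))) next
        gap <- e_i - b - 8
        if (gap >= model$bp_to_acceptor_min &&
            gap <= model$bp_to_acceptor_max) { has_bp <- TRUE; break }
      }
      if (!has_bp) next
      if (!or_match(model$donor_pattern,
                    paste0(substr(s, p, p), sub(e_i + 1, e_i + 5)))) next
      # minimal external intron: G1 + remainder after e_i
      for (Le in sseq(model$min_intron_len, model$max_intron_len)) {
        E <- e_i + Le - 1
        if (E > n) break
        if (!or_match(model$acceptor_pattern, sub(E - 2, E))) next
        ok_bp <- FALSE
        for (b in sseq(e_i + 6, E - 11)) {
          if (!or_match(model$bp_pattern, sub(b, b + 5))) next
          gap <- E - b - 8
          if (gap >= model$bp_to_acceptor_min &&
              gap <= model$bp_to_acceptor_max) { ok_bp <- TRUE; break }
        }
        if (ok_bp) { found <- c(start = p, internal_end = e_i, end = E); break }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) res[[length(res) + 1L]] <- found
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), internal_end = integer(0),
                      end = integer(0)))
  }
  as.data.frame(do.call(rbind, res))
}

# Brute-force optimal affine alignment score for tiny strings: enumerate all
# complete alignments recursively and score each from its explicit gap
# structure.
or_align_best <- function(a, b, scoring = alignment_scoring()) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  score_alignment <- function(ops) {
    # ops: vector over {"M","X","Y"}
    sc <- 0; i <- 0; j <- 0; prev <- ""
    for (op in ops) {
      if (op == "M") {
        i <- i + 1; j <- j + 1
        sc <- sc + if (ca[i] == cb[j]) scoring$match else scoring$mismatch
      } else if (op == "X") {
        i <- i + 1
        sc <- sc - scoring$gap_extend - if (prev == "X") 0 else scoring$gap_open
      } else {
        j <- j + 1
        sc <- sc - scoring$gap_extend - if (prev == "Y") 0 else scoring$gap_open
      }
      prev <- op
    }
    sc
  }
  best <- -Inf
  recurse <- function(i, j, ops) {
    if (i == length(ca) && j == length(cb)) {
      best <<- max(best, score_alignment(ops))
      return(invisible())
    }
    if (i < length(ca) && j < length(cb)) recurse(i + 1, j + 1, c(ops, "M"))
    if (i < length(ca)) recurse(i + 1, j, c(ops, "X"))
    if (j < length(cb)) recurse(i, j + 1, c(ops, "Y"))
  }
  recurse(0, 0, character(0))
  best
}

or_tsd <- function(flank5, flank3, min_len = 2, max_len = 10) {
  n5 <- nchar(flank5)
  best <- 0
  for (k in seq_len(max_len)) {
    if (substr(flank5, n5 - k + 1, n5) == substr(flank3, 1, k)) {
      if (k >= min_len) best <- k
    }
  }
  best
}

# brute-force best terminal arm pair: max arm length L such that the first L
# and last L nt are reverse complements at >= min_id (gapless comparison)
or_best_terminal_arm <- function(s, min_id = 0.6) {
  n <- nchar(s)
  best <- 0
  for (L in seq_len(n %/% 2)) {
    a <- substr(s, 1, L)
    b <- substr(s, n - L + 1, n)
    rb <- reverse_complement(b)
    m <- sum(strsplit(a, "")[[1]] == strsplit(rb, "")[[1]])
    if (m / L >= min_id) best <- L
  }
  best
}

# shift a stwintron object (template-local coordinates) by an offset, for
# placing the template inside a longer pre-mRNA
offset_stwintron <- function(stw, offset) {
  stw$location$start <- stw$location$start + offset
  stw$location$end <- stw$location$end + offset
  stw$g1 <- stw$g1 + offset
  stw$internal$start <- stw$internal$start + offset
  stw$internal$end <- stw$internal$end + offset
  stw$external$cont_start <- stw$external$cont_start + offset
  stw$external$end <- stw$external$end + offset
  stw
}

# one shared template for tests that only need a valid stwintron
shared_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- make_template(seed = 42L)
    tpl
  }
})
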