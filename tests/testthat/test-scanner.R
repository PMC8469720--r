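# Scanner tests are built around explicit toy constructions on a poly-C
# background (C runs can form no donor/BP/acceptor motif, so every motif in
# the toy is planted) and brute-force oracle equivalence.

Cs <- function(n) strrep("C", n)

# exon(20) G1 [GTAAGT ... ACTAAC gap TAG] TAAGT ... ACTAAC gap TAG exon
toy_stwintron <- function(downstream_g = FALSE) {
  paste0(
    Cs(20), "G",
    "GTAAGT", Cs(19), "ACTAAC", Cs(10), "TAG",   # internal intron, 44 nt
    "TAAGT", Cs(15), "ACTAAC", Cs(10), "TAG",    # external continuation, 39 nt
    if (downstream_g) "G" else "C", Cs(19)
  )
}

test_that("find_canonical_introns finds exactly the planted intron", {
  s <- paste0(Cs(50), "GTAAGT", Cs(35), "ACTAAC", Cs(10), "TAG", Cs(50))
  ins <- find_canonical_introns(s)
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$start, 51L)
  expect_equal(ins$end, 110L)
  expect_equal(ins$donor_seq, "GTAAGT")
  expect_equal(ins$acceptor_seq, "TAG")
  expect_equal(ins$bp_start, 92L)
  orc <- or_find_introns(s)
  expect_equal(ins$start, orc$start)
  expect_equal(ins$end, orc$end)
  expect_equal(ins$bp_start, orc$bp_start)
})

test_that("poly-A sequence yields no introns", {
  expect_equal(nrow(find_canonical_introns(strrep("A", 500))), 0L)
})

test_that("intron-definition mode picks the nearer acceptor", {
  # two valid acceptors for one donor; minimal intron wins
  s <- paste0(Cs(10), "GTAAGT", Cs(25), "ACTAAC", Cs(10), "TAG",
              Cs(20), "TAG", Cs(10))
  mini <- find_canonical_introns(s)
  exh <- find_canonical_introns(s, mode = "exhaustive")
  expect_equal(nrow(mini), 1L)
  expect_gt(nrow(exh), 1L)
  expect_equal(mini$end, min(exh$end))
  orc <- or_find_introns(s)
  expect_equal(mini$end, orc$end[1])
})

test_that("scanner matches the brute-force oracle on random sequences", {
  set.seed(104)
  for (len in c(400L, 900L, 1500L)) {
    s <- rand_dna(len, gc = 0.5)
    got <- find_canonical_introns(s)
    orc <- or_find_introns(s)
    expect_equal(got$start, orc$start, info = paste("len", len))
    expect_equal(got$end, orc$end, info = paste("len", len))
    expect_equal(got$bp_start, orc$bp_start, info = paste("len", len))
  }
  # exhaustive mode on a shorter sequence
  s <- rand_dna(400)
  got <- find_canonical_introns(s, mode = "exhaustive")
  orc <- or_find_introns(s, mode = "exhaustive")
  expect_equal(got$start, orc$start)
  expect_equal(got$end, orc$end)
})

test_that("find_d12_stwintrons parses the constructed toy exactly", {
  s <- toy_stwintron()
  hits <- find_d12_stwintrons(s)
  expect_length(hits, 1L)
  h <- hits[[1]]
  expect_equal(h$location$start, 21L)
  expect_equal(h$g1, 21L)
  expect_equal(h$internal$start, 22L)
  expect_equal(h$internal$end, 65L)      # internal intron 44 nt
  expect_equal(h$location$end, 104L)     # external intron 40 nt incl. G1
  expect_equal(h$central_signature, "AGT")
  expect_false(h$a23_alternative)
  # oracle agreement
  orc <- or_find_d12(s)
  expect_equal(h$location$start, orc$start[1])
  expect_equal(h$internal$end, orc$internal_end[1])
  expect_equal(h$location$end, orc$end[1])
})

test_that("mutating the donor continuation abolishes the hit", {
  s <- toy_stwintron()
  substr(s, 66, 66) <- "C"   # T of the reconstructed external donor G1|T...
  expect_length(find_d12_stwintrons(s), 0L)
})

test_that("a downstream exonic G flags the (A2,3) alternative", {
  expect_true(find_d12_stwintrons(toy_stwintron(downstream_g = TRUE))[[1]]$a23_alternative)
  expect_false(find_d12_stwintrons(toy_stwintron(FALSE))[[1]]$a23_alternative)
})

test_that("GGC-starting stwintrons obey the allow_gc_internal_donor switch", {
  s <- toy_stwintron()
  substr(s, 23, 23) <- "C"   # internal donor GTAAGT -> GCAAGT
  expect_length(find_d12_stwintrons(s), 1L)
  off <- intron_model(allow_gc_internal_donor = FALSE)
  expect_length(find_d12_stwintrons(s, off), 0L)
})

test_that("scanner and oracle agree on the synthetic template", {
  tpl <- shared_template()
  got <- find_d12_stwintrons(tpl$seq)
  orc <- or_find_d12(tpl$seq)
  expect_equal(length(got), nrow(orc))
  for (i in seq_along(got)) {
    expect_equal(got[[i]]$location$start, orc$start[i])
    expect_equal(got[[i]]$internal$end, orc$internal_end[i])
    expect_equal(got[[i]]$location$end, orc$end[i])
  }
})

test_that("every reported stwintron re-validates after internal excision", {
  tpl <- shared_template()
  seqs <- c(toy_stwintron(), toy_stwintron(TRUE), tpl$seq)
  for (s in seqs) {
    for (h in find_d12_stwintrons(s)) {
      spliced <- paste0(substr(s, 1, h$internal$start - 1L),
                        substr(s, h$internal$end + 1L, nchar(s)))
      ins <- find_canonical_introns(spliced)
      # the external intron must start exactly at G1's position in the
      # spliced string
      expect_true(any(ins$start == h$g1 &
                        ins$end == h$location$end - (h$internal$end -
                                                       h$internal$start + 1L)))
    }
  }
})

test_that("reverse-strand hits are mapped to the forward axis", {
  s <- toy_stwintron()
  contig <- paste0(Cs(30), reverse_complement(s), Cs(15))
  res <- scan_genome(c(ctg = contig))
  df <- res$stwintrons
  minus <- df[df$strand == "-", , drop = FALSE]
  expect_equal(nrow(minus), 1L)
  # feature at 21..104 in s maps to forward-axis coordinates
  n <- nchar(contig)
  expect_equal(minus$start, 30L + (nchar(s) - 104L + 1L))
  expect_equal(minus$end, 30L + (nchar(s) - 21L + 1L))
})

test_that("scan_genome is deterministic and ordered; empty input is empty", {
  tpl <- shared_template()
  g <- c(a = paste0(Cs(25), tpl$seq, Cs(25)), b = toy_stwintron())
  r1 <- scan_genome(g)$stwintrons
  r2 <- scan_genome(g)$stwintrons
  attr(r1, "objects") <- attr(r2, "objects") <- NULL
  expect_identical(r1, r2)
  expect_false(is.unsorted(order(r1$seq_id, r1$start)))
  empty <- scan_genome(setNames(character(0), character(0)))
  expect_equal(nrow(empty$stwintrons), 0L)
})
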