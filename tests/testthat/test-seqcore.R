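test_that("reverse_complement handles palindromes, degenerate codes and errors", {
  expect_identical(reverse_complement("TTTCTAGAAA"), "TTTCTAGAAA")
  expect_identical(reverse_complement("GGTAAG"), "CTTACC")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("RYWSKMN"), "NKMSWRY")
  expect_error(reverse_complement("ACGU"), "position 4")
})

test_that("reverse_complement is an involution on random IUPAC strings", {
  set.seed(101)
  alph <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")
  ok <- vapply(1:1000, function(i) {
    s <- paste(sample(alph, sample(1:40, 1), replace = TRUE), collapse = "")
    identical(reverse_complement(reverse_complement(s)), s)
  }, logical(1))
  expect_true(all(ok))
})

test_that("iupac_match follows the degeneracy sets, with conservative N", {
  expect_true(iupac_match("WTTCTAGAAA", "ATTCTAGAAA"))
  expect_true(iupac_match("GTRWGY", "GTAAGT"))
  expect_true(iupac_match("YAG", "TAG"))
  expect_false(iupac_match("YAG", "GAG"))
  # N in the window only matches a pattern N
  expect_false(iupac_match("YAG", "NAG"))
  expect_true(iupac_match("NAG", "NAG"))
  expect_error(iupac_match("YAG", "TAGA"), "length")
})

test_that("iupac_match agrees with the independent matcher on random cases", {
  set.seed(102)
  alph <- c("A", "C", "G", "T", "N")
  pats <- c("GTRWGY", "RCTRAC", "YAG", "WTTCTAGAAA")
  ok <- vapply(1:200, function(i) {
    p <- sample(pats, 1)
    w <- paste(sample(alph, nchar(p), replace = TRUE), collapse = "")
    identical(iupac_match(p, w), or_match(p, w))
  }, logical(1))
  expect_true(all(ok))
})

test_that("FASTA round trip preserves records; empty file warns", {
  set.seed(103)
  seqs <- setNames(vapply(1:3, function(i) rand_dna(80), character(1)),
                   c("ctg1", "ctg2", "ctg3"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_identical(unname(back[names(seqs)]), unname(seqs))

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_warning(res <- read_fasta(empty), "empty")
  expect_length(res, 0)
})

test_that("GFF3 round trip preserves coordinates and attributes", {
  feats <- data.frame(
    seq_id = c("ctg1", "ctg1", "ctg2"),
    start = c(11L, 40L, 5L), end = c(20L, 120L, 64L),
    strand = c("+", "-", "+"),
    type = c("intron", "stwintron", "intron"),
    ID = c("i1", "s1", "i2"),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, path)
  # on-disk coordinates are identical to the internal 1-based inclusive ones
  raw <- read.table(path, sep = "\t", comment.char = "#")
  expect_identical(raw$V4, feats$start)
  expect_identical(raw$V5, feats$end)
  back <- read_gff3(path)
  expect_identical(back$start, feats$start)
  expect_identical(back$end, feats$end)
  expect_identical(back$strand, feats$strand)
  expect_identical(back$type, feats$type)
  expect_identical(back$ID, feats$ID)
})

test_that("report writers emit TSV with header and JSON", {
  rows <- data.frame(id = c("a", "b"), x = c(1.5, 2.5))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(rows, tsv, "tsv")
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back, rows)
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rows, js, "json")
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE), rows)
})

test_that("interval and intron_model validate their invariants", {
  expect_error(interval("x", 5, 4), "invalid interval")
  expect_error(interval("x", 0, 4), "invalid interval")
  expect_error(intron_model(donor_pattern = "GT"), "6 nt")
  expect_error(intron_model(min_intron_len = 10), "combined motif")
  m <- intron_model(bp_pattern = "CTNAAY")
  expect_identical(m$bp_pattern, "CTNAAY")
})
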