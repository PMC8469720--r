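test_that("type-2 crop arithmetic on a constructed parent", {
  tpl <- shared_template()
  ev <- predict_type2_crop(tpl$stw)
  hits <- find_palindrome_hits(tpl$seq)
  # deletion spans end of 5' copy + 1 .. end of 3' copy, then canonically
  # right-shifted within the microhomology; G1 is dropped
  expect_gte(ev$breakpoint5, hits$end[1] + 1L)
  expect_equal(ev$breakpoint3 - ev$breakpoint5, hits$end[2] - hits$end[1] - 1L)
  del <- ev$breakpoint3 - ev$breakpoint5 + 1L
  expect_equal(nchar(ev$product), nchar(tpl$seq) - del - 1L)
  expect_true(ev$product_valid_intron)
  expect_equal(ev$frame_note, "g1_exonised_requires_compensation")
  # retained copy is the perfect palindrome at the 5' copy's position
  expect_identical(substr(ev$product, ev$retained_palindrome$start,
                          ev$retained_palindrome$end), "TTTCTAGAAA")
  # product begins with the internal donor and ends with the acceptor
  expect_identical(substr(ev$product, 1, 6), substr(tpl$seq, 2, 7))
  expect_identical(substr(ev$product, nchar(ev$product) - 2,
                          nchar(ev$product)),
                   substr(tpl$seq, nchar(tpl$seq) - 2, nchar(tpl$seq)))
})

test_that("type-2 products keep exactly one palindrome; parents two", {
  set.seed(117)
  for (sd in c(1, 2, 4)) {
    tpl <- make_template(seed = sd)
    expect_equal(nrow(find_palindrome_hits(tpl$seq)), 2L)
    p <- predict_type2_crop(tpl$stw)$product
    expect_equal(nrow(find_palindrome_hits(p)), 1L)
    expect_lt(nchar(p), 0.6 * nchar(tpl$seq))
  }
})

test_that("type-2 products classify as cropped_type2 against their parent", {
  tpl <- shared_template()
  p <- predict_type2_crop(tpl$stw)$product
  expect_equal(classify_relative(p, tpl$stw)$category, "cropped_type2")
})

test_that("type-1 crop returns the internal intron verbatim", {
  tpl <- shared_template()
  ev <- predict_type1_crop(tpl$stw)
  expect_identical(ev$product,
                   substr(tpl$seq, tpl$stw$internal$start,
                          tpl$stw$internal$end))
  expect_true(ev$product_valid_intron)
  expect_equal(ev$frame_note, "none")
  ins <- find_canonical_introns(ev$product)
  expect_true(any(ins$start == 1L & ins$end == nchar(ev$product)))
})

test_that("long-intron product is the parent minus G1", {
  tpl <- shared_template()
  ev <- predict_long_intron(tpl$stw)
  expect_equal(nchar(ev$product), nchar(tpl$seq) - 1L)
  expect_identical(substr(ev$product, 1, 6), substr(tpl$seq, 2, 7))
  expect_true(ev$product_valid_intron)
  expect_equal(ev$frame_note, "g1_exonised_requires_compensation")
})

test_that("alt one-step splicing equals carrying the long intron product", {
  tpl <- shared_template()
  up <- rand_dna(50); down <- rand_dna(50)
  pre <- paste0(up, tpl$seq, down)
  sp <- splice_stwintron(pre, offset_stwintron(tpl$stw, 50L))
  # excising the long product from a gene that carries it at the same site
  # (after the exonised G) gives the same mature message
  lng <- predict_long_intron(tpl$stw)$product
  gene2 <- paste0(up, "G", lng, down)
  mature2 <- paste0(up, "G", down)
  expect_identical(sp$alt_mature, mature2)
  expect_identical(gene2, pre)  # same genomic sequence, reinterpreted
})

test_that("breakpoint inference round-trips predict_type2_crop exactly", {
  for (sd in c(1, 2, 4, 5, 42)) {
    tpl <- make_template(seed = sd)
    ev <- predict_type2_crop(tpl$stw)
    inf <- infer_crop_breakpoints(tpl$seq, ev$product)
    expect_equal(inf$breakpoint5, ev$breakpoint5, info = paste("seed", sd))
    expect_equal(inf$breakpoint3, ev$breakpoint3, info = paste("seed", sd))
    expect_equal(inf$path, "type2")
  }
})

test_that("breakpoint inference classifies type-1 and rejects non-crops", {
  tpl <- shared_template()
  t1 <- predict_type1_crop(tpl$stw)
  inf <- infer_crop_breakpoints(tpl$seq, t1$product)
  expect_equal(inf$path, "type1")
  expect_equal(inf$breakpoint3, nchar(tpl$seq))
  expect_null(infer_crop_breakpoints(tpl$seq, tpl$seq))
  expect_error(infer_crop_breakpoints("", "ACGT"), "empty")
})

test_that("breakpoints survive 5% substitution noise within +/-3 nt", {
  set.seed(11)
  tpl <- shared_template()
  ev <- predict_type2_crop(tpl$stw)
  ch <- strsplit(ev$product, "")[[1]]
  pos <- sample(length(ch), round(0.05 * length(ch)))
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  noisy <- paste(ch, collapse = "")
  inf <- infer_crop_breakpoints(tpl$seq, noisy)
  expect_lte(abs(inf$breakpoint5 - ev$breakpoint5), 3L)
  expect_lte(abs(inf$breakpoint3 - ev$breakpoint3), 3L)
})

test_that("type-2 crop requires a palindrome copy in each section", {
  tpl <- shared_template()
  broken <- tpl$stw
  ch <- strsplit(broken$seq, "")[[1]]
  h <- find_palindrome_hits(broken$seq)
  ch[h$start[1]:(h$start[1] + 4L)] <- c("G", "C", "G", "C", "G")
  broken$seq <- paste(ch, collapse = "")
  expect_error(predict_type2_crop(broken), "palindrome")
})
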