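test_that("global_align scores identical sequences and errors on empties", {
  set.seed(106)
  s <- rand_dna(100)
  a <- global_align(s, s)
  expect_equal(a$percent_identity, 100)
  expect_equal(a$score, 200)
  expect_error(global_align("ACGT", ""), "empty")
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment is optimal: exhaustive enumeration oracle on tiny strings", {
  set.seed(107)
  ok <- vapply(1:40, function(i) {
    a <- rand_dna(sample(2:6, 1))
    b <- rand_dna(sample(2:6, 1))
    isTRUE(all.equal(global_align(a, b)$score, or_align_best(a, b)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("alignment of a substituted copy reaches the oracle optimum", {
  set.seed(108)
  s <- rand_dna(100)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(100, 10)
  for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  mut <- paste(ch, collapse = "")
  a <- global_align(s, mut)
  expect_gte(a$percent_identity, 90)
  expect_equal(a$score, 90 * 2 - 10 * 1)  # gapless diagonal is optimal here
})

test_that("alignment and traceback are deterministic", {
  set.seed(109)
  a <- rand_dna(80); b <- rand_dna(80)
  r1 <- global_align(a, b); r2 <- global_align(a, b)
  expect_identical(r1$aligned_a, r2$aligned_a)
  expect_identical(r1$aligned_b, r2$aligned_b)
  # degapping restores the inputs
  expect_identical(gsub("-", "", r1$aligned_a, fixed = TRUE), a)
  expect_identical(gsub("-", "", r1$aligned_b, fixed = TRUE), b)
})

test_that("collect_family separates copies from unrelated randoms", {
  tpl <- shared_template()
  set.seed(110)
  copies <- vapply(1:5, function(i) {
    evolve_copy(tpl, rate = 0.2, protect_motifs = TRUE)$seq
  }, character(1))
  randoms <- vapply(1:5, function(i) rand_dna(nchar(tpl$seq)), character(1))
  cands <- setNames(c(tpl$seq, copies, randoms),
                    c("seed", paste0("copy", 1:5), paste0("rnd", 1:5)))
  fam <- collect_family(cands, tpl$seq)
  expect_setequal(fam$member_id, c("seed", paste0("copy", 1:5)))
  expect_true(all(fam$identity >= 55))
  # threshold extremes
  expect_equal(nrow(collect_family(cands, tpl$seq, min_identity = 101)), 0L)
  expect_equal(nrow(collect_family(setNames(character(0), character(0)),
                                   tpl$seq)), 0L)
})

test_that("classify_relative recovers definitional constructions", {
  tpl <- shared_template()
  sec <- stwinscan:::.template_sections(tpl$stw)
  # internal intron verbatim -> type-1 crop
  internal <- substr(tpl$seq, sec$internal[1], sec$internal[2])
  expect_equal(classify_relative(internal, tpl$stw)$category, "cropped_type1")
  # MMEJ product -> type-2 crop
  t2 <- predict_type2_crop(tpl$stw)$product
  a2 <- classify_relative(t2, tpl$stw)
  expect_equal(a2$category, "cropped_type2")
  expect_false(isTRUE(a2$extra_g_subgroup))
  # template minus G1 with degraded internal BP -> long intron
  lng <- stwinscan:::.long_product(tpl$stw, tpl$m, intron_model())
  expect_equal(classify_relative(lng, tpl$stw)$category, "long_intron")
  # the template itself and a moderately evolved copy -> full sisters
  expect_equal(classify_relative(tpl$seq, tpl$stw)$category, "full_sister")
  set.seed(7)
  ev <- evolve_copy(tpl, rate = 0.2, protect_motifs = TRUE)
  expect_equal(classify_relative(ev$seq, tpl$stw)$category, "full_sister")
  # unrelated random sequence
  expect_equal(classify_relative(rand_dna(nchar(tpl$seq)), tpl$stw)$category,
               "unrelated")
})

test_that("the extra-G subgroup attribute is read before the acceptor", {
  tpl <- shared_template()
  t2 <- predict_type2_crop(tpl$stw)$product
  n <- nchar(t2)
  with_g <- paste0(substr(t2, 1, n - 3), "G", substr(t2, n - 2, n))
  a <- classify_relative(with_g, tpl$stw)
  expect_equal(a$category, "cropped_type2")
  expect_true(a$extra_g_subgroup)
})

test_that("sheared elements classify by their conserved section", {
  tpl <- shared_template()
  set.seed(111)
  sh_i <- stwinscan:::.shear_template(tpl, "internal")
  sh_e <- stwinscan:::.shear_template(tpl, "external")
  expect_equal(classify_relative(sh_i, tpl$stw)$category, "sheared_internal")
  expect_equal(classify_relative(sh_e, tpl$stw)$category, "sheared_external")
})

test_that("full sisters and unrelated satisfy the identity floor definition", {
  tpl <- shared_template()
  set.seed(112)
  for (i in 1:5) {
    ev <- evolve_copy(tpl, rate = runif(1, 0, 0.15), protect_motifs = TRUE)
    a <- classify_relative(ev$seq, tpl$stw)
    if (a$category == "full_sister") expect_gte(a$identity_to_seed, 55)
  }
  for (i in 1:3) {
    a <- classify_relative(rand_dna(200), tpl$stw)
    expect_equal(a$category, "unrelated")
    expect_lt(a$identity_to_seed, 55)
  }
})
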