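test_that("make_template honours its generator contract", {
  tpl <- shared_template()
  # exactly one stwintron, spanning the whole template
  hits <- find_d12_stwintrons(tpl$seq)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$location$start, 1L)
  expect_equal(hits[[1]]$location$end, nchar(tpl$seq))
  expect_identical(substr(tpl$seq, 1, 3), "GGT")
  # TIR with arm in the configured range
  tir <- find_tir(tpl$seq)
  expect_true(tir$tir_present)
  expect_gte(tir$arm_length, 45L - 5L)
  expect_lte(tir$arm_length, 55L + 5L)
  expect_gte(tir$arm_identity, 70)
  # exactly two palindrome copies: 5' perfect (W=T), 3' with W=A
  h <- find_palindrome_hits(tpl$seq)
  expect_equal(nrow(h), 2L)
  expect_identical(h$w_base, c("T", "A"))
  expect_equal(h$matches[1], 10L)
  # infeasible ranges fail loudly
  expect_error(make_template(template_params(arm_length = c(10L, 12L)),
                             max_attempts = 5L), "feasible")
})

test_that("evolve_copy at rate 0 is the identity; divergence is recorded", {
  tpl <- shared_template()
  ev0 <- evolve_copy(tpl, rate = 0, seed = 1)
  expect_identical(ev0$seq, tpl$seq)
  expect_equal(ev0$divergence, 0)
  ev <- evolve_copy(tpl, rate = 0.2, seed = 2)
  expect_gt(ev$divergence, 0.1)
  expect_lt(ev$divergence, 0.3)
  expect_equal(ev$n_subs,
               round(ev$divergence * sum(!seq_len(nchar(tpl$seq)) %in%
                                           tpl$protected)))
})

test_that("motif protection keeps copies splice-competent; unprotected decays", {
  tpl <- shared_template()
  set.seed(9)
  prot_ok <- vapply(1:100, function(i) {
    s <- evolve_copy(tpl, rate = 0.1, protect_motifs = TRUE)$seq
    hits <- find_d12_stwintrons(s)
    any(vapply(hits, function(h) h$location$start == 1L, logical(1)))
  }, logical(1))
  expect_equal(mean(prot_ok), 1)
  unprot_ok <- vapply(1:100, function(i) {
    s <- evolve_copy(tpl, rate = 0.1, protect_motifs = FALSE)$seq
    hits <- find_d12_stwintrons(s)
    any(vapply(hits, function(h) h$location$start == 1L, logical(1)))
  }, logical(1))
  expect_lt(mean(unprot_ok), mean(prot_ok))
})

test_that("divergence dial: identity to template decreases with rate", {
  tpl <- shared_template()
  set.seed(122)
  rates <- c(0, 0.05, 0.1, 0.2, 0.3)
  mean_id <- vapply(rates, function(r) {
    mean(vapply(1:10, function(i) {
      global_align(evolve_copy(tpl, r)$seq, tpl$seq)$percent_identity
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(rates, mean_id, method = "spearman"), 0)
  expect_true(all(diff(mean_id) < 0))
})

test_that("build_genome output is deterministic and internally consistent", {
  p <- sim_params(seed = 77, n_genes = 8L, n_full_copies = 2L, n_sheared = 1L,
                  n_type1 = 1L, n_type2 = 1L, n_long = 0L,
                  divergence = c(0, 0.1))
  g1 <- build_genome(p)
  g2 <- build_genome(p)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$truth, g2$truth)
  # truth coordinates point at the planted element
  for (i in seq_len(nrow(g1$truth))) {
    tr <- g1$truth[i, ]
    el <- substr(g1$sequences[[tr$gene_id]], tr$start, tr$end)
    expect_equal(nchar(el), tr$length)
    if (tr$category == "full_sister") {
      expect_identical(substr(el, 1, 1), "G")
    }
  }
  # one element per gene at most
  expect_lte(max(table(g1$truth$gene_id)), 1L)
})

test_that("written genome round-trips and is byte-stable", {
  p <- sim_params(seed = 78, n_genes = 6L, n_full_copies = 2L, n_sheared = 0L,
                  n_type1 = 0L, n_type2 = 1L, n_long = 0L)
  g <- build_genome(p)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome(g, file.path(d1, ""))
  write_genome(build_genome(p), file.path(d2, ""))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  back <- read_fasta(file.path(d1, "genome.fasta"))
  expect_identical(unname(back[names(g$sequences)]), unname(g$sequences))
  tr <- jsonlite::read_json(file.path(d1, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$start, g$truth$start)
})

test_that("planted elements are seamlessly inserted (round-trip identity)", {
  p <- sim_params(seed = 79, n_genes = 8L, n_full_copies = 3L, n_sheared = 1L,
                  n_type1 = 1L, n_type2 = 1L, n_long = 1L,
                  divergence = c(0, 0.1))
  g <- build_genome(p)
  # flanks must carry no created duplication; 2-3-nt coincidental repeats
  # can occur in random sequence, so the assertion is on length >= 4
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    s <- g$sequences[[tr$gene_id]]
    f5 <- substr(s, tr$start - 12L, tr$start - 1L)
    f3 <- substr(s, tr$end + 1L, tr$end + 12L)
    expect_lt(tsd_scan(f5, f3)$length, 4L)
  }
})

test_that("type-2 planted derivatives keep exactly one palindrome copy", {
  p <- sim_params(seed = 80, n_genes = 10L, n_full_copies = 0L,
                  n_sheared = 0L, n_type1 = 0L, n_type2 = 6L, n_long = 0L,
                  divergence = c(0, 0.05))
  g <- build_genome(p)
  expect_equal(nrow(g$truth), 6L)
  for (i in 1:6) {
    tr <- g$truth[i, ]
    el <- substr(g$sequences[[tr$gene_id]], tr$start, tr$end)
    expect_equal(nrow(find_palindrome_hits(el)), 1L, info = tr$element_id)
  }
})

test_that("a genome with no planted elements yields no family calls", {
  p <- sim_params(seed = 81, n_genes = 6L, n_full_copies = 0L, n_sheared = 0L,
                  n_type1 = 0L, n_type2 = 0L, n_long = 0L)
  g <- build_genome(p)
  expect_equal(nrow(g$truth), 0L)
  sc <- scan_genome(g$sequences)
  # background stwintron-like false positives are possible; none should
  # resemble the template family
  hits <- sc$stwintrons
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      el <- substr(g$sequences[[hits$seq_id[i]]], hits$start[i], hits$end[i])
      if (hits$strand[i] == "-") el <- reverse_complement(el)
      expect_equal(classify_relative(el, g$template$stw)$category,
                   "unrelated")
    }
  }
})
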