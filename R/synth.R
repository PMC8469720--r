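# Synthetic genomes, genes and (stw)intron families with machine-readable
# ground truth. The generator's defaults state the world the analysis
# assumes: an ancestral (D1,2) template with 45-55 nt terminal inverted
# repeats overlapping two copies of the 10-nt palindrome (5' copy perfect,
# 3' copy with W = A), family sizes matching the published census (23 full
# sisters, 13 sheared, 2 type-1, 10 type-2, 1 long intron), a tunable
# per-copy divergence dial, background canonical introns at ~3-4 per gene,
# and seamless insertion at uniform-random coding positions.

.BASES <- c("A", "C", "G", "T")

.rand_bases <- function(n, gc = 0.5) {
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# sample a concrete instance of an IUPAC pattern
.instantiate <- function(pattern) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(pc, function(p) {
    opts <- .IUPAC_SETS[[p]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Parameters of the ancestral stwintron template
#'
#' @param arm_length TIR arm length range (nt), default 45-55.
#' @param spacer_length range of nt between the arms, default 90-110.
#' @param palindrome the 10-nt palindrome (5' copy; perfect by default).
#' @param arm_divergence substitution fraction applied to the 3' arm relative
#'   to the exact reverse complement of the 5' arm; the default 0.27 yields
#'   TIR identities around the low seventies, as observed for real sister
#'   stwintrons, and stays above the >= 70%-by-construction floor only
#'   loosely -- templates are rejection-sampled against the detector.
#' @param gc background GC fraction of unconstrained positions.
#' @return list of class `"template_params"`.
#' @export
template_params <- function(arm_length = c(45L, 55L),
                            spacer_length = c(90L, 110L),
                            palindrome = "TTTCTAGAAA",
                            arm_divergence = 0.27,
                            gc = 0.5) {
  stopifnot(length(arm_length) == 2L, length(spacer_length) == 2L,
            nchar(palindrome) == 10L, arm_divergence >= 0, arm_divergence < 0.5)
  structure(list(arm_length = as.integer(arm_length),
                 spacer_length = as.integer(spacer_length),
                 palindrome = toupper(palindrome),
                 arm_divergence = arm_divergence, gc = gc),
            class = "template_params")
}

#' Simulation parameters
#'
#' Defaults state the published family census; the divergence dial sets the
#' per-copy substitution rate drawn uniformly per element.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes (one contig per gene); genes beyond the
#'   planted-element count are negatives.
#' @param gene_length CDS length range (nt).
#' @param background_gc background base composition.
#' @param template a [template_params()].
#' @param n_full_copies,n_sheared,n_type1,n_type2,n_long planted counts per
#'   category (defaults 23 / 13 / 2 / 10 / 1).
#' @param divergence per-copy substitution-rate range.
#' @param indel_rate per-nt indel rate applied alongside substitutions.
#' @param protect_motifs keep splice motifs intact during evolution (the
#'   observed families are splice-competent, so this is on by default).
#' @param background_introns_per_gene range of canonical background introns
#'   per gene (fungal gene density ~3-4).
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(seed = 1L, n_genes = 60L, gene_length = c(1200L, 1800L),
                       background_gc = 0.5, template = template_params(),
                       n_full_copies = 23L, n_sheared = 13L, n_type1 = 2L,
                       n_type2 = 10L, n_long = 1L,
                       divergence = c(0.0, 0.2), indel_rate = 0.01,
                       protect_motifs = TRUE,
                       background_introns_per_gene = c(3L, 4L)) {
  counts <- c(n_full_copies, n_sheared, n_type1, n_type2, n_long)
  stopifnot(all(counts >= 0L), all(divergence >= 0), all(divergence < 0.5),
            indel_rate >= 0, indel_rate <= 1)
  n_elements <- sum(counts)
  if (n_genes < n_elements) stop("need n_genes >= total planted elements")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 background_gc = background_gc, template = template,
                 n_full_copies = as.integer(n_full_copies),
                 n_sheared = as.integer(n_sheared),
                 n_type1 = as.integer(n_type1),
                 n_type2 = as.integer(n_type2), n_long = as.integer(n_long),
                 divergence = divergence, indel_rate = indel_rate,
                 protect_motifs = isTRUE(protect_motifs),
                 background_introns_per_gene =
                   as.integer(background_introns_per_gene)),
            class = "sim_params")
}

# Protected positions of a template given its planted structure.
.template_protected <- function(m, N) {
  sort(unique(c(1L, 2L:7L,                       # G1 + internal donor
                (m - 18L):(m - 13L),             # internal BP
                (m - 2L):m,                      # internal acceptor
                (m + 1L):(m + 5L),               # external donor continuation
                (N - 18L):(N - 13L),             # external BP
                (N - 2L):N)))                    # external acceptor
}

#' Generate the ancestral (D1,2) stwintron template
#'
#' Rejection-samples a sequence that (i) the scanner parses as exactly one
#' full-span stwintron with the planted internal/external decomposition,
#' (ii) carries exactly two palindrome hits (5' copy perfect, in the internal
#' intron; 3' copy with W = A, in the external intron), and (iii) shows a TIR
#' under default detector settings. The 3' arm is a mutated reverse
#' complement of the 5' arm.
#'
#' @param tp a [template_params()].
#' @param model an [intron_model()].
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling budget.
#' @return list of class `"stw_template"`: `seq`, `stw` (the parsed
#'   `"stwintron"` object), `protected` (motif positions), `m` (internal
#'   acceptor end), `N` (length), `palindrome5`, `palindrome3` (hit
#'   intervals), `params`.
#' @export
make_template <- function(tp = template_params(), model = intron_model(),
                          seed = 42L, max_attempts = 1000L) {
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_attempts)) {
    L <- sample(tp$arm_length[1]:tp$arm_length[2], 1L)
    S <- sample(tp$spacer_length[1]:tp$spacer_length[2], 1L)
    N <- 2L * L + S
    m <- L + S %/% 2L                      # internal acceptor end
    int_len <- m - 1L
    ext_len <- N - m + 1L
    if (int_len < model$min_intron_len || int_len > model$max_intron_len ||
        ext_len < model$min_intron_len || ext_len > model$max_intron_len) next
    if (L < 20L) next

    ch <- .rand_bases(N, tp$gc)
    ch[1] <- "G"
    donor_i <- .instantiate(model$donor_pattern)
    ch[2:7] <- strsplit(donor_i, "", fixed = TRUE)[[1]]
    # 5' palindrome at the end of the 5' arm (inside the internal intron)
    ch[(L - 9L):L] <- strsplit(tp$palindrome, "", fixed = TRUE)[[1]]
    ch[(m - 18L):(m - 13L)] <- strsplit(.instantiate(model$bp_pattern), "",
                                        fixed = TRUE)[[1]]
    ch[(m - 2L):m] <- c("T", "A", "G")
    # external donor continuation: G1 + these 5 nt must match the donor
    cont <- substr(.instantiate(model$donor_pattern), 2L, 6L)
    ch[(m + 1L):(m + 5L)] <- strsplit(cont, "", fixed = TRUE)[[1]]
    # 3' arm: mutated reverse complement of the (finished) 5' arm
    arm5 <- ch[1:L]
    arm3 <- vapply(rev(arm5), function(b) .IUPAC_COMPLEMENT[[b]], character(1))
    ch[(N - L + 1L):N] <- arm3
    p3_start <- N - L + 1L                 # 3' palindrome copy position
    ch[p3_start] <- "A"                    # W = A in the 3' copy
    ch[(N - 18L):(N - 13L)] <- strsplit(.instantiate(model$bp_pattern), "",
                                        fixed = TRUE)[[1]]
    ch[(N - 2L):N] <- c("T", "A", "G")
    # top up substitutions in the 3' arm until the arm-level divergence
    # reaches the dial: the motif overlays (external BP, acceptor, W) already
    # break the mirror at several positions, so count mismatches first
    protected <- .template_protected(m, N)
    arm_mism <- function() sum(vapply(seq_len(L), function(i) {
      ch[i] != .IUPAC_COMPLEMENT[[ch[N + 1L - i]]]
    }, logical(1)))
    target <- round(tp$arm_divergence * L)
    cand <- setdiff((N - L + 1L):N, c(protected, p3_start:(p3_start + 9L)))
    cand <- sample(cand)
    for (i in cand) {
      if (arm_mism() >= target) break
      ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
    }
    s <- paste(ch, collapse = "")

    # contract checks
    hits <- find_palindrome_hits(s)
    if (nrow(hits) != 2L) next
    if (!(hits$end[1] == L && hits$start[2] == p3_start)) next
    stws <- find_d12_stwintrons(genomic_sequence("template", s), model)
    if (length(stws) != 1L) next
    h <- stws[[1]]
    if (!(h$location$start == 1L && h$location$end == N &&
          h$internal$end == m)) next
    tir <- try(find_tir(s), silent = TRUE)
    if (inherits(tir, "try-error") || !tir$tir_present) next
    if (tir$arm_identity < 70) next
    if (abs(tir$arm_length - L) > 5L) next  # detector must read the planted arm
    # the three derivation products must themselves be clean minimal-parse
    # introns, or the derived family members could not have propagated
    prod_ok <- tryCatch({
      .minimal_parse_full_span(predict_type1_crop(h, model)$product, model) &&
        .minimal_parse_full_span(predict_type2_crop(h, model)$product, model) &&
        .minimal_parse_full_span(.long_product(h, m, model), model)
    }, error = function(e) FALSE)
    if (!prod_ok) next

    return(structure(list(
      seq = s, stw = h, protected = protected, m = m, N = N,
      palindrome5 = interval("template", L - 9L, L),
      palindrome3 = interval("template", p3_start, p3_start + 9L),
      params = tp, attempts = attempt
    ), class = "stw_template"))
  }
  stop("make_template: no feasible template in ", max_attempts, " attempts")
}

#' @export
print.stw_template <- function(x, ...) {
  cat(sprintf("stwintron template: %d nt, internal 2-%d, palindromes %d-%d / %d-%d\n",
              x$N, x$m, x$palindrome5$start, x$palindrome5$end,
              x$palindrome3$start, x$palindrome3$end))
  invisible(x)
}

#' Evolve a copy of a sequence under substitutions and indels
#'
#' Substitutions and indels are applied uniformly outside protected motif
#' positions (when `protect_motifs`); protected positions are never mutated
#' or deleted and insertions never open inside them. Realised divergence is
#' recorded as substituted positions / unprotected positions.
#'
#' @param template a `"stw_template"`, or any character sequence (then
#'   `protected` supplies the motif positions).
#' @param rate per-nt substitution probability (< 0.5).
#' @param indel_rate per-nt indel probability (half deletions, half
#'   single-base insertions).
#' @param protect_motifs logical.
#' @param seed optional RNG seed (omit to continue the current stream).
#' @param protected integer positions to protect when `template` is a bare
#'   string.
#' @return list `seq`, `divergence` (realised substitution fraction),
#'   `n_subs`, `n_indels`.
#' @export
evolve_copy <- function(template, rate, indel_rate = 0, protect_motifs = TRUE,
                        seed = NULL, protected = integer(0)) {
  stopifnot(rate >= 0, rate < 0.5)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (inherits(template, "stw_template")) {
    s <- template$seq
    protected <- template$protected
  } else {
    s <- toupper(template)
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  prot <- rep(FALSE, n)
  if (protect_motifs && length(protected)) prot[protected] <- TRUE
  out <- character(0)
  n_subs <- 0L; n_indels <- 0L
  for (i in seq_len(n)) {
    if (prot[i]) {
      out <- c(out, ch[i])
      next
    }
    u <- runif(1)
    if (indel_rate > 0 && u < indel_rate / 2) {        # deletion
      n_indels <- n_indels + 1L
      next
    }
    if (indel_rate > 0 && u < indel_rate) {            # insertion after i
      out <- c(out, ch[i], sample(.BASES, 1L))
      n_indels <- n_indels + 1L
      next
    }
    if (runif(1) < rate) {
      out <- c(out, sample(setdiff(.BASES, ch[i]), 1L))
      n_subs <- n_subs + 1L
    } else {
      out <- c(out, ch[i])
    }
  }
  n_unprot <- max(1L, sum(!prot))
  list(seq = paste(out, collapse = ""), divergence = n_subs / n_unprot,
       n_subs = n_subs, n_indels = n_indels)
}

# Protected positions of a full-span canonical intron product: donor, BP
# (leftmost parse), acceptor.
.intron_protected <- function(s, model) {
  ins <- find_canonical_introns(s, model, mode = "exhaustive")
  full <- ins[ins$start == 1L & ins$end == nchar(s), , drop = FALSE]
  if (!nrow(full)) return(integer(0))
  b <- full$bp_start[1]
  n <- nchar(s)
  sort(unique(c(1:6, b:(b + 5L), (n - 2L):n)))
}

# Shear a template: keep one section, randomise the unconstrained body of the
# other. Returns the sheared sequence (still a valid full-span stwintron).
.shear_template <- function(template, side = c("internal", "external"),
                            gc = 0.5, model = intron_model(),
                            max_attempts = 200L) {
  side <- match.arg(side)
  ch0 <- strsplit(template$seq, "", fixed = TRUE)[[1]]
  m <- template$m; N <- template$N
  prot <- template$protected
  target <- if (side == "internal") {
    setdiff((m + 6L):N, prot)     # randomise external body, keep internal
  } else {
    setdiff(8L:(m - 3L), prot)    # randomise internal body, keep external
  }
  for (a in seq_len(max_attempts)) {
    ch <- ch0
    ch[target] <- .rand_bases(length(target), gc)
    # the non-conserved section of a real sheared sister is unique sequence
    # with its own splice motifs: re-instantiate them from the patterns
    # rather than inheriting the template's instances
    if (side == "internal") {
      ch[(N - 18L):(N - 13L)] <- strsplit(.instantiate(model$bp_pattern), "",
                                          fixed = TRUE)[[1]]
      ch[(m + 1L):(m + 5L)] <- strsplit(substr(.instantiate(model$donor_pattern),
                                               2L, 6L), "", fixed = TRUE)[[1]]
      ch[N - 2L] <- sample(c("T", "C"), 1L)
    } else {
      ch[2L:7L] <- strsplit(.instantiate(model$donor_pattern), "",
                            fixed = TRUE)[[1]]
      ch[(m - 18L):(m - 13L)] <- strsplit(.instantiate(model$bp_pattern), "",
                                          fixed = TRUE)[[1]]
      ch[m - 2L] <- sample(c("T", "C"), 1L)
    }
    s <- paste(ch, collapse = "")
    stws <- find_d12_stwintrons(genomic_sequence("sheared", s), model)
    ok <- any(vapply(stws, function(h) {
      h$location$start == 1L && h$location$end == N
    }, logical(1)))
    if (ok) return(s)
  }
  stop("failed to shear template (", side, ")")
}

# Splice-competence filters applied to evolved copies: the published family
# members are all verified to splice across their full span, so copies in
# which mutation has created a cryptic splice site (shifting the minimal
# parse away from the planted coordinates) are rejected and redrawn --
# purifying selection, not parameter tuning.
.parses_full_span_d12 <- function(s, model) {
  hits <- find_d12_stwintrons(genomic_sequence("el", s), model)
  any(vapply(hits, function(h) h$location$start == 1L &&
               h$location$end == nchar(s), logical(1)))
}

# The smallest-intron parse from the element's own donor must span the whole
# element: a cryptic internal acceptor would change the splice product in
# vivo, so such derivatives do not persist.
.minimal_parse_full_span <- function(s, model) {
  ins <- find_canonical_introns(s, model, mode = "intron_definition")
  nrow(ins) > 0 && any(ins$start == 1L & ins$end == nchar(s))
}

# Long-intron derivation: the one-step product with the internal BP
# degenerated (branch A flipped), so the internal splice sites can no longer
# pre-empt the full-span parse.
.long_product <- function(stw, m, model) {
  p <- predict_long_intron(stw, model)$product
  bp5 <- m - 19L                      # internal BP start in product coords
  substr(p, bp5 + 4L, bp5 + 4L) <- "C"
  p
}

.evolve_validated <- function(s, rate, indel_rate, protect_motifs, protected,
                              check, max_tries = 100L) {
  ev <- NULL
  for (t in seq_len(max_tries)) {
    ev <- evolve_copy(s, rate, indel_rate, protect_motifs,
                      protected = protected)
    if (!protect_motifs || check(ev$seq)) return(ev)
  }
  ev
}

# One planted element: category-specific derivation from the template.
.derive_element <- function(template, category, rate, indel_rate,
                            protect_motifs, gc, model) {
  if (category == "full_sister") {
    ev <- .evolve_validated(template$seq, rate, indel_rate, protect_motifs,
                            template$protected,
                            function(x) .parses_full_span_d12(x, model))
    return(list(seq = ev$seq, divergence = ev$divergence))
  }
  if (category %in% c("sheared_internal", "sheared_external")) {
    side <- sub("sheared_", "", category)
    s <- .shear_template(template, side, gc, model)
    ev <- .evolve_validated(s, rate, indel_rate, protect_motifs,
                            template$protected,
                            function(x) .parses_full_span_d12(x, model))
    return(list(seq = ev$seq, divergence = ev$divergence))
  }
  product <- switch(category,
    cropped_type1 = predict_type1_crop(template$stw, model)$product,
    cropped_type2 = predict_type2_crop(template$stw, model)$product,
    long_intron = .long_product(template$stw, template$m, model),
    stop("unknown category: ", category))
  ev <- .evolve_validated(product, rate, indel_rate, protect_motifs,
                          .intron_protected(product, model),
                          function(x) .minimal_parse_full_span(x, model))
  list(seq = ev$seq, divergence = ev$divergence)
}

# A background canonical intron (50-80 nt) for gene realism.
.background_intron <- function(model, gc = 0.5) {
  n <- sample(50:80, 1L)
  ch <- .rand_bases(n, gc)
  ch[1:6] <- strsplit(.instantiate(model$donor_pattern), "", fixed = TRUE)[[1]]
  ch[(n - 18L):(n - 13L)] <- strsplit(.instantiate(model$bp_pattern), "",
                                      fixed = TRUE)[[1]]
  ch[(n - 2L):n] <- c("T", "A", "G")
  paste(ch, collapse = "")
}

#' Build a synthetic genome with planted (stw)intron families
#'
#' One contig per gene. Each gene is a random CDS with ~3-4 background
#' canonical introns; planted elements (at most one per gene) are derived
#' from a single ancestral template -- evolved full copies, sheared copies,
#' and cropped/long derivatives generated through the crop model -- and
#' inserted seamlessly at uniform-random coding offsets (no tandem site
#' duplication, no exonic loss). All ground truth is recorded.
#'
#' @param params a [sim_params()].
#' @param model an [intron_model()].
#' @return list of class `"synthetic_genome"`: `sequences` (named character
#'   vector), `truth` (data.frame: `element_id`, `gene_id`, `category`,
#'   `start`, `end`, `cds_offset`, `phase`, `divergence`, `length`),
#'   `features` (GFF3-ready data.frame including background introns),
#'   `template` (the `"stw_template"`), `params`.
#' @export
build_genome <- function(params = sim_params(), model = intron_model()) {
  set.seed(params$seed)
  template_seed <- sample.int(.Machine$integer.max, 1L)
  template <- make_template(params$template, model, seed = template_seed)
  set.seed(params$seed + 1L)

  categories <- c(rep("full_sister", params$n_full_copies),
                  rep("sheared_internal", ceiling(params$n_sheared / 2)),
                  rep("sheared_external", floor(params$n_sheared / 2)),
                  rep("cropped_type1", params$n_type1),
                  rep("cropped_type2", params$n_type2),
                  rep("long_intron", params$n_long))
  n_el <- length(categories)

  elements <- vector("list", n_el)
  for (i in seq_len(n_el)) {
    rate <- runif(1, params$divergence[1], params$divergence[2])
    elements[[i]] <- c(.derive_element(template, categories[i], rate,
                                       params$indel_rate,
                                       params$protect_motifs,
                                       params$background_gc, model),
                       list(category = categories[i]))
  }

  host_genes <- sample.int(params$n_genes, n_el)
  seqs <- character(params$n_genes)
  names(seqs) <- sprintf("gene%03d", seq_len(params$n_genes))
  truth_rows <- list()
  feat_rows <- list()

  for (g in seq_len(params$n_genes)) {
    gid <- names(seqs)[g]
    cds_len <- sample(params$gene_length[1]:params$gene_length[2], 1L)
    cds_len <- cds_len - cds_len %% 3L
    cds <- paste(.rand_bases(cds_len, params$background_gc), collapse = "")
    nb <- sample(params$background_introns_per_gene[1]:
                   params$background_introns_per_gene[2], 1L)
    bpos <- sort(sample(seq(60L, cds_len - 60L), nb))
    pre <- ""
    prev <- 0L
    exon_map <- integer(0)  # for each pre position, exonic offset (0 if intronic)
    boffsets <- integer(0)
    for (b in bpos) {
      pre <- paste0(pre, substr(cds, prev + 1L, b))
      bi <- .background_intron(model, params$background_gc)
      boffsets <- c(boffsets, nchar(pre) + 1L)
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        seq_id = gid, start = nchar(pre) + 1L,
        end = nchar(pre) + nchar(bi), strand = "+",
        type = "intron", ID = sprintf("%s_bg%d", gid, length(boffsets)),
        stringsAsFactors = FALSE)
      pre <- paste0(pre, bi)
      prev <- b
    }
    pre <- paste0(pre, substr(cds, prev + 1L, cds_len))
    # recompute background intron spans in pre coordinates for offset mapping
    el_i <- which(host_genes == g)
    if (length(el_i) == 1L) {
      el <- elements[[el_i]]
      # exonic insertion offset, margins for flanks
      o <- sample(seq(30L, cds_len - 30L), 1L)
      # map exonic offset o to position in pre: add lengths of background
      # introns that start at or before that exonic position
      gene_feats <- Filter(function(f) f$seq_id == gid, feat_rows)
      intron_lens <- vapply(gene_feats, function(f) f$end - f$start + 1L,
                            integer(1))
      starts_ex <- bpos  # exonic offset just before each background intron
      shift <- sum(intron_lens[starts_ex <= o])
      pos <- o + shift
      gene_seq <- paste0(substr(pre, 1L, pos), el$seq,
                         substr(pre, pos + 1L, nchar(pre)))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        element_id = sprintf("el%02d_%s", el_i, el$category),
        gene_id = gid, category = el$category,
        start = pos + 1L, end = pos + nchar(el$seq),
        cds_offset = o, phase = o %% 3L,
        divergence = el$divergence, length = nchar(el$seq),
        stringsAsFactors = FALSE)
      # shift background features downstream of the insertion
      for (k in seq_along(feat_rows)) {
        f <- feat_rows[[k]]
        if (f$seq_id == gid && f$start > pos) {
          f$start <- f$start + nchar(el$seq)
          f$end <- f$end + nchar(el$seq)
          feat_rows[[k]] <- f
        }
      }
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        seq_id = gid, start = pos + 1L, end = pos + nchar(el$seq),
        strand = "+", type = if (el$category %in%
          c("full_sister", "sheared_internal", "sheared_external"))
          "stwintron" else "intron",
        ID = sprintf("el%02d_%s", el_i, el$category),
        stringsAsFactors = FALSE)
      seqs[g] <- gene_seq
    } else {
      seqs[g] <- pre
    }
  }

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(element_id = character(0), gene_id = character(0),
               category = character(0), start = integer(0), end = integer(0),
               cds_offset = integer(0), phase = integer(0),
               divergence = numeric(0), length = integer(0),
               stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene_id, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  features <- do.call(rbind, feat_rows)
  features <- features[order(features$seq_id, features$start), , drop = FALSE]
  rownames(features) <- NULL

  structure(list(sequences = seqs, truth = truth, features = features,
                 template = template, params = params),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d genes (%d nt), %d planted elements\n",
              length(x$sequences), sum(nchar(x$sequences)), nrow(x$truth)))
  print(table(x$truth$category))
  invisible(x)
}

#' Write a synthetic genome to FASTA + GFF3 + truth JSON
#'
#' @param genome a `"synthetic_genome"`.
#' @param out_prefix path prefix; writes `<prefix>genome.fasta`,
#'   `<prefix>genes.gff3`, `<prefix>truth.json`, `<prefix>template.fasta`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_genome <- function(genome, out_prefix) {
  paths <- c(fasta = paste0(out_prefix, "genome.fasta"),
             gff3 = paste0(out_prefix, "genes.gff3"),
             truth = paste0(out_prefix, "truth.json"),
             template = paste0(out_prefix, "template.fasta"))
  write_fasta(genome$sequences, paths[["fasta"]])
  write_gff3(genome$features, paths[["gff3"]])
  jsonlite::write_json(genome$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_fasta(setNames(genome$template$seq, "template"), paths[["template"]])
  invisible(paths)
}
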