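# Orchestration: scan -> family -> symmetry -> crop -> context over one or
# more genomes, with a single summary report. Stage outputs are pure
# functions of inputs + config; reruns with the same config are
# byte-identical.

#' Build a pipeline run configuration
#'
#' Every spec-level threshold surfaces here. `config` files on disk are JSON
#' (read with [read_run_config()]).
#'
#' @param fasta path to the genome FASTA (required at run time).
#' @param seed_fasta optional FASTA with the family seed/template element; if
#'   absent the longest detected stwintron seeds the family.
#' @param out_dir output directory (created if needed).
#' @param model an [intron_model()] or list of overrides for one.
#' @param min_identity family identity floor (percent).
#' @param min_arm,min_tir_identity TIR detector thresholds.
#' @param both_strands scan both strands?
#' @param seed RNG seed for any sampling steps (none by default; recorded for
#'   provenance).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(fasta, seed_fasta = NULL, out_dir = "stwinscan_out",
                       model = intron_model(), min_identity = 55,
                       min_arm = 30L, min_tir_identity = 60,
                       both_strands = TRUE, seed = 1L) {
  if (is.list(model) && !inherits(model, "intron_model")) {
    model <- do.call(intron_model, model)
  }
  structure(list(fasta = fasta, seed_fasta = seed_fasta, out_dir = out_dir,
                 model = model, min_identity = min_identity,
                 min_arm = as.integer(min_arm),
                 min_tir_identity = min_tir_identity,
                 both_strands = isTRUE(both_strands), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a JSON run configuration
#'
#' @param path JSON file with any subset of [run_config()]'s fields.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline on a genome
#'
#' Stages: (1) scan all contigs for (D1,2) stwintrons and canonical introns;
#' (2) collect the sister family around the seed and classify every detected
#' element; (3) symmetry analysis (TIR, palindrome copies, duplex score) per
#' element; (4) crop-product prediction per stwintron; (5) summary counts.
#' Writes `stwintrons.gff3`, `assignments.tsv`, `symmetry.tsv`, `crops.tsv`
#' and `summary.json` under `config$out_dir`.
#'
#' @param config a `"run_config"` (or path to a JSON config).
#' @return the summary list, invisibly; files as side effects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!file.exists(config$fasta)) stop("missing input FASTA: ", config$fasta)
  seqs <- read_fasta(config$fasta)
  if (!length(seqs)) stop("empty FASTA: ", config$fasta)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- config$model

  message("[scan] ", length(seqs), " sequence(s), ",
          sum(nchar(seqs)), " nt")
  scan <- scan_genome(seqs, model, both_strands = config$both_strands,
                      what = c("stwintrons", "introns"))
  stw_df <- scan$stwintrons
  stw_objs <- attr(stw_df, "objects")
  message("[scan] ", nrow(stw_df), " stwintron candidate(s)")

  element_seq <- function(i) {
    s <- seqs[[stw_df$seq_id[i]]]
    sub <- substr(s, stw_df$start[i], stw_df$end[i])
    if (stw_df$strand[i] == "-") reverse_complement(sub) else sub
  }
  el_ids <- sprintf("%s_%d_%d%s", stw_df$seq_id, stw_df$start, stw_df$end,
                    ifelse(stw_df$strand == "-", "_rc", ""))
  el_seqs <- if (nrow(stw_df)) vapply(seq_len(nrow(stw_df)), element_seq,
                                      character(1)) else character(0)
  names(el_seqs) <- el_ids

  # seed element and template parse
  if (!is.null(config$seed_fasta)) {
    seed_seq <- read_fasta(config$seed_fasta)[[1]]
  } else if (length(el_seqs)) {
    seed_seq <- el_seqs[[which.max(nchar(el_seqs))]]
  } else {
    seed_seq <- NULL
  }
  template <- NULL
  if (!is.null(seed_seq)) {
    th <- find_d12_stwintrons(genomic_sequence("seed", seed_seq), model)
    full <- Filter(function(h) h$location$start == 1L &&
                     h$location$end == nchar(seed_seq), th)
    if (length(full)) template <- full[[1]]
  }

  message("[family] classifying ", length(el_seqs), " element(s)")
  fam <- if (!is.null(template) && length(el_seqs)) {
    rows <- lapply(seq_along(el_seqs), function(i) {
      a <- classify_relative(el_seqs[[i]], template, model,
                             min_identity = config$min_identity)
      data.frame(member_id = el_ids[i], category = a$category,
                 identity = a$identity_to_seed,
                 match_identity = a$match_identity,
                 extra_g = isTRUE(a$extra_g_subgroup),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    data.frame(member_id = character(0), category = character(0),
               identity = numeric(0), match_identity = numeric(0),
               extra_g = logical(0), stringsAsFactors = FALSE)
  }

  # survey canonical introns for cropped/long sister relatives: candidates
  # are introns carrying a palindrome hit (every derivation path keeps at
  # least one copy)
  message("[family] surveying canonical introns for cropped relatives")
  int_df <- scan$introns
  crop_fam <- data.frame(member_id = character(0), seq_id = character(0),
                         start = integer(0), end = integer(0),
                         category = character(0), identity = numeric(0),
                         match_identity = numeric(0), extra_g = logical(0),
                         stringsAsFactors = FALSE)
  if (!is.null(template) && nrow(int_df)) {
    crows <- list()
    for (i in seq_len(nrow(int_df))) {
      s <- substr(seqs[[int_df$seq_id[i]]], int_df$start[i], int_df$end[i])
      if (int_df$strand[i] == "-") s <- reverse_complement(s)
      if (!nrow(find_palindrome_hits(s))) next
      a <- classify_relative(s, template, model,
                             min_identity = config$min_identity)
      if (a$category == "unrelated") next
      crows[[length(crows) + 1L]] <- data.frame(
        member_id = sprintf("%s_%d_%d%s", int_df$seq_id[i], int_df$start[i],
                            int_df$end[i],
                            ifelse(int_df$strand[i] == "-", "_rc", "")),
        seq_id = int_df$seq_id[i], start = int_df$start[i],
        end = int_df$end[i],
        category = a$category, identity = a$identity_to_seed,
        match_identity = a$match_identity,
        extra_g = isTRUE(a$extra_g_subgroup), stringsAsFactors = FALSE)
    }
    if (length(crows)) crop_fam <- do.call(rbind, crows)
  }

  # resolve overlapping calls, strand-agnostically (the elements are
  # near-symmetric, so reverse-complement re-detection is common, and one
  # locus is often reached from several upstream candidate donors, giving
  # lower-identity superspans of the true element).
  # Stage 1: stwintron calls compete by match_identity (tie: tighter span).
  span <- stw_df$end - stw_df$start + 1L
  acc <- logical(nrow(stw_df))
  if (nrow(stw_df)) {
    for (i in order(-fam$match_identity, span, stw_df$seq_id, stw_df$start)) {
      clash <- which(acc & stw_df$seq_id == stw_df$seq_id[i] &
                       stw_df$start <= stw_df$end[i] &
                       stw_df$end >= stw_df$start[i])
      if (!length(clash)) acc[i] <- TRUE
    }
  }
  # Stage 2: intron calls fill loci without a positive stwintron call; a
  # stronger intron call may displace an overlapping call classified
  # unrelated, never a positive one.
  acc_int <- logical(nrow(crop_fam))
  if (nrow(crop_fam)) {
    cspan <- crop_fam$end - crop_fam$start + 1L
    for (i in order(-crop_fam$match_identity, cspan, crop_fam$seq_id,
                    crop_fam$start)) {
      iclash <- which(acc_int & crop_fam$seq_id == crop_fam$seq_id[i] &
                        crop_fam$start <= crop_fam$end[i] &
                        crop_fam$end >= crop_fam$start[i])
      if (length(iclash)) next
      sclash <- which(acc & stw_df$seq_id == crop_fam$seq_id[i] &
                        stw_df$start <= crop_fam$end[i] &
                        stw_df$end >= crop_fam$start[i])
      if (!length(sclash)) {
        acc_int[i] <- TRUE
      } else if (all(fam$category[sclash] == "unrelated") &&
                 all(fam$match_identity[sclash] <
                       crop_fam$match_identity[i])) {
        acc[sclash] <- FALSE
        acc_int[i] <- TRUE
      }
    }
  }
  fam_all <- rbind(
    if (any(acc)) cbind(fam[acc, , drop = FALSE],
                        seq_id = stw_df$seq_id[acc],
                        start = stw_df$start[acc], end = stw_df$end[acc],
                        kind = "stwintron") else NULL,
    if (any(acc_int)) cbind(crop_fam[acc_int, c("member_id", "category",
                                                "identity", "match_identity",
                                                "extra_g"), drop = FALSE],
                            seq_id = crop_fam$seq_id[acc_int],
                            start = crop_fam$start[acc_int],
                            end = crop_fam$end[acc_int],
                            kind = "intron") else NULL
  )
  if (is.null(fam_all)) {
    fam_all <- data.frame(member_id = character(0), category = character(0),
                          identity = numeric(0), match_identity = numeric(0),
                          extra_g = logical(0), seq_id = character(0),
                          start = integer(0), end = integer(0),
                          kind = character(0), stringsAsFactors = FALSE)
  } else {
    fam_all <- fam_all[order(fam_all$seq_id, fam_all$start), , drop = FALSE]
    rownames(fam_all) <- NULL
  }
  message("[family] ", nrow(fam_all), " element(s) after overlap resolution")

  # retained stwintron calls drive the symmetry and crop stages
  keep_stw <- which(acc)
  stw_df <- stw_df[keep_stw, , drop = FALSE]
  stw_objs <- stw_objs[keep_stw]
  el_seqs <- el_seqs[keep_stw]
  el_ids <- el_ids[keep_stw]
  rownames(stw_df) <- NULL

  message("[symmetry] TIR/palindrome analysis")
  sym <- if (length(el_seqs)) do.call(rbind, lapply(seq_along(el_seqs),
    function(i) {
      s <- el_seqs[[i]]
      if (nchar(s) < 2L * config$min_arm) {
        return(data.frame(member_id = el_ids[i], tir_present = FALSE,
                          arm_length = 0L, arm_identity = NA_real_,
                          spacer = NA_integer_, n_palindromes = NA_integer_,
                          duplex = NA_real_, stringsAsFactors = FALSE))
      }
      r <- find_tir(s, config$min_arm, config$min_tir_identity)
      data.frame(member_id = el_ids[i], tir_present = r$tir_present,
                 arm_length = r$arm_length, arm_identity = r$arm_identity,
                 spacer = r$spacer_length,
                 n_palindromes = nrow(r$palindrome_hits),
                 duplex = r$duplex_score_normalised, stringsAsFactors = FALSE)
    })) else data.frame()

  message("[crop] product prediction")
  crops <- if (length(stw_objs)) do.call(rbind, lapply(seq_along(stw_objs),
    function(i) {
      h <- stw_objs[[i]]
      t2 <- tryCatch(predict_type2_crop(h, model), error = function(e) NULL)
      t1 <- predict_type1_crop(h, model)
      lg <- predict_long_intron(h, model)
      data.frame(member_id = el_ids[i],
                 type1_len = nchar(t1$product),
                 type1_valid = t1$product_valid_intron,
                 type2_len = if (is.null(t2)) NA_integer_ else
                   nchar(t2$product),
                 type2_valid = if (is.null(t2)) NA else
                   t2$product_valid_intron,
                 long_len = nchar(lg$product),
                 long_valid = lg$product_valid_intron,
                 stringsAsFactors = FALSE)
    })) else data.frame()

  summary <- list(
    n_sequences = length(seqs),
    total_nt = sum(nchar(seqs)),
    n_stwintrons = nrow(stw_df),
    category_counts = if (nrow(fam_all))
      as.list(table(fam_all$category)) else list(),
    tir = if (nrow(sym)) list(
      n_with_tir = sum(sym$tir_present),
      mean_arm_length = mean(sym$arm_length[sym$tir_present]),
      mean_arm_identity = mean(sym$arm_identity[sym$tir_present])
    ) else list(),
    palindromes = if (nrow(sym)) list(
      n_with_two_hits = sum(!is.na(sym$n_palindromes) &
                              sym$n_palindromes >= 2L)
    ) else list(),
    seed_length = if (is.null(seed_seq)) NA else nchar(seed_seq),
    config = list(min_identity = config$min_identity,
                  min_arm = config$min_arm,
                  min_tir_identity = config$min_tir_identity,
                  both_strands = config$both_strands,
                  seed = config$seed)
  )

  gff <- stw_df
  if (nrow(gff)) {
    gff$type <- "stwintron"
    gff$ID <- el_ids
  } else {
    gff <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0), stringsAsFactors = FALSE)
  }
  attr(gff, "objects") <- NULL
  write_gff3(gff, file.path(config$out_dir, "stwintrons.gff3"))
  write_report(fam_all, file.path(config$out_dir, "assignments.tsv"), "tsv")
  write_report(sym, file.path(config$out_dir, "symmetry.tsv"), "tsv")
  write_report(crops, file.path(config$out_dir, "crops.tsv"), "tsv")
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
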