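#' Infer the mature miRNA interval from a read stack
#'
#' Picks the most abundant pooled read that matches the precursor exactly
#' (no mismatches, fully templated, 18-30 nt); its interval defines the
#' mature miRNA, as in miRDeep2-style candidate output. Ties go to the
#' 5'-most start, then the shorter read.
#'
#' @param stack A [read_stack()].
#' @param precursor_seq Precursor sequence.
#' @return Interval \code{c(start, end)}, or \code{NULL} when no exact read
#'   exists.
#' @export
infer_mature_from_stack <- function(stack, precursor_seq) {
  if (nrow(stack) == 0L) return(NULL)
  pooled <- stats::aggregate(count ~ start + sequence, data = as.data.frame(stack),
                             FUN = sum)
  mm <- vapply(seq_len(nrow(pooled)), function(i)
    read_mismatch_profile(pooled$sequence[i], pooled$start[i], precursor_seq)$n_total,
    integer(1))
  len <- nchar(pooled$sequence)
  ok <- mm == 0L & len >= 18L & len <= 30L &
    pooled$start + len - 1L <= nchar(precursor_seq)
  if (!any(ok)) return(NULL)
  cand <- pooled[ok, , drop = FALSE]
  cand <- cand[order(-cand$count, cand$start, nchar(cand$sequence)), , drop = FALSE]
  c(cand$start[1], cand$start[1] + nchar(cand$sequence[1]) - 1L)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    base <- dirname(normalizePath(config))
    config <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config)
              else if (ext == "json") jsonlite::read_json(config, simplifyVector = TRUE)
              else mc_stop("config_error", "config must be .yaml/.yml/.json")
    # resolve input paths relative to the config file
    for (k in c("precursors", "stacks", "known_matures", "sample_sheet", "fastq"))
      if (!is.null(config[[k]]) && !file.exists(config[[k]]))
        config[[k]] <- file.path(base, config[[k]])
  }
  config
}

#' Run the full curation pipeline
#'
#' Orchestrates: optional read QC, duplex geometry, read-stack evidence, the
#' seven-rule confidence classification, conserved/novel assignment and
#' family naming, isomiR detection, windowed quantification, TPM
#' normalization, differential expression across stages, and composition
#' statistics. All stages are deterministic functions of the inputs, so
#' repeated runs produce byte-identical outputs.
#'
#' @param config Path to a YAML/JSON config, or an equivalent list. Keys:
#'   \code{precursors} (TSV), \code{stacks} (TSV), optional
#'   \code{known_matures} (FASTA), optional \code{sample_sheet} (TSV),
#'   optional \code{fastq} + \code{qc} (params), optional \code{thresholds}
#'   (overrides for [mirna_thresholds()]), \code{require_r4},
#'   \code{family_prefix}, \code{isomir} (overrides for [call_isomirs()]),
#'   \code{de} (\code{lfc_threshold}, \code{alpha}).
#' @param out_dir Output directory (created if missing); overrides
#'   \code{config$out_dir}.
#' @param quiet Suppress progress messages (written to stderr).
#' @return Invisibly, the summary list (also written to
#'   \code{summary.json}).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- read_pipeline_config(config)
  say <- function(...) if (!quiet) message("[mircurate] ", sprintf(...))
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) mc_stop("config_error", "no output directory given")
  for (k in c("precursors", "stacks")) {
    if (is.null(cfg[[k]]))
      mc_stop("config_error", "config is missing required input '%s'", k)
    if (!file.exists(cfg[[k]]))
      mc_stop("config_error", "input file for '%s' not found: %s", k, cfg[[k]])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  thr <- do.call(mirna_thresholds, as.list(cfg$thresholds %||% list()))
  wu <- cfg$window_up %||% 2L
  wd <- cfg$window_down %||% 5L

  if (!is.null(cfg$fastq)) {
    say("stage qc")
    qc <- read_qc(cfg$fastq, do.call(qc_params, as.list(cfg$qc %||% list())))
    write_tsv(data.frame(metric = c("input", "retained", "adapter_trimmed",
                                    names(qc$stats$removed)),
                         value = c(qc$stats$input, qc$stats$retained,
                                   qc$stats$adapter_trimmed,
                                   unname(qc$stats$removed))),
              file.path(out_dir, "qc_stats.tsv"))
  }

  say("stage geometry/evidence/classification")
  precursors <- read_precursors(cfg$precursors)
  stacks <- read_stacks(cfg$stacks)
  candidates <- list(); matures <- list()
  for (p in precursors) {
    st <- stacks[[p$id]]
    if (is.null(st)) next
    mat <- infer_mature_from_stack(st, p$sequence)
    if (is.null(mat)) next
    matures[[p$id]] <- mat
    candidates[[p$id]] <- list(precursor = p, mature = mat, stack = st)
  }
  if (length(candidates) == 0L)
    mc_stop("config_error", "no candidate has read support")
  report <- classify_batch(candidates, thr, require_r4 = isTRUE(cfg$require_r4),
                           window_up = wu, window_down = wd)
  write_tsv(report, file.path(out_dir, "confidence_report.tsv"))
  yaml::write_yaml(unclass(thr), file.path(out_dir, "thresholds.yaml"))

  hc_ids <- report$id[report$category != "rejected"]
  hc <- report[report$category != "rejected", , drop = FALSE]
  say("%d candidates -> %d high confidence (%d very high)",
      nrow(report), length(hc_ids),
      sum(report$category == "very_high_confidence"))

  prec_by_id <- stats::setNames(precursors,
                                vapply(precursors, `[[`, character(1), "id"))
  mature_seq <- vapply(hc_ids, function(id) {
    iv <- matures[[id]]
    substr(prec_by_id[[id]]$sequence, iv[1], iv[2])
  }, character(1))

  say("stage homology/families")
  known <- if (!is.null(cfg$known_matures)) read_known_matures(cfg$known_matures)
           else NULL
  abund <- vapply(hc_ids, function(id) {
    ac <- arm_exact_counts(stacks[[id]], prec_by_id[[id]]$sequence,
                           matures[[id]], matures[[id]])
    as.numeric(ac[["mature"]])
  }, numeric(1))
  calls <- do.call(rbind, lapply(seq_along(hc_ids), function(i) {
    cc <- match_known(mature_seq[i], known)
    data.frame(id = hc_ids[i], sequence = mature_seq[i], status = cc$status,
               best_match_id = cc$best_match_id, mismatches = cc$mismatches,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(calls)) {
    calls <- assign_families(calls, abund, prefix = cfg$family_prefix %||% "Jcu")
    write_tsv(calls, file.path(out_dir, "conserved_novel.tsv"))
  }

  say("stage isomiRs")
  iso_args <- as.list(cfg$isomir %||% list())
  isomirs <- do.call(rbind, lapply(hc_ids, function(id) {
    p <- prec_by_id[[id]]
    pt <- parse_dotbracket(p$structure)
    star <- tryCatch(infer_star_coords(pt, matures[[id]]),
                     mircurate_error = function(e) NULL)
    iso <- tryCatch(
      do.call(call_isomirs, c(list(stack = stacks[[id]], prec = p,
                                   mature = matures[[id]], star = star),
                              iso_args)),
      mircurate_error = function(e) NULL)
    if (is.null(iso) || nrow(iso) == 0L) return(NULL)
    cbind(precursor_id = id, iso)
  }))
  if (is.null(isomirs))
    isomirs <- data.frame(precursor_id = character(0), sequence = character(0),
                          type = character(0))
  write_tsv(isomirs, file.path(out_dir, "isomirs.tsv"))

  say("stage quantification")
  sheet <- if (!is.null(cfg$sample_sheet)) read_sample_sheet(cfg$sample_sheet)
           else NULL
  libs <- if (!is.null(sheet)) sheet$sample_id
          else sort(unique(unlist(lapply(stacks[hc_ids], function(s)
            as.character(s$library_id)))))
  counts <- t(vapply(hc_ids, function(id)
    quantify(stacks[[id]], prec_by_id[[id]]$sequence, matures[[id]],
             wu, wd, cfg$quantify_max_mm %||% 1L, libraries = libs),
    integer(length(libs))))
  colnames(counts) <- libs
  write_tsv(data.frame(id = rownames(counts), counts, check.names = FALSE),
            file.path(out_dir, "counts.tsv"))

  n_de <- NA_integer_
  if (!is.null(sheet)) {
    tpm_mat <- tpm(counts, stats::setNames(sheet$genome_mapped_reads,
                                           sheet$sample_id))
    write_tsv(data.frame(id = rownames(tpm_mat), round(tpm_mat, 4),
                         check.names = FALSE),
              file.path(out_dir, "tpm.tsv"))
    reps_ok <- all(table(sheet$stage)[c("young", "intermediate", "mature")] >= 2)
    if (isTRUE(reps_ok)) {
      say("stage differential expression")
      de_cfg <- cfg$de %||% list()
      de <- de_stages(counts, sheet, de_cfg$lfc_threshold %||% 1,
                      de_cfg$alpha %||% 0.05)
      for (cn in names(de$contrasts))
        write_tsv(de$contrasts[[cn]],
                  file.path(out_dir, sprintf("de_%s.tsv", cn)))
      write_tsv(de$flags, file.path(out_dir, "de_flags.tsv"))
      n_de <- sum(de$flags$differentially_expressed)
    }
  }

  comp <- composition_stats(mature_seq)
  write_tsv(data.frame(length = names(comp$length_histogram),
                       count = unname(comp$length_histogram)),
            file.path(out_dir, "composition_length.tsv"))
  write_tsv(data.frame(length = rownames(comp$first_base_matrix),
                       comp$first_base_matrix, check.names = FALSE),
            file.path(out_dir, "composition_first_base.tsv"))

  summary <- list(
    n_candidates = nrow(report),
    n_high_confidence = length(hc_ids),
    n_very_high_confidence = sum(report$category == "very_high_confidence"),
    n_rescued = sum(hc$rescue_applied),
    n_conserved = if (is.null(calls)) 0L else sum(calls$status == "conserved"),
    n_novel = if (is.null(calls)) 0L else sum(calls$status == "novel"),
    n_isomirs = nrow(isomirs),
    n_differentially_expressed = n_de)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  say("done: %s", out_dir)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a complete synthetic fixture bundle
#'
#' Generates a batch of hairpins with planted confidence categories, planted
#' conserved/novel status, planted isomiRs and planted differential
#' expression across a 3-stage x 3-replicate design, and writes the exact
#' file formats [run_pipeline()] consumes: \code{precursors.tsv},
#' \code{stacks.tsv}, \code{sample_sheet.tsv}, \code{known_matures.fasta},
#' \code{truth.json} and \code{config.yaml}. All content is synthetic and
#' reproducible from the seed.
#'
#' @param dir Output directory.
#' @param n_candidates Number of hairpins.
#' @param depth Baseline per-sample read depth per hairpin.
#' @param n_reps Replicates per stage.
#' @param seed RNG seed.
#' @return Invisibly, the path to \code{config.yaml}.
#' @export
write_fixture <- function(dir, n_candidates = 16L, depth = 600L,
                          n_reps = 3L, seed = 42L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    stages <- c("young", "intermediate", "mature")
    sheet <- data.frame(
      sample_id = paste0(rep(substr(stages, 1, 1), each = n_reps),
                         rep(seq_len(n_reps), 3L)),
      stage = rep(stages, each = n_reps),
      replicate = rep(seq_len(n_reps), 3L),
      genome_mapped_reads = 2000000L, stringsAsFactors = FALSE)

    cats <- rep_len(c("very_high_confidence", "very_high_confidence",
                      "high_confidence", "rejected"), n_candidates)
    known_rows <- character(0)
    prec_rows <- list(); stack_rows <- list(); truth <- list()
    for (i in seq_len(n_candidates)) {
      id <- sprintf("fix%03d", i)
      mode <- switch(cats[i], very_high_confidence = "none",
                     high_confidence = sample(c("r5_star_reads", "r7_mfe"), 1L),
                     rejected = "r2_r3")
      args <- list(mature_len = sample(20:22, 1L),
                   mismatches = sample(0:2, 1L), id = id,
                   first_base = sample(RNA_BASES, 1L, prob = c(.1, .1, .1, .7)))
      if (mode == "r7_mfe") args$energy_scale <- 0.2
      if (mode == "r2_r3") {
        args$mismatches <- 6L
        args$bulges <- data.frame(arm = c("mature", "star"), size = c(1L, 1L))
      }
      hp <- do.call(make_hairpin, args)
      p <- hp$precursor

      # planted DE: every 4th candidate changes 4x from young to mature
      de_lfc <- if (i %% 4L == 1L) 2 * (if (i %% 8L == 1L) 1 else -1) else 0
      stage_mult <- stats::setNames(2^(de_lfc * c(0, 0.5, 1)), stages)
      iso <- if (i %% 5L == 0L)
        list(list(type = "3p_extension", shift = 1L, fraction = 0.6)) else list()
      st <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(j) {
        as.data.frame(simulate_stack(
          hp, depth = max(20L, round(depth * stage_mult[[sheet$stage[j]]])),
          excision = 0.92, homogeneity = 0.9,
          star_fraction = if (mode == "r5_star_reads") 0 else 0.3,
          n_libraries = 1L, isomirs = iso,
          library_ids = sheet$sample_id[j]))
      }))

      # half the non-rejected candidates are planted as conserved
      mseq <- substr(p$sequence, hp$mature[1], hp$mature[2])
      conserved <- cats[i] != "rejected" && i %% 2L == 0L
      if (conserved)
        known_rows <- c(known_rows,
                        sprintf(">ath-miR%03d", i),
                        gsub("U", "T", mseq, fixed = TRUE))

      prec_rows[[i]] <- data.frame(id = id, sequence = p$sequence,
                                   structure = p$structure, mfe = p$mfe,
                                   n_genome_hits = p$n_genome_hits,
                                   stringsAsFactors = FALSE)
      stack_rows[[i]] <- cbind(precursor_id = id, st)
      truth[[i]] <- list(id = id, planted_category = cats[i],
                         planted_violation = mode,
                         planted_conserved = conserved,
                         planted_lfc_M_vs_Y = de_lfc,
                         planted_isomirs = length(iso),
                         mature = hp$mature, star = hp$star)
    }
    write_tsv(do.call(rbind, prec_rows), file.path(dir, "precursors.tsv"))
    write_tsv(do.call(rbind, stack_rows), file.path(dir, "stacks.tsv"))
    write_tsv(sheet, file.path(dir, "sample_sheet.tsv"))
    writeLines(known_rows, file.path(dir, "known_matures.fasta"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    cfg <- list(precursors = "precursors.tsv", stacks = "stacks.tsv",
                sample_sheet = "sample_sheet.tsv",
                known_matures = "known_matures.fasta",
                family_prefix = "Jcu")
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    invisible(file.path(dir, "config.yaml"))
  })
}
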