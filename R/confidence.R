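#' Thresholds for the seven-rule confidence scheme
#'
#' Defaults reproduce the published curation criteria: duplexes with 2-nt 3'
#' overhangs (rule 1, with a multi-library fallback when the star is absent),
#' at most four mature/star mismatches (rule 2), at most one asymmetric bulge
#' of fewer than two bases (rule 3), more than 75 percent of reads excised
#' precisely from the two duplex arms (rule 4), at least 10 exact reads per
#' arm (rule 5), at least 50 percent 5' homogeneity per arm (rule 6), and a
#' folding energy below -0.2 kcal/mol/nt (rule 7). Two ancillary candidate
#' checks ride along: at least 60 percent of arm nucleotides paired
#' (informative by default) and at most 15 genome hits.
#'
#' \code{max_bulge_size} is an exclusive bound: a bulge passes when its size
#' is strictly below it, so the default 2 admits only 1-nt bulges ("less than
#' two bases in the bulge"). Set it to 3 to admit 2-nt bulges.
#'
#' @param max_mismatches,max_bulges,max_bulge_size,min_overhang,min_excision
#'   Rule 1-4 thresholds; see above.
#' @param min_paired_fraction Minimum fraction of paired arm nucleotides.
#' @param min_arm_exact_reads,min_5p_homogeneity,max_mfe_per_nt Rule 5-7
#'   thresholds.
#' @param min_libraries Libraries required by the rule-1 fallback
#'   ("multiple, independent libraries"; >= 2 by default).
#' @param max_genome_hits Candidate filter on genome multi-mapping.
#' @return Named list of class \code{"mirna_thresholds"}.
#' @export
mirna_thresholds <- function(max_mismatches = 4L,
                             max_bulges = 1L,
                             max_bulge_size = 2L,
                             min_overhang = 2L,
                             min_excision = 0.75,
                             min_paired_fraction = 0.60,
                             min_arm_exact_reads = 10L,
                             min_5p_homogeneity = 0.50,
                             max_mfe_per_nt = -0.2,
                             min_libraries = 2L,
                             max_genome_hits = 15L) {
  t <- list(max_mismatches = max_mismatches, max_bulges = max_bulges,
            max_bulge_size = max_bulge_size, min_overhang = min_overhang,
            min_excision = min_excision,
            min_paired_fraction = min_paired_fraction,
            min_arm_exact_reads = min_arm_exact_reads,
            min_5p_homogeneity = min_5p_homogeneity,
            max_mfe_per_nt = max_mfe_per_nt,
            min_libraries = min_libraries,
            max_genome_hits = max_genome_hits)
  bad <- vapply(t, function(x) !is.numeric(x) || length(x) != 1L || is.na(x),
                logical(1))
  if (any(bad))
    mc_stop("parameter_error", "invalid threshold(s): %s",
            paste(names(t)[bad], collapse = ", "))
  for (f in c("min_excision", "min_paired_fraction", "min_5p_homogeneity"))
    if (t[[f]] < 0 || t[[f]] > 1)
      mc_stop("parameter_error", "%s must lie in [0, 1]", f)
  structure(t, class = c("mirna_thresholds", "list"))
}

#' Evaluate the seven confidence rules on one candidate
#'
#' Every rule records both its verdict and the observed value it was judged
#' on; degenerate inputs (e.g. \code{NA} homogeneity for an arm with no
#' reads) fail the rule rather than erroring. Boundary semantics follow the
#' published wording exactly: "at least" is \code{>=}, "more than" and
#' "less than" are strict.
#'
#' @param profile A [duplex_profile()].
#' @param evidence An [evidence_summary()].
#' @param prec The [precursor()].
#' @param star_present Logical: was a star strand observed in the reads?
#'   When \code{FALSE}, rule 1 falls back to multi-library detection.
#' @param thresholds A [mirna_thresholds()] list.
#' @return List of class \code{"rule_report"}: elements \code{r1} .. \code{r7},
#'   \code{paired_fraction_ok} and \code{genome_hits_ok}, each a list with
#'   \code{pass} and \code{observed}; plus \code{star_present}.
#' @export
evaluate_rules <- function(profile, evidence, prec, star_present,
                           thresholds = mirna_thresholds()) {
  t <- thresholds
  ok <- function(x) length(x) == 1L && !is.na(x)
  rule <- function(pass, observed) list(pass = isTRUE(pass), observed = observed)

  overhangs <- c(profile$overhang_mature_3p, profile$overhang_star_3p)
  r1 <- if (isTRUE(star_present)) {
    rule(all(overhangs >= t$min_overhang), overhangs)
  } else {
    rule(evidence$libraries_detected >= t$min_libraries,
         evidence$libraries_detected)
  }
  bulge_ok <- nrow(profile$bulges) <= t$max_bulges &&
    (nrow(profile$bulges) == 0L || all(profile$bulges$size < t$max_bulge_size))
  exact <- c(evidence$arm_exact_reads_mature, evidence$arm_exact_reads_star)
  hom <- c(evidence$five_prime_homogeneity_mature,
           evidence$five_prime_homogeneity_star)
  pf <- c(profile$paired_fraction_mature, profile$paired_fraction_star)
  structure(class = "rule_report", list(
    r1 = c(r1, list(star_present = isTRUE(star_present),
                    libraries_detected = evidence$libraries_detected)),
    r2 = rule(profile$mismatches <= t$max_mismatches, profile$mismatches),
    r3 = rule(bulge_ok, profile$bulges),
    r4 = rule(ok(evidence$excision_fraction) &&
                evidence$excision_fraction > t$min_excision,
              evidence$excision_fraction),
    r5 = rule(all(exact >= t$min_arm_exact_reads), exact),
    r6 = rule(all(!is.na(hom)) && all(hom >= t$min_5p_homogeneity), hom),
    r7 = rule(mfe_per_nt(prec) < t$max_mfe_per_nt, mfe_per_nt(prec)),
    paired_fraction_ok = rule(all(pf >= t$min_paired_fraction), pf),
    genome_hits_ok = rule(prec$n_genome_hits <= t$max_genome_hits,
                          prec$n_genome_hits),
    star_present = isTRUE(star_present)
  ))
}

#' Turn a rule report into a confidence call
#'
#' High confidence requires the three structural rules (1-3) to pass; a
#' candidate violating exactly one of them is rescued when precise excision
#' (rule 4) is shown. Candidates passing rules 1-3 but not rule 4 remain high
#' confidence with a \code{low_excision} warning flag (set
#' \code{require_r4 = TRUE} to make rule 4 a hard requirement). Very high
#' confidence additionally needs the read-support rules 5-7. Candidates
#' exceeding the genome multi-hit filter are rejected outright.
#'
#' @param report A [evaluate_rules()] report.
#' @param require_r4 Make rule 4 mandatory for non-rescued candidates.
#' @return List of class \code{"confidence_call"}: \code{category} (one of
#'   \code{"rejected"}, \code{"high_confidence"},
#'   \code{"very_high_confidence"}), \code{rescue_applied},
#'   \code{low_excision}, and the \code{report}.
#' @export
classify <- function(report, require_r4 = FALSE) {
  core <- c(report$r1$pass, report$r2$pass, report$r3$pass)
  r4 <- report$r4$pass
  rescue <- FALSE
  hc <- FALSE
  if (report$genome_hits_ok$pass) {
    if (all(core) && (r4 || !require_r4)) {
      hc <- TRUE
    } else if (sum(!core) == 1L && r4) {
      hc <- TRUE
      rescue <- TRUE
    }
  }
  vhc <- hc && report$r5$pass && report$r6$pass && report$r7$pass
  structure(class = "confidence_call", list(
    category = if (vhc) "very_high_confidence"
               else if (hc) "high_confidence" else "rejected",
    rescue_applied = rescue,
    low_excision = hc && !rescue && !r4,
    report = report
  ))
}

#' @export
print.confidence_call <- function(x, ...) {
  verdicts <- vapply(x$report[paste0("r", 1:7)], function(r) r$pass, logical(1))
  cat(sprintf("<%s | rules: %s%s%s>\n", x$category,
              paste(ifelse(verdicts, "+", "-"), collapse = ""),
              if (x$rescue_applied) " rescued" else "",
              if (x$low_excision) " low-excision" else ""))
  invisible(x)
}

#' Classify a batch of candidates
#'
#' Runs geometry, evidence and classification for a set of precursors with
#' known mature intervals and read stacks, returning one report row per
#' candidate.
#'
#' @param candidates List of lists, each with \code{precursor} (a
#'   [precursor()]), \code{mature} interval, optional \code{star} interval
#'   (inferred from structure when absent) and \code{stack} (a
#'   [read_stack()]).
#' @param thresholds A [mirna_thresholds()].
#' @param require_r4 Passed to [classify()].
#' @param window_up,window_down Quantifier windows for the evidence metrics.
#' @return data.frame with observed values, per-rule verdicts, rescue flag
#'   and final category, one row per candidate.
#' @export
classify_batch <- function(candidates, thresholds = mirna_thresholds(),
                           require_r4 = FALSE,
                           window_up = 2L, window_down = 5L) {
  rows <- lapply(candidates, function(cand) {
    p <- cand$precursor
    pt <- parse_dotbracket(p$structure)
    geom_fail <- function(e) NULL
    star <- cand$star
    if (is.null(star))
      star <- tryCatch(infer_star_coords(pt, cand$mature), mircurate_error = geom_fail)
    prof <- if (is.null(star)) NULL else
      tryCatch(duplex_profile(pt, cand$mature, star), mircurate_error = geom_fail)
    if (is.null(prof)) {
      # unresolvable duplex geometry: structural rules fail, candidate rejected
      return(data.frame(
        id = p$id, category = "rejected", rescue_applied = FALSE,
        low_excision = FALSE, star_present = FALSE, mismatches = NA_integer_,
        n_bulges = NA_integer_, max_bulge_size = NA_integer_,
        overhang_mature_3p = NA_integer_, overhang_star_3p = NA_integer_,
        paired_fraction_mature = NA_real_, paired_fraction_star = NA_real_,
        excision_fraction = NA_real_, arm_exact_reads_mature = NA_integer_,
        arm_exact_reads_star = NA_integer_,
        five_prime_homogeneity_mature = NA_real_,
        five_prime_homogeneity_star = NA_real_,
        libraries_detected = NA_integer_, dominance = NA_real_,
        mfe_per_nt = mfe_per_nt(p), n_genome_hits = p$n_genome_hits,
        r1 = FALSE, r2 = FALSE, r3 = FALSE, r4 = FALSE, r5 = FALSE,
        r6 = FALSE, r7 = FALSE, paired_fraction_ok = FALSE,
        genome_hits_ok = TRUE, stringsAsFactors = FALSE))
    }
    ev <- evidence_summary(cand$stack, p$sequence, cand$mature, star,
                           window_up, window_down)
    star_present <- ev$arm_exact_reads_star > 0L
    rep <- evaluate_rules(prof, ev, p, star_present, thresholds)
    call <- classify(rep, require_r4)
    data.frame(
      id = p$id, category = call$category,
      rescue_applied = call$rescue_applied, low_excision = call$low_excision,
      star_present = star_present, mismatches = prof$mismatches,
      n_bulges = nrow(prof$bulges),
      max_bulge_size = if (nrow(prof$bulges)) max(prof$bulges$size) else 0L,
      overhang_mature_3p = prof$overhang_mature_3p,
      overhang_star_3p = prof$overhang_star_3p,
      paired_fraction_mature = prof$paired_fraction_mature,
      paired_fraction_star = prof$paired_fraction_star,
      excision_fraction = ev$excision_fraction,
      arm_exact_reads_mature = ev$arm_exact_reads_mature,
      arm_exact_reads_star = ev$arm_exact_reads_star,
      five_prime_homogeneity_mature = ev$five_prime_homogeneity_mature,
      five_prime_homogeneity_star = ev$five_prime_homogeneity_star,
      libraries_detected = ev$libraries_detected, dominance = ev$dominance,
      mfe_per_nt = mfe_per_nt(p), n_genome_hits = p$n_genome_hits,
      r1 = rep$r1$pass, r2 = rep$r2$pass, r3 = rep$r3$pass, r4 = rep$r4$pass,
      r5 = rep$r5$pass, r6 = rep$r6$pass, r7 = rep$r7$pass,
      paired_fraction_ok = rep$paired_fraction_ok$pass,
      genome_hits_ok = rep$genome_hits_ok$pass, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
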