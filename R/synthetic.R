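#' Construct a synthetic hairpin precursor with prescribed duplex geometry
#'
#' Builds a stem-loop whose mature/star duplex has exactly the requested
#' number of symmetric mismatches, the requested asymmetric bulges, and the
#' requested 3' overhangs, so that [duplex_profile()] on the product
#' round-trips the request. The synthetic MFE is a deterministic function of
#' the structure, \code{-energy_scale * paired_fraction * length}, so rule 7
#' can be steered to either side of its threshold without thermodynamic
#' folding.
#'
#' @param mature_len Mature length in nt (18-30).
#' @param mismatches Number of single-base symmetric mismatches in the duplex.
#' @param bulges data.frame with columns \code{arm} (\code{"mature"} or
#'   \code{"star"}) and \code{size} (nt), or an empty list.
#' @param overhangs 3' overhang length at both duplex ends (canonical: 2).
#' @param flank5,flank3 Unpaired flank lengths.
#' @param loop Loop length (>= 3).
#' @param first_base Optional first nucleotide of the mature sequence.
#' @param energy_scale kcal/mol/nt per unit paired fraction (default 0.5
#'   gives mfe_per_nt around -0.33 for a typical stem).
#' @param id Precursor id.
#' @param n_genome_hits Planted genome multi-hit count.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return List with \code{precursor} (a [precursor()]), \code{mature} and
#'   \code{star} intervals.
#' @export
make_hairpin <- function(mature_len = 21L, mismatches = 0L, bulges = list(),
                         overhangs = 2L, flank5 = 5L, flank3 = 2L,
                         loop = 8L, first_base = NULL, energy_scale = 0.5,
                         id = "hp1", n_genome_hits = 1L, seed = NULL) {
  with_seed(seed, {
    if (is.list(bulges) && !is.data.frame(bulges)) {
      bulges <- if (length(bulges) == 0L)
        data.frame(arm = character(0), size = integer(0))
      else do.call(rbind, lapply(bulges, function(b)
        data.frame(arm = b[["arm"]], size = as.integer(b[["size"]]))))
    }
    if (loop < 3L)
      mc_stop("parameter_error", "loop must be >= 3 nt")
    if (mature_len < 18L || mature_len > 30L)
      mc_stop("parameter_error", "mature_len must be in [18, 30]")
    if (nrow(bulges) && (!all(bulges$arm %in% c("mature", "star")) ||
                         any(bulges$size < 1L)))
      mc_stop("parameter_error", "bulges need arm in {mature, star} and size >= 1")
    m_bulge <- sum(bulges$size[bulges$arm == "mature"])
    s_bulge <- sum(bulges$size[bulges$arm == "star"])
    P <- mature_len - overhangs - mismatches - m_bulge  # paired columns
    n_events <- mismatches + nrow(bulges)
    if (P < 2L || n_events > P - 1L)
      mc_stop("parameter_error",
              "infeasible duplex: %d paired columns for %d events", P, n_events)

    # event tokens spread over distinct interior gaps (after paired column g)
    events <- c(rep(list(list(kind = "mm")), mismatches),
                if (nrow(bulges)) lapply(seq_len(nrow(bulges)), function(i)
                  list(kind = "bulge", arm = bulges$arm[i],
                       size = bulges$size[i])))
    gaps <- if (n_events)
      unique(round(seq(1, P - 1L, length.out = n_events + 2L)))[-c(1L, n_events + 2L)]
    else integer(0)
    if (length(gaps) < n_events)
      gaps <- seq_len(n_events)  # dense fallback for tiny stems

    star_core <- P + mismatches + s_bulge
    star_len <- star_core + overhangs
    ms <- flank5 + 1L
    me <- ms + mature_len - 1L
    ss <- me + loop + 1L
    se <- ss + star_len - 1L
    L <- se + flank3
    partner <- rep(NA_integer_, L)
    mism_m <- integer(0)  # mature position of each mismatch column
    mism_s <- integer(0)  # opposing star position

    m_pos <- ms
    s_pos <- se - overhangs
    ev_at <- stats::setNames(events, as.character(gaps))
    for (g in seq_len(P)) {
      partner[m_pos] <- s_pos
      partner[s_pos] <- m_pos
      m_pos <- m_pos + 1L; s_pos <- s_pos - 1L
      ev <- ev_at[[as.character(g)]]
      if (!is.null(ev)) {
        if (ev$kind == "mm") {
          mism_m <- c(mism_m, m_pos)
          mism_s <- c(mism_s, s_pos)
          m_pos <- m_pos + 1L; s_pos <- s_pos - 1L
        } else if (ev$arm == "mature") {
          m_pos <- m_pos + ev$size
        } else {
          s_pos <- s_pos - ev$size
        }
      }
    }
    stopifnot(m_pos == me - overhangs + 1L, s_pos == ss - 1L)

    base <- character(L)
    unset <- setdiff(seq_len(L), which(!is.na(partner)))
    base[unset] <- sample(RNA_BASES, length(unset), replace = TRUE)
    # mature side first, then complement across pairs
    midx <- ms:me
    base[midx[is.na(base[midx]) | base[midx] == ""]] <-
      sample(RNA_BASES, sum(base[midx] == ""), replace = TRUE)
    if (!is.null(first_base)) base[ms] <- first_base
    for (i in midx) if (!is.na(partner[i])) base[partner[i]] <- RNA_COMPLEMENT[[base[i]]]
    # mismatch columns: opposing star base identical to the mature base
    # (no base pairs with itself, so the column can never pair)
    if (length(mism_m)) base[mism_s] <- base[mism_m]
    structure_chars <- rep(".", L)
    paired <- which(!is.na(partner))
    structure_chars[paired[partner[paired] > paired]] <- "("
    structure_chars[paired[partner[paired] < paired]] <- ")"

    pf <- length(paired) / L
    p <- precursor(id, paste(base, collapse = ""),
                   paste(structure_chars, collapse = ""),
                   mfe = -energy_scale * pf * L, n_genome_hits = n_genome_hits)
    list(precursor = p, mature = c(ms, me), star = c(ss, se))
  })
}

# Build one isomiR read template from a type spec against the mature arm.
isomir_template <- function(pseq, mature, type, shift = 1L, mm_pos = 5L) {
  ms <- mature[1]; me <- mature[2]
  sub <- function(a, b) substr(pseq, a, b)
  flip <- function(b) RNA_BASES[RNA_BASES != b][1]
  switch(type,
    "5p_deletion" = list(start = ms + shift, sequence = sub(ms + shift, me)),
    "5p_extension" = list(start = ms - shift, sequence = sub(ms - shift, me)),
    "3p_extension" = list(start = ms, sequence = sub(ms, me + shift)),
    "3p_deletion" = list(start = ms, sequence = sub(ms, me - shift)),
    "3p_nontemplated" = {
      s <- seq_chars(sub(ms, me))
      n <- length(s)
      k <- max(1L, shift)
      s[(n - k + 1L):n] <- vapply(s[(n - k + 1L):n], flip, character(1))
      list(start = ms, sequence = paste(s, collapse = ""))
    },
    "polymorphic" = {
      s <- seq_chars(sub(ms, me))
      s[mm_pos] <- flip(s[mm_pos])
      list(start = ms, sequence = paste(s, collapse = ""))
    },
    mc_stop("parameter_error", "unknown isomiR type '%s'", type))
}

#' Simulate a small-RNA read stack over a hairpin
#'
#' Draws multinomial read counts per library over a small set of read
#' templates: modal mature/star reads, 5'-shifted variants (controlling 5'
#' homogeneity), off-duplex loop-spanning reads (controlling the excision
#' fraction), and optional planted isomiRs whose pooled counts are fixed
#' fractions of the sampled modal mature count.
#'
#' @param hp A [make_hairpin()] result.
#' @param depth Expected read count per library.
#' @param excision Fraction of reads inside the windowed duplex arms.
#' @param homogeneity Fraction of arm reads sharing the modal 5' end.
#' @param star_fraction Fraction of duplex reads on the star arm.
#' @param n_libraries Number of libraries (multinomial draws).
#' @param isomirs List of planted isomiRs, each
#'   \code{list(type =, shift =, fraction =)} with \code{fraction} relative
#'   to the pooled modal mature count.
#' @param library_ids Optional library names.
#' @param seed Optional RNG seed.
#' @return A [read_stack()].
#' @export
simulate_stack <- function(hp, depth = 1000L, excision = 0.9,
                           homogeneity = 0.95, star_fraction = 0.2,
                           n_libraries = 3L, isomirs = list(),
                           library_ids = NULL, seed = NULL) {
  for (f in c(excision, homogeneity, star_fraction))
    if (!is.finite(f) || f < 0 || f > 1)
      mc_stop("parameter_error", "fractions must lie in [0, 1]")
  with_seed(seed, {
    p <- hp$precursor; pseq <- p$sequence
    mature <- hp$mature; star <- hp$star
    ms <- mature[1]; me <- mature[2]; ss <- star[1]; se <- star[2]
    mature_seq <- substr(pseq, ms, me)
    star_seq <- substr(pseq, ss, se)
    # 5'-shifted variants; keep >= 18 nt by extending the 3' end when needed.
    # Non-modal mass is split over two shifted starts so that low homogeneity
    # settings really dethrone the modal 5' end (no single start > 50%).
    shift_tmpl <- function(a, b) {
      while (b - a + 1L < 18L) b <- b + 1L
      list(start = a, sequence = substr(pseq, a, b))
    }
    shift_m1 <- shift_tmpl(ms + 1L, me); shift_m2 <- shift_tmpl(ms + 2L, me)
    shift_s1 <- shift_tmpl(ss + 1L, se); shift_s2 <- shift_tmpl(ss + 2L, se)
    off1 <- list(start = me - 8L, sequence = substr(pseq, me - 8L, me + 9L))
    off2 <- list(start = me - 9L, sequence = substr(pseq, me - 9L, me + 8L))

    pm <- excision * (1 - star_fraction); ps <- excision * star_fraction
    tmpl <- data.frame(
      start = c(ms, shift_m1$start, shift_m2$start,
                ss, shift_s1$start, shift_s2$start, off1$start, off2$start),
      sequence = c(mature_seq, shift_m1$sequence, shift_m2$sequence,
                   star_seq, shift_s1$sequence, shift_s2$sequence,
                   off1$sequence, off2$sequence),
      p = c(pm * homogeneity, pm * (1 - homogeneity) / 2, pm * (1 - homogeneity) / 2,
            ps * homogeneity, ps * (1 - homogeneity) / 2, ps * (1 - homogeneity) / 2,
            (1 - excision) / 2, (1 - excision) / 2),
      stringsAsFactors = FALSE)
    tmpl <- tmpl[tmpl$p > 0, , drop = FALSE]
    if (is.null(library_ids))
      library_ids <- sprintf("lib%02d", seq_len(n_libraries))

    counts <- stats::rmultinom(length(library_ids), depth, tmpl$p)
    rows <- do.call(rbind, lapply(seq_along(library_ids), function(j) {
      keep <- counts[, j] > 0L
      if (!any(keep)) return(NULL)
      data.frame(library_id = library_ids[j], start = tmpl$start[keep],
                 sequence = tmpl$sequence[keep], count = counts[keep, j],
                 stringsAsFactors = FALSE)
    }))

    # planted isomiRs: pooled count pinned to a fraction of the sampled
    # modal mature count, spread round-robin over libraries
    modal_pool <- sum(counts[which(tmpl$start == ms & tmpl$sequence == mature_seq), ])
    for (iso in isomirs) {
      tm <- isomir_template(pseq, mature, iso$type,
                            shift = if (is.null(iso$shift)) 1L else iso$shift)
      tot <- round(iso$fraction * modal_pool)
      if (tot < 1L) next
      per <- diff(round(seq(0, tot, length.out = length(library_ids) + 1L)))
      for (j in seq_along(library_ids)) if (per[j] > 0L)
        rows <- rbind(rows, data.frame(
          library_id = library_ids[j], start = tm$start,
          sequence = tm$sequence, count = per[j], stringsAsFactors = FALSE))
    }
    if (is.null(rows))
      rows <- data.frame(library_id = character(0), start = integer(0),
                         sequence = character(0), count = integer(0))
    read_stack(p$id, rows)
  })
}

#' Simulate a classifier benchmark batch with planted categories
#'
#' Generates candidates whose planted confidence category is forced by
#' deterministic geometry or by wide-margin read evidence: very high
#' confidence candidates pass all seven rules comfortably; high confidence
#' candidates fail exactly one of rules 5-7 (absent star reads, scrambled 5'
#' ends, or a weak synthetic MFE) or are rescued single-structural-rule
#' violators; rejected candidates violate two structural rules or the genome
#' multi-hit filter.
#'
#' @param n Number of candidates.
#' @param composition Named proportions over \code{very_high_confidence},
#'   \code{high_confidence}, \code{rejected}.
#' @param depth,n_libraries Read-stack parameters.
#' @param seed RNG seed.
#' @return List with \code{candidates} (input for [classify_batch()]) and
#'   \code{truth} (data.frame \code{id}, \code{planted_category},
#'   \code{planted_violation}).
#' @export
simulate_candidates <- function(n = 100L,
                                composition = c(very_high_confidence = 0.45,
                                                high_confidence = 0.35,
                                                rejected = 0.20),
                                depth = 2000L, n_libraries = 3L, seed = 1L) {
  with_seed(seed, {
    cats <- sample(names(composition), n, replace = TRUE, prob = composition)
    hc_modes <- c("r5_star_reads", "r6_homogeneity", "r7_mfe", "rescued_r2")
    rej_modes <- c("r2_r3", "genome_hits")
    cands <- vector("list", n)
    truth <- data.frame(id = sprintf("syn%04d", seq_len(n)),
                        planted_category = cats,
                        planted_violation = NA_character_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      id <- truth$id[i]
      mode <- switch(cats[i],
                     very_high_confidence = "none",
                     high_confidence = sample(hc_modes, 1L),
                     rejected = sample(rej_modes, 1L))
      truth$planted_violation[i] <- mode
      mm <- sample(0:2, 1L)
      bul <- if (stats::runif(1) < 0.3)
        data.frame(arm = sample(c("mature", "star"), 1L), size = 1L)
      else list()
      args <- list(mature_len = sample(20:22, 1L), mismatches = mm,
                   bulges = bul, id = id)
      stack_args <- list(depth = depth, excision = 0.92, homogeneity = 0.9,
                         star_fraction = 0.3, n_libraries = n_libraries)
      if (mode == "r5_star_reads") stack_args$star_fraction <- 0
      if (mode == "r6_homogeneity") stack_args$homogeneity <- 0.25
      if (mode == "r7_mfe") args$energy_scale <- 0.2
      if (mode == "rescued_r2") {
        # single structural violation rescued by precise excision; the weak
        # synthetic MFE keeps the call at high (not very high) confidence
        args$mismatches <- 5L
        args$energy_scale <- 0.2
      }
      if (mode == "r2_r3") {
        args$mismatches <- 6L
        args$bulges <- data.frame(arm = c("mature", "star"), size = c(1L, 1L))
      }
      if (mode == "genome_hits") args$n_genome_hits <- 20L
      hp <- do.call(make_hairpin, args)
      stack <- do.call(simulate_stack, c(list(hp = hp), stack_args))
      cands[[i]] <- list(precursor = hp$precursor, mature = hp$mature,
                         star = hp$star, stack = stack)
    }
    list(candidates = cands, truth = truth)
  })
}

#' Simulate a 3-stage x n-replicate count experiment with planted effects
#'
#' Draws negative-binomial counts for each miRNA across young, intermediate
#' and mature stages. A planted fraction of miRNAs changes expression by
#' \code{planted_lfc} log2 units between young and mature (half the effect
#' at the intermediate stage, i.e. a continuous trend), with alternating
#' sign. Mature lengths follow \code{length_mix} and first bases follow a
#' per-length bias (defaults: 21-nt modal with a 24-nt secondary class;
#' U-dominant first base at 20-22 nt, C-preference at 24 nt).
#'
#' @param n_mirnas Number of miRNAs.
#' @param n_reps Replicates per stage.
#' @param mean_baseline Median baseline expression (counts).
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param planted_de_fraction Fraction of miRNAs with a planted effect.
#' @param planted_lfc Planted |log2 fold change| between mature and young.
#' @param length_mix Named probabilities over mature lengths.
#' @param first_base_bias Named list: length -> probability vector over
#'   \code{A,C,G,U}.
#' @param genome_mapped Genome-mapped read total per sample.
#' @param seed RNG seed.
#' @return List with \code{counts} (matrix), \code{sample_sheet},
#'   \code{truth} (per-miRNA planted log2 fold changes, length, first base)
#'   and \code{mature_sequences}.
#' @export
simulate_experiment <- function(n_mirnas = 100L, n_reps = 3L,
                                mean_baseline = 200, dispersion = 0.1,
                                planted_de_fraction = 0.2, planted_lfc = 2,
                                length_mix = c("20" = 0.10, "21" = 0.55,
                                               "22" = 0.15, "24" = 0.20),
                                first_base_bias = NULL,
                                genome_mapped = 2e6, seed = 1L) {
  if (abs(sum(length_mix) - 1) > 1e-8)
    mc_stop("parameter_error", "length_mix must sum to 1")
  if (is.null(first_base_bias))
    first_base_bias <- list(
      "20" = c(A = .1, C = .1, G = .1, U = .7),
      "21" = c(A = .1, C = .1, G = .1, U = .7),
      "22" = c(A = .1, C = .1, G = .1, U = .7),
      "24" = c(A = .15, C = .5, G = .15, U = .2))
  with_seed(seed, {
    stages <- c("young", "intermediate", "mature")
    sheet <- data.frame(
      sample_id = paste0(rep(substr(stages, 1, 1), each = n_reps),
                         rep(seq_len(n_reps), 3L)),
      stage = rep(stages, each = n_reps),
      replicate = rep(seq_len(n_reps), 3L),
      genome_mapped_reads = as.integer(genome_mapped),
      stringsAsFactors = FALSE)

    base_mu <- stats::rlnorm(n_mirnas, log(mean_baseline), 1)
    n_de <- round(planted_de_fraction * n_mirnas)
    lfc_my <- numeric(n_mirnas)
    if (n_de > 0)
      lfc_my[seq_len(n_de)] <- planted_lfc * rep_len(c(1, -1), n_de)
    stage_lfc <- cbind(young = 0, intermediate = lfc_my / 2, mature = lfc_my)

    counts <- matrix(0L, n_mirnas, nrow(sheet),
                     dimnames = list(sprintf("mir%04d", seq_len(n_mirnas)),
                                     sheet$sample_id))
    for (j in seq_len(nrow(sheet))) {
      mu <- base_mu * 2^stage_lfc[, sheet$stage[j]]
      counts[, j] <- stats::rnbinom(n_mirnas, size = 1 / dispersion, mu = mu)
    }

    len_vals <- as.integer(names(length_mix))
    lens <- len_vals[sample.int(length(len_vals), n_mirnas, replace = TRUE,
                                prob = length_mix)]
    first <- vapply(lens, function(l) {
      bias <- first_base_bias[[as.character(l)]]
      if (is.null(bias)) bias <- stats::setNames(rep(0.25, 4), RNA_BASES)
      sample(RNA_BASES, 1L, prob = bias[RNA_BASES])
    }, character(1))
    seqs <- vapply(seq_len(n_mirnas), function(i)
      paste0(first[i], paste(sample(RNA_BASES, lens[i] - 1L, replace = TRUE),
                             collapse = "")), character(1))

    list(counts = counts, sample_sheet = sheet,
         truth = data.frame(id = rownames(counts), planted_lfc_M_vs_Y = lfc_my,
                            length = lens, first_base = first,
                            stringsAsFactors = FALSE),
         mature_sequences = seqs)
  })
}
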