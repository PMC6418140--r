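#' Build a read stack
#'
#' A read stack is the set of small-RNA reads aligned to one precursor,
#' across libraries, with counts. Canonical on-disk form is a TSV with
#' columns \code{precursor_id, library_id, start, sequence, count}
#' (\code{start} 1-based on the precursor).
#'
#' @param precursor_id Precursor identifier.
#' @param reads data.frame with columns \code{library_id}, \code{start},
#'   \code{sequence}, \code{count}.
#' @return data.frame of class \code{"read_stack"} with a
#'   \code{precursor_id} attribute.
#' @export
read_stack <- function(precursor_id, reads) {
  need <- c("library_id", "start", "sequence", "count")
  miss <- setdiff(need, names(reads))
  if (length(miss))
    mc_stop("format_error", "read stack missing column(s): %s",
            paste(miss, collapse = ", "))
  reads <- reads[need]
  reads$sequence <- toupper(gsub("T", "U", reads$sequence, fixed = TRUE))
  reads$start <- as.integer(reads$start)
  reads$count <- as.integer(reads$count)
  if (nrow(reads) && any(reads$count < 1L))
    mc_stop("format_error", "read counts must be >= 1")
  len <- nchar(reads$sequence)
  if (nrow(reads) && any(len < 18L | len > 30L))
    mc_stop("format_error", "read lengths must be in [18, 30] nt")
  attr(reads, "precursor_id") <- as.character(precursor_id)
  class(reads) <- c("read_stack", "data.frame")
  reads
}

# Per-read mismatch structure against the precursor: positions beyond the
# precursor 3' end count as (trailing) mismatches. Returns n_internal,
# n_trailing3p (the maximal run of terminal 3' mismatches) and the
# read-relative positions of internal mismatches.
read_mismatch_profile <- function(sequence, start, precursor_seq) {
  rs <- seq_chars(sequence)
  n <- length(rs)
  pos <- start + seq_len(n) - 1L
  plen <- nchar(precursor_seq)
  tmpl <- rep(NA_character_, n)
  ok <- pos >= 1L & pos <= plen
  if (any(ok)) tmpl[ok] <- seq_chars(precursor_seq)[pos[ok]]
  mm <- is.na(tmpl) | rs != tmpl
  n_trail <- 0L
  while (n_trail < n && mm[n - n_trail]) n_trail <- n_trail + 1L
  internal <- which(mm[seq_len(n - n_trail)])
  list(n_internal = length(internal), n_trailing3p = n_trail,
       internal_positions = internal, n_total = sum(mm))
}

# Vectorized total mismatch count per read (internal + trailing).
stack_mismatch_counts <- function(stack, precursor_seq) {
  if (nrow(stack) == 0L) return(integer(0))
  vapply(seq_len(nrow(stack)), function(i)
    read_mismatch_profile(stack$sequence[i], stack$start[i], precursor_seq)$n_total,
    integer(1))
}

# Windowed-arm assignment: a read belongs to an arm iff its full span lies in
# [arm_start - window_up, arm_end + window_down]. Reads fitting both arms go
# to mature (conservative toward the excision rule).
assign_arm <- function(stack, mature, star = NULL,
                       window_up = 2L, window_down = 5L) {
  if (nrow(stack) == 0L) return(character(0))
  s <- stack$start
  e <- stack$start + nchar(stack$sequence) - 1L
  in_iv <- function(iv) !is.null(iv) &
    s >= iv[1] - window_up & e <= iv[2] + window_down
  out <- rep(NA_character_, nrow(stack))
  if (!is.null(star)) out[in_iv(star)] <- "star"
  out[in_iv(mature)] <- "mature"
  out
}

#' Exact read support for the two duplex arms
#'
#' Counts reads that map with zero mismatches, start exactly at the arm's
#' 5' end, and lie entirely within the arm interval (confidence rule 5 asks
#' for at least 10 such reads on each arm).
#'
#' @param stack A [read_stack()].
#' @param precursor_seq Precursor sequence the stack is aligned to.
#' @param mature,star Arm intervals.
#' @return Named integer vector \code{c(mature = , star = )}.
#' @export
arm_exact_counts <- function(stack, precursor_seq, mature, star) {
  if (nrow(stack) == 0L) return(c(mature = 0L, star = 0L))
  mm <- stack_mismatch_counts(stack, precursor_seq)
  e <- stack$start + nchar(stack$sequence) - 1L
  one <- function(iv) {
    hit <- mm == 0L & stack$start == iv[1] & e <= iv[2]
    sum(stack$count[hit])
  }
  c(mature = one(mature), star = one(star))
}

#' Precise-excision fraction
#'
#' Fraction of total read counts lying inside the windowed mature or star
#' intervals; confidence rule 4 requires more than 75 percent.
#'
#' @inheritParams arm_exact_counts
#' @param window_up,window_down Window in nt added at the arm 5'/3' ends.
#' @export
excision_fraction <- function(stack, mature, star,
                              window_up = 2L, window_down = 5L) {
  total <- sum(stack$count)
  if (total == 0L)
    mc_stop("undefined_evidence_error", "read stack has zero total count")
  arm <- assign_arm(stack, mature, star, window_up, window_down)
  sum(stack$count[!is.na(arm)]) / total
}

#' 5' homogeneity of an arm
#'
#' Fraction of arm-assigned read counts sharing the modal 5' start
#' (confidence rule 6 requires at least 50 percent per arm). Ties in the
#' modal start are broken to the 5'-most (smallest) position.
#'
#' @inheritParams excision_fraction
#' @param arm Interval of the arm being evaluated.
#' @export
five_prime_homogeneity <- function(stack, arm, window_up = 2L, window_down = 5L) {
  asn <- assign_arm(stack, arm, NULL, window_up, window_down)
  keep <- !is.na(asn)
  if (!any(keep))
    mc_stop("undefined_evidence_error", "no reads assigned to the arm")
  counts <- tapply(stack$count[keep], stack$start[keep], sum)
  starts <- as.integer(names(counts))
  modal <- starts[counts == max(counts)]
  modal <- min(modal)  # tie -> leftmost
  sum(counts[starts == modal]) / sum(counts)
}

#' Number of libraries in which the mature miRNA is detected
#'
#' A library "detects" the miRNA when it contributes at least one read inside
#' the windowed mature interval. Used by the rule-1 fallback when no star
#' reads exist ("found in multiple, independent libraries").
#'
#' @inheritParams excision_fraction
#' @export
libraries_detected <- function(stack, mature, window_up = 2L, window_down = 5L) {
  if (nrow(stack) == 0L) return(0L)
  asn <- assign_arm(stack, mature, NULL, window_up, window_down)
  length(unique(stack$library_id[!is.na(asn)]))
}

#' Mature-arm dominance
#'
#' Fraction of all read counts assigned to the windowed mature arm.
#'
#' @inheritParams excision_fraction
#' @export
dominance <- function(stack, mature, star, window_up = 2L, window_down = 5L) {
  total <- sum(stack$count)
  if (total == 0L)
    mc_stop("undefined_evidence_error", "read stack has zero total count")
  asn <- assign_arm(stack, mature, star, window_up, window_down)
  sum(stack$count[!is.na(asn) & asn == "mature"]) / total
}

#' Summarize read-stack evidence for the confidence rules
#'
#' Computes every read-derived quantity the classifier consumes. Quantities
#' that are undefined on a degenerate stack (e.g. 5' homogeneity of an arm
#' with no reads) come back as \code{NA} and fail their rule downstream
#' rather than erroring the pipeline.
#'
#' @inheritParams arm_exact_counts
#' @inheritParams excision_fraction
#' @return List of class \code{"evidence_summary"}:
#'   \code{arm_exact_reads_mature}, \code{arm_exact_reads_star},
#'   \code{excision_fraction}, \code{five_prime_homogeneity_mature},
#'   \code{five_prime_homogeneity_star}, \code{libraries_detected},
#'   \code{dominance}.
#' @export
evidence_summary <- function(stack, precursor_seq, mature, star,
                             window_up = 2L, window_down = 5L) {
  soft <- function(expr) tryCatch(expr, mircurate_error = function(e) NA_real_)
  exact <- arm_exact_counts(stack, precursor_seq, mature, star)
  structure(class = "evidence_summary", list(
    arm_exact_reads_mature = unname(exact["mature"]),
    arm_exact_reads_star = unname(exact["star"]),
    excision_fraction = soft(excision_fraction(stack, mature, star, window_up, window_down)),
    five_prime_homogeneity_mature = soft(five_prime_homogeneity(stack, mature, window_up, window_down)),
    five_prime_homogeneity_star = soft(five_prime_homogeneity(stack, star, window_up, window_down)),
    libraries_detected = libraries_detected(stack, mature, window_up, window_down),
    dominance = soft(dominance(stack, mature, star, window_up, window_down))
  ))
}
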