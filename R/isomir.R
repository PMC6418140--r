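#' Detect and type isomiRs on a precursor
#'
#' Pools reads by (start, sequence) across libraries and screens each variant
#' against its reference miRNA (the mature, or the star when the read's 5'
#' end is closer to it). A candidate isomiR must: carry at most one internal
#' mismatch against the precursor (a terminal run of 3' mismatches is treated
#' as a nontemplated tail, not as internal), not be identical to the mature
#' or star read, have pooled count >= \code{min_count}, length within
#' \code{len_range}, and a 5' shift of at most \code{max_shift} positions. It
#' is retained when its pooled count reaches \code{min_frac} of the reference
#' read count, or exceeds \code{min_reads} outright.
#'
#' Typing: a nonzero 5' shift gives \code{5p_deletion} (downstream start) or
#' \code{5p_extension} (upstream start), with any 3' difference recorded as a
#' secondary tag; otherwise a 3' difference gives \code{3p_nontemplated}
#' (tail mismatching the precursor), \code{3p_extension} or
#' \code{3p_deletion}; identical ends with one internal mismatch give
#' \code{polymorphic}. \code{seed_polymorphic} flags internal mismatches in
#' read positions 2-9 (1-based), the seed region.
#'
#' @param stack A [read_stack()].
#' @param prec A [precursor()] (or plain precursor sequence).
#' @param mature Mature interval \code{c(start, end)}.
#' @param star Optional star interval.
#' @param min_count Minimum pooled count to consider a variant (default 100).
#' @param max_shift Maximum |5' shift| in nt (default 4).
#' @param min_frac Retention fraction of the reference count (default 0.5).
#' @param min_reads Absolute retention count overriding \code{min_frac}
#'   (default 10000, strict \code{>}).
#' @param len_range Allowed isomiR lengths (default 18-26 nt).
#' @return data.frame with one row per retained isomiR: \code{sequence},
#'   \code{start}, \code{count}, \code{reference} (mature/star),
#'   \code{shift5p}, \code{type}, \code{tag3p}, \code{seed_polymorphic},
#'   \code{abundance_fraction}.
#' @export
call_isomirs <- function(stack, prec, mature, star = NULL,
                         min_count = 100L, max_shift = 4L,
                         min_frac = 0.5, min_reads = 10000L,
                         len_range = c(18L, 26L)) {
  pseq <- if (inherits(prec, "precursor")) prec$sequence else prec
  mature <- check_interval(mature, nchar(pseq), "mature")
  if (!is.null(star)) star <- check_interval(star, nchar(pseq), "star")

  pooled <- stats::aggregate(count ~ start + sequence, data = as.data.frame(stack),
                             FUN = sum)
  mature_seq <- substr(pseq, mature[1], mature[2])
  ref_count <- function(iv, seq) {
    hit <- pooled$start == iv[1] & pooled$sequence == seq
    if (any(hit)) sum(pooled$count[hit]) else 0L
  }
  mat_ref <- ref_count(mature, mature_seq)
  if (mat_ref == 0L)
    mc_stop("undefined_reference_error",
            "no reads identical to the mature miRNA (reference count 0)")
  star_seq <- if (!is.null(star)) substr(pseq, star[1], star[2]) else NULL
  star_ref <- if (!is.null(star)) ref_count(star, star_seq) else 0L

  empty <- data.frame(sequence = character(0), start = integer(0),
                      count = integer(0), reference = character(0),
                      shift5p = integer(0), type = character(0),
                      tag3p = character(0), seed_polymorphic = logical(0),
                      abundance_fraction = numeric(0), stringsAsFactors = FALSE)
  if (nrow(pooled) == 0L) return(empty)

  rows <- lapply(seq_len(nrow(pooled)), function(i) {
    sq <- pooled$sequence[i]; st <- pooled$start[i]; ct <- pooled$count[i]
    len <- nchar(sq)
    if (st == mature[1] && sq == mature_seq) return(NULL)
    if (!is.null(star) && st == star[1] && identical(sq, star_seq)) return(NULL)
    if (len < len_range[1] || len > len_range[2]) return(NULL)
    if (ct < min_count) return(NULL)
    prof <- read_mismatch_profile(sq, st, pseq)
    if (prof$n_internal > 1L) return(NULL)

    shift_m <- st - mature[1]
    shift_s <- if (!is.null(star)) st - star[1] else NA_integer_
    use_star <- !is.null(star) && !is.na(shift_s) &&
      abs(shift_s) < abs(shift_m)
    shift <- if (use_star) shift_s else shift_m
    ref_iv <- if (use_star) star else mature
    rc <- if (use_star) star_ref else mat_ref
    if (abs(shift) > max_shift) return(NULL)

    frac <- if (rc > 0L) ct / rc else NA_real_
    if (!((!is.na(frac) && frac >= min_frac) || ct > min_reads)) return(NULL)

    read_end <- st + len - 1L
    tag3p <- if (prof$n_trailing3p > 0L) "3p_nontemplated"
             else if (read_end > ref_iv[2]) "3p_extension"
             else if (read_end < ref_iv[2]) "3p_deletion"
             else NA_character_
    type <- if (shift > 0L) "5p_deletion"
            else if (shift < 0L) "5p_extension"
            else if (!is.na(tag3p)) tag3p
            else "polymorphic"
    data.frame(sequence = sq, start = st, count = ct,
               reference = if (use_star) "star" else "mature",
               shift5p = shift, type = type,
               tag3p = if (shift != 0L) tag3p else NA_character_,
               seed_polymorphic = any(prof$internal_positions >= 2L &
                                        prof$internal_positions <= 9L),
               abundance_fraction = frac, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$count, out$start, out$sequence), , drop = FALSE]
}
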