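# Independent reference implementations used to check the package's
# algorithms. These deliberately use different algorithms/representations
# than the code under test.

# Pair table by O(n^2) partner search: for each '(', walk right counting
# depth until the matching ')' (no stack).
oracle_parse_dotbracket <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  pt <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (ch[i] != "(") next
    depth <- 0L
    for (j in i:n) {
      if (ch[j] == "(") depth <- depth + 1L
      if (ch[j] == ")") depth <- depth - 1L
      if (depth == 0L) { pt[i] <- j; pt[j] <- i; break }
    }
  }
  pt
}

# All balanced dot-bracket strings of length n (memoized recursion).
.struct_memo <- new.env(parent = emptyenv())
enumerate_structures <- function(n) {
  key <- as.character(n)
  if (!is.null(.struct_memo[[key]])) return(.struct_memo[[key]])
  out <- if (n == 0L) "" else {
    r <- paste0(".", enumerate_structures(n - 1L))
    if (n >= 2L) for (k in 0:(n - 2L))
      r <- c(r, as.vector(outer(paste0("(", enumerate_structures(k), ")"),
                                enumerate_structures(n - 2L - k), paste0)))
    r
  }
  .struct_memo[[key]] <- out
  out
}

# Duplex profile by explicit column-wise alignment of the two arms: walk the
# mature arm 5'->3' and the star arm 3'->5' between the first and last
# mature/star base pair, emitting pair / mismatch / bulge columns.
oracle_duplex_profile <- function(pt, mature, star) {
  midx <- mature[1]:mature[2]
  duplex <- !is.na(pt[midx]) & pt[midx] >= star[1] & pt[midx] <= star[2]
  mp <- midx[duplex]
  m_lo <- min(mp); m_hi <- max(mp)
  s_lo <- pt[m_hi]; s_hi <- pt[m_lo]
  is_pair <- function(m, s) !is.na(pt[m]) && pt[m] == s
  cols <- character(0)
  m <- m_lo; s <- s_hi
  while (m <= m_hi || s >= s_lo) {
    if (m <= m_hi && s >= s_lo && is_pair(m, s)) {
      cols <- c(cols, "pair"); m <- m + 1L; s <- s - 1L
    } else {
      m_free <- m <= m_hi && !(m %in% mp)
      s_free <- s >= s_lo && !(s %in% pt[mp])
      if (m_free && s_free) { cols <- c(cols, "mm"); m <- m + 1L; s <- s - 1L }
      else if (m_free) { cols <- c(cols, "bm"); m <- m + 1L }
      else if (s_free) { cols <- c(cols, "bs"); s <- s - 1L }
      else stop("oracle walk stuck")
    }
  }
  # bulge runs: maximal stretches of bm / bs columns
  arm <- character(0); size <- integer(0)
  run <- rle(cols)
  for (k in seq_along(run$values)) {
    if (run$values[k] == "bm") { arm <- c(arm, "mature"); size <- c(size, run$lengths[k]) }
    if (run$values[k] == "bs") { arm <- c(arm, "star"); size <- c(size, run$lengths[k]) }
  }
  list(mismatches = sum(cols == "mm"),
       bulges = data.frame(arm = arm, size = size, stringsAsFactors = FALSE),
       overhang_mature_3p = as.integer(mature[2] - m_hi),
       overhang_star_3p = as.integer(star[2] - s_hi),
       paired_fraction_mature = mean(!is.na(pt[midx])),
       paired_fraction_star = mean(!is.na(pt[star[1]:star[2]])))
}

# Literal per-read isomiR predicate: plain string operations, no shared
# helpers with the implementation.
oracle_isomir_call <- function(seq, start, count, pseq, mature, star,
                               mat_ref, star_ref,
                               min_count = 100, max_shift = 4,
                               min_frac = 0.5, min_reads = 10000,
                               len_range = c(18, 26)) {
  len <- nchar(seq)
  mature_seq <- substr(pseq, mature[1], mature[2])
  star_seq <- if (!is.null(star)) substr(pseq, star[1], star[2]) else NULL
  if (start == mature[1] && seq == mature_seq) return(NULL)
  if (!is.null(star) && start == star[1] && seq == star_seq) return(NULL)
  if (len < len_range[1] || len > len_range[2]) return(NULL)
  if (count < min_count) return(NULL)
  # mismatches vs precursor, split into trailing-3' run and internal
  rch <- strsplit(seq, "")[[1]]
  mm <- logical(len)
  for (k in seq_len(len)) {
    p <- start + k - 1
    mm[k] <- p > nchar(pseq) || substr(pseq, p, p) != rch[k]
  }
  trail <- 0
  while (trail < len && mm[len - trail]) trail <- trail + 1
  internal <- which(mm)[which(mm) <= len - trail]
  if (length(internal) > 1) return(NULL)
  sm <- start - mature[1]
  ss <- if (!is.null(star)) start - star[1] else NA
  use_star <- !is.na(ss) && abs(ss) < abs(sm)
  shift <- if (use_star) ss else sm
  if (abs(shift) > max_shift) return(NULL)
  rc <- if (use_star) star_ref else mat_ref
  keep <- (rc > 0 && count / rc >= min_frac) || count > min_reads
  if (!keep) return(NULL)
  ref_end <- if (use_star) star[2] else mature[2]
  rend <- start + len - 1
  t3 <- if (trail > 0) "3p_nontemplated"
        else if (rend > ref_end) "3p_extension"
        else if (rend < ref_end) "3p_deletion" else NA
  type <- if (shift > 0) "5p_deletion" else if (shift < 0) "5p_extension"
          else if (!is.na(t3)) t3 else "polymorphic"
  list(type = type, shift5p = shift,
       reference = if (use_star) "star" else "mature",
       seed_polymorphic = length(internal) == 1 && internal >= 2 && internal <= 9)
}

# rank of a confidence category, for monotonicity checks
category_rank <- function(x)
  match(x, c("rejected", "high_confidence", "very_high_confidence"))
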