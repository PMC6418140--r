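#' QC parameters for raw small-RNA reads
#'
#' Defaults reproduce the published clean-read filters: drop reads with more
#' than 20 percent of bases below Q30, more than 10 percent N bases, near
#' homopolymer composition (polyA/T/C/G, interpreted as one base making up
#' at least \code{homopolymer_fraction} of the read), or trimmed length
#' outside 18-30 nt.
#'
#' @param max_low_quality_fraction Maximum fraction of bases below
#'   \code{q_threshold}.
#' @param q_threshold Phred quality threshold (Sanger encoding, offset 33).
#' @param max_n_fraction Maximum fraction of N bases.
#' @param min_len,max_len Length bounds after adapter trimming.
#' @param homopolymer_fraction Single-base fraction at which a read counts
#'   as a homopolymer.
#' @param adapter 3' adapter sequence (DNA), or \code{NULL} to skip trimming.
#' @return Named list of class \code{"qc_params"}.
#' @export
qc_params <- function(max_low_quality_fraction = 0.20, q_threshold = 30L,
                      max_n_fraction = 0.10, min_len = 18L, max_len = 30L,
                      homopolymer_fraction = 0.9, adapter = NULL) {
  if (min_len > max_len)
    mc_stop("parameter_error", "min_len must be <= max_len")
  structure(list(max_low_quality_fraction = max_low_quality_fraction,
                 q_threshold = q_threshold, max_n_fraction = max_n_fraction,
                 min_len = min_len, max_len = max_len,
                 homopolymer_fraction = homopolymer_fraction,
                 adapter = adapter), class = c("qc_params", "list"))
}

# Trim a 3' adapter: leftmost exact full occurrence, else the longest read
# suffix matching an adapter prefix with >= min_overlap nt.
trim_adapter <- function(seq, adapter, min_overlap = 6L) {
  hit <- regexpr(adapter, seq, fixed = TRUE)
  if (hit > 0L) return(substr(seq, 1L, hit - 1L))
  n <- nchar(seq)
  for (k in min(n, nchar(adapter)):min_overlap) {
    if (k > n) next
    if (substr(seq, n - k + 1L, n) == substr(adapter, 1L, k))
      return(substr(seq, 1L, n - k))
  }
  seq
}

#' Filter raw FASTQ reads into clean reads
#'
#' Removes the 3' adapter (exact match, or a terminal suffix/prefix overlap
#' of at least 6 nt), then applies the clean-read filters in the published
#' order: base quality, N content, homopolymer composition, length. Each
#' removed read is counted under the first filter it triggers.
#'
#' @param fastq Path to a FASTQ file (Sanger qualities), or a data.frame
#'   with columns \code{id}, \code{sequence}, \code{quality}.
#' @param params A [qc_params()] list.
#' @return List with \code{reads} (data.frame \code{id}, \code{sequence},
#'   \code{quality} of retained, trimmed reads) and \code{stats} (input
#'   count, retained count, removals per reason, adapter-trimmed count).
#' @export
read_qc <- function(fastq, params = qc_params()) {
  if (is.character(fastq)) {
    reads <- tryCatch({
      set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
      data.frame(
        id = vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L),
        sequence = as.character(set),
        quality = as.character(Biostrings::quality(set)),
        row.names = NULL, stringsAsFactors = FALSE)
    }, error = function(e)
      mc_stop("format_error", "malformed FASTQ '%s': %s", fastq,
              conditionMessage(e)))
    # byte-based validation: truncated records can come back with garbage
    # (non-ASCII) quality strings rather than a parse error
    if (nrow(reads)) {
      bad <- vapply(seq_len(nrow(reads)), function(i) {
        q <- charToRaw(reads$quality[i])
        length(q) != nchar(reads$sequence[i], type = "bytes") ||
          any(q < as.raw(33L)) || any(q > as.raw(126L))
      }, logical(1))
      if (any(bad))
        mc_stop("format_error", "malformed FASTQ '%s': record %d", fastq,
                which(bad)[1])
    }
  } else reads <- fastq

  reasons <- c("low_quality", "n_bases", "homopolymer", "length")
  removed <- stats::setNames(integer(length(reasons)), reasons)
  n_trimmed <- 0L
  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    sq <- reads$sequence[i]; ql <- reads$quality[i]
    if (!is.null(params$adapter)) {
      trimmed <- trim_adapter(sq, params$adapter)
      if (nchar(trimmed) < nchar(sq)) {
        n_trimmed <- n_trimmed + 1L
        ql <- substr(ql, 1L, nchar(trimmed))
        sq <- trimmed
      }
    }
    reads$sequence[i] <- sq; reads$quality[i] <- ql
    n <- nchar(sq)
    fail <- if (n == 0L) "length"
      else if (mean(utf8ToInt(ql) - 33L < params$q_threshold) >
               params$max_low_quality_fraction) "low_quality"
      else if (mean(seq_chars(sq) == "N") > params$max_n_fraction) "n_bases"
      else if (max(table(seq_chars(sq))) / n >= params$homopolymer_fraction)
        "homopolymer"
      else if (n < params$min_len || n > params$max_len) "length"
      else NA_character_
    if (is.na(fail)) keep[i] <- TRUE else removed[fail] <- removed[fail] + 1L
  }
  list(reads = reads[keep, , drop = FALSE],
       stats = list(input = nrow(reads), retained = sum(keep),
                    removed = removed, adapter_trimmed = n_trimmed))
}

#' Length and first-nucleotide composition of mature miRNAs
#'
#' @param matures Character vector of mature RNA sequences.
#' @return List of class \code{"composition_summary"}:
#'   \code{length_histogram} (named counts by length) and
#'   \code{first_base_matrix} (lengths x \code{A,C,G,U} counts). Row sums of
#'   the matrix equal the histogram.
#' @export
composition_stats <- function(matures) {
  matures <- toupper(gsub("T", "U", matures, fixed = TRUE))
  if (length(matures) == 0L)
    return(structure(list(length_histogram = integer(0),
                          first_base_matrix = matrix(0L, 0, 4,
                            dimnames = list(NULL, RNA_BASES))),
                     class = "composition_summary"))
  len <- nchar(matures)
  first <- substr(matures, 1L, 1L)
  lens <- sort(unique(len))
  hist <- vapply(lens, function(l) sum(len == l), integer(1))
  names(hist) <- lens
  mat <- t(vapply(lens, function(l)
    vapply(RNA_BASES, function(b) sum(len == l & first == b), integer(1)),
    integer(4)))
  dimnames(mat) <- list(lens, RNA_BASES)
  structure(list(length_histogram = hist, first_base_matrix = mat),
            class = "composition_summary")
}
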