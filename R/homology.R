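#' Ungapped distance between two mature miRNA sequences
#'
#' Equal-length sequences are compared position-wise (Hamming distance).
#' When lengths differ by at most \code{max_len_diff} nt, the shorter
#' sequence slides along the longer one and each overhanging base of the
#' longer sequence counts as a mismatch; the minimum over placements is
#' returned. Larger length differences give \code{Inf}.
#'
#' @param a,b RNA sequences (character scalars).
#' @param max_len_diff Maximum tolerated length difference (nt).
#' @return Non-negative distance (possibly \code{Inf}).
#' @export
mature_distance <- function(a, b, max_len_diff = 2L) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  d <- la - lb
  if (d > max_len_diff) return(Inf)
  ca <- seq_chars(a); cb <- seq_chars(b)
  best <- Inf
  for (off in 0:d) {
    ham <- sum(ca[off + seq_len(lb)] != cb)
    best <- min(best, ham + d)
  }
  best
}

#' Match a mature sequence against known miRNAs
#'
#' Scans a miRBase-style set of known mature sequences; a candidate within
#' two mismatches of any known mature is called conserved, otherwise novel.
#' Ties in the best distance go to the first known entry in input order.
#'
#' @param mature_seq Candidate mature RNA sequence.
#' @param known data.frame with columns \code{id} and \code{sequence}
#'   (see [read_known_matures()]), or \code{NULL}/empty for no references.
#' @param max_mm Mismatch allowance for a conserved call (default 2).
#' @return List of class \code{"conservation_call"}: \code{status}
#'   (\code{"conserved"}/\code{"novel"}), \code{best_match_id},
#'   \code{mismatches}, \code{family} (\code{NA}; filled by
#'   [assign_families()]).
#' @export
match_known <- function(mature_seq, known, max_mm = 2L) {
  mature_seq <- toupper(gsub("T", "U", mature_seq, fixed = TRUE))
  best_id <- NA_character_; best_d <- Inf
  if (!is.null(known) && nrow(known)) {
    for (i in seq_len(nrow(known))) {
      d <- mature_distance(mature_seq, known$sequence[i])
      if (d < best_d) { best_d <- d; best_id <- known$id[i] }
    }
  }
  conserved <- is.finite(best_d) && best_d <= max_mm
  structure(class = "conservation_call", list(
    status = if (conserved) "conserved" else "novel",
    best_match_id = if (conserved) best_id else NA_character_,
    mismatches = if (is.finite(best_d)) as.integer(best_d) else NA_integer_,
    family = NA_character_))
}

# "ath-miR156a" -> "MIR156"; falls back to the whole name token.
known_family <- function(id) {
  m <- regmatches(id, regexpr("(?i)mir[0-9]+", id, perl = TRUE))
  if (length(m)) toupper(m) else toupper(id)
}

#' Assign family names to a batch of conservation calls
#'
#' Conserved miRNAs inherit the family of their best miRBase-style match
#' (e.g. a hit to \code{ath-miR156a} yields \code{<prefix>-MIR156}). Novel
#' miRNAs are clustered by single linkage at mature-sequence distance <= 2
#' and families are numbered \code{<prefix>-nMIR001}, ... in order of
#' decreasing total read abundance (ties by the lexicographically smallest
#' member sequence).
#'
#' @param calls data.frame with columns \code{id}, \code{sequence},
#'   \code{status}, \code{best_match_id}.
#' @param abundances Numeric vector of total read counts, parallel to
#'   \code{calls} (defaults to zeros).
#' @param prefix Species prefix for family names.
#' @param max_mm Clustering distance for novel families.
#' @return \code{calls} with a \code{family} column appended.
#' @export
assign_families <- function(calls, abundances = NULL, prefix = "Jcu",
                            max_mm = 2L) {
  n <- nrow(calls)
  if (is.null(abundances)) abundances <- rep(0, n)
  family <- rep(NA_character_, n)
  cons <- which(calls$status == "conserved")
  family[cons] <- paste0(prefix, "-", vapply(calls$best_match_id[cons],
                                             known_family, character(1)))
  nov <- which(calls$status == "novel")
  if (length(nov)) {
    # single-linkage clusters under mature_distance <= max_mm (union-find)
    parent <- seq_along(nov)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (length(nov) > 1L) {
      for (i in seq_len(length(nov) - 1L)) for (j in (i + 1L):length(nov)) {
        if (mature_distance(calls$sequence[nov[i]], calls$sequence[nov[j]]) <= max_mm) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    root <- vapply(seq_along(nov), find, integer(1))
    groups <- split(seq_along(nov), root)
    tot <- vapply(groups, function(g) sum(abundances[nov[g]]), numeric(1))
    key <- vapply(groups, function(g) min(calls$sequence[nov[g]]), character(1))
    ord <- order(-tot, key)
    for (k in seq_along(ord)) {
      g <- groups[[ord[k]]]
      family[nov[g]] <- sprintf("%s-nMIR%03d", prefix, k)
    }
  }
  calls$family <- family
  calls
}

#' Read known mature miRNAs from a miRBase-style FASTA
#'
#' @param path FASTA file of mature sequences; header tokens like
#'   \code{ath-miR156a} carry the family.
#' @return data.frame with columns \code{id}, \code{sequence}.
#' @export
read_known_matures <- function(path) {
  set <- Biostrings::readBStringSet(path)
  data.frame(
    id = vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L),
    sequence = toupper(gsub("T", "U", as.character(set), fixed = TRUE)),
    row.names = NULL, stringsAsFactors = FALSE)
}
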