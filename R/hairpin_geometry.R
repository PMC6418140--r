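#' Candidate precursor hairpin
#'
#' Bundles a candidate miRNA precursor: its RNA sequence, the dot-bracket
#' secondary structure produced by an external folder (e.g. RNAfold), the
#' minimum free energy of that structure, and the number of genome loci the
#' originating small RNA mapped to (used by the multi-hit candidate filter).
#'
#' Coordinates throughout the package are 1-based and closed, the R /
#' Bioconductor convention.
#'
#' @param id Precursor identifier.
#' @param sequence RNA sequence over \code{A,C,G,U} (\code{T} is converted).
#' @param structure Dot-bracket string, same length as \code{sequence}.
#' @param mfe Minimum free energy in kcal/mol; must be <= 0.
#' @param n_genome_hits Number of genome loci for the candidate sRNA (>= 1).
#' @return An object of class \code{"precursor"}: a list with the fields above.
#' @examples
#' p <- precursor("mir-1", "GGGAAACCC", "(((...)))", mfe = -4.2)
#' mfe_per_nt(p)
#' @export
precursor <- function(id, sequence, structure, mfe, n_genome_hits = 1L) {
  sequence <- toupper(gsub("T", "U", sequence, fixed = TRUE))
  if (!grepl("^[ACGUN]*$", sequence))
    mc_stop("parameter_error", "sequence contains non-RNA characters")
  if (nchar(sequence) != nchar(structure))
    mc_stop("parameter_error", "sequence (%d nt) and structure (%d) lengths differ",
            nchar(sequence), nchar(structure))
  if (!is.finite(mfe) || mfe > 0)
    mc_stop("parameter_error", "mfe must be <= 0 kcal/mol, got %s", format(mfe))
  parse_dotbracket(structure)  # validates balance / alphabet
  structure(class = "precursor",
            list(id = as.character(id), sequence = sequence,
                 structure = structure, mfe = as.numeric(mfe),
                 n_genome_hits = as.integer(n_genome_hits)))
}

#' @export
print.precursor <- function(x, ...) {
  cat(sprintf("<precursor %s: %d nt, mfe %.2f kcal/mol (%.3f /nt), %d genome hit(s)>\n",
              x$id, nchar(x$sequence), x$mfe, mfe_per_nt(x), x$n_genome_hits))
  invisible(x)
}

#' Parse a dot-bracket string into a pair table
#'
#' Standard stack parse of a nested (pseudoknot-free) secondary structure.
#'
#' @param structure String over \code{'(' , ')' , '.'}.
#' @return Integer vector \code{pt} with \code{pt[i]} the 1-based partner of
#'   position \code{i}, or \code{NA} if unpaired. Satisfies
#'   \code{pt[pt[i]] == i} for all paired \code{i}.
#' @examples
#' parse_dotbracket("((..))")  # c(6, 5, NA, NA, 2, 1)
#' @export
parse_dotbracket <- function(structure) {
  ch <- seq_chars(structure)
  n <- length(ch)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    c_i <- ch[i]
    if (c_i == "(") {
      stack <- c(stack, i)
    } else if (c_i == ")") {
      if (length(stack) == 0L)
        mc_stop("structure_format_error",
                "unmatched ')' at position %d", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i
      pt[i] <- j
    } else if (c_i != ".") {
      mc_stop("structure_format_error",
              "illegal character '%s' at position %d", c_i, i)
    }
  }
  if (length(stack) > 0L)
    mc_stop("structure_format_error",
            "unmatched '(' at position %d", stack[1])
  pt
}

# Which arm does a mature interval sit on? +1 if partners lie 3' of it
# (5' arm), -1 if 5' of it. Errors if positions pair within the interval
# (the interval spans the loop apex).
arm_direction <- function(pt, iv) {
  idx <- iv[1]:iv[2]
  partners <- pt[idx]
  inside <- !is.na(partners) & partners >= iv[1] & partners <= iv[2]
  if (any(inside))
    mc_stop("not_a_duplex_error",
            "interval [%d,%d] spans the hairpin loop (self-pairing)", iv[1], iv[2])
  paired <- partners[!is.na(partners)]
  if (length(paired) == 0L)
    mc_stop("not_a_duplex_error",
            "interval [%d,%d] has no paired positions", iv[1], iv[2])
  if (all(paired > iv[2])) 1L else if (all(paired < iv[1])) -1L else
    mc_stop("not_a_duplex_error",
            "interval [%d,%d] pairs to both sides (not on a single arm)", iv[1], iv[2])
}

# Nearest paired position starting at i, stepping by `dir`, staying within iv.
scan_paired <- function(pt, i, dir, iv) {
  while (i >= iv[1] && i <= iv[2]) {
    if (!is.na(pt[i])) return(i)
    i <- i + dir
  }
  mc_stop("not_a_duplex_error",
          "no paired anchor position found inside [%d,%d]", iv[1], iv[2])
}

#' Infer star-strand coordinates from the pair table
#'
#' Reads the miRNA* interval off the secondary structure assuming a canonical
#' Dicer duplex with \code{overhang}-nt 3' overhangs: the star 5' end pairs
#' with the mature base \code{overhang} positions in from its 3' end, and the
#' star 3' end extends \code{overhang} nt past the partner of the mature
#' 5' end. When an anchor base is unpaired (a bulge or mismatch at the duplex
#' end) the nearest paired base toward the duplex interior is used instead.
#'
#' @param pt Pair table from [parse_dotbracket()].
#' @param mature Mature interval \code{c(start, end)}, 1-based closed.
#' @param overhang Overhang length in nt (canonical Dicer: 2).
#' @return Star interval \code{c(start, end)}.
#' @export
infer_star_coords <- function(pt, mature, overhang = 2L) {
  mature <- check_interval(mature, length(pt), "mature")
  arm_direction(pt, mature)  # errors if mature spans the loop
  a1 <- scan_paired(pt, mature[2] - overhang, -1L, mature)  # 3'-side anchor
  a2 <- scan_paired(pt, mature[1], +1L, mature)             # 5'-side anchor
  star <- c(pt[a1], pt[a2] + overhang)
  if (star[2] > length(pt))
    mc_stop("truncated_precursor_error",
            "star 3' end (%d) exceeds precursor length (%d)", star[2], length(pt))
  if (star[1] > star[2])
    mc_stop("not_a_duplex_error", "inferred star interval is empty")
  as.integer(star)
}

#' Geometry of a mature/star duplex
#'
#' Walks the duplex between consecutive mature positions that pair into the
#' star interval. In each gap, with \code{a} unpaired mature bases and
#' \code{b} unpaired opposing star bases, \code{min(a, b)} mismatches are
#' accumulated and, when \code{a != b}, one asymmetric bulge of size
#' \code{|a - b|} is recorded on the longer arm. Unpaired terminal bases (the
#' Dicer 3' overhangs) are reported separately and excluded from the
#' mismatch/bulge accounting. Paired fractions count positions paired to
#' anything, per interval.
#'
#' @param pt Pair table.
#' @param mature,star Intervals \code{c(start, end)}, 1-based closed, on
#'   opposite arms.
#' @param sequence Optional precursor sequence (unused by the geometry; kept
#'   for interface symmetry with callers that carry it).
#' @return A list of class \code{"duplex_profile"}: \code{mismatches},
#'   \code{bulges} (data.frame \code{arm}, \code{size}),
#'   \code{overhang_mature_3p}, \code{overhang_star_3p},
#'   \code{paired_fraction_mature}, \code{paired_fraction_star}.
#' @export
duplex_profile <- function(pt, mature, star, sequence = NULL) {
  mature <- check_interval(mature, length(pt), "mature")
  star <- check_interval(star, length(pt), "star")
  if (mature[1] <= star[2] && star[1] <= mature[2])
    mc_stop("invalid_duplex_error",
            "mature [%d,%d] and star [%d,%d] intervals overlap",
            mature[1], mature[2], star[1], star[2])
  midx <- mature[1]:mature[2]
  in_star <- !is.na(pt[midx]) & pt[midx] >= star[1] & pt[midx] <= star[2]
  mp <- midx[in_star]
  if (length(mp) == 0L)
    mc_stop("not_a_duplex_error", "no base pairs between mature and star intervals")

  mismatches <- 0L
  arm <- character(0); size <- integer(0)
  if (length(mp) > 1L) {
    for (k in seq_len(length(mp) - 1L)) {
      a <- mp[k + 1L] - mp[k] - 1L
      b <- abs(pt[mp[k]] - pt[mp[k + 1L]]) - 1L
      mismatches <- mismatches + min(a, b)
      if (a != b) {
        arm <- c(arm, if (a > b) "mature" else "star")
        size <- c(size, abs(a - b))
      }
    }
  }
  sp <- pt[mp]  # star-side partners
  structure(class = "duplex_profile", list(
    mismatches = mismatches,
    bulges = data.frame(arm = arm, size = size, stringsAsFactors = FALSE),
    overhang_mature_3p = as.integer(mature[2] - max(mp)),
    overhang_star_3p = as.integer(star[2] - max(sp)),
    paired_fraction_mature = mean(!is.na(pt[midx])),
    paired_fraction_star = mean(!is.na(pt[star[1]:star[2]]))
  ))
}

#' @export
print.duplex_profile <- function(x, ...) {
  cat(sprintf(
    "<duplex: %d mismatch(es), %d bulge(s), 3' overhangs %d/%d nt, paired %.2f/%.2f>\n",
    x$mismatches, nrow(x$bulges), x$overhang_mature_3p, x$overhang_star_3p,
    x$paired_fraction_mature, x$paired_fraction_star))
  invisible(x)
}

#' Folding free energy per nucleotide
#'
#' The adjusted MFE used by confidence rule 7 (threshold -0.2 kcal/mol/nt).
#'
#' @param p A [precursor()].
#' @return MFE divided by precursor length, kcal/mol/nt.
#' @export
mfe_per_nt <- function(p) {
  n <- nchar(p$sequence)
  if (n == 0L) mc_stop("parameter_error", "zero-length precursor")
  p$mfe / n
}
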