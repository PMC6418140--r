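#' Read candidate precursors
#'
#' Two on-disk forms are supported: a single TSV with columns \code{id},
#' \code{sequence}, \code{structure}, \code{mfe} and optional
#' \code{n_genome_hits}; or a FASTA of sequences plus a 3-line-per-record
#' structure file (\code{>id} / dot-bracket / \code{mfe=<float>}).
#'
#' @param path TSV path, or FASTA path when \code{structure_file} is given.
#' @param structure_file Optional companion structure file for FASTA input.
#' @return List of [precursor()] objects, in file order.
#' @export
read_precursors <- function(path, structure_file = NULL) {
  if (is.null(structure_file)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "sequence", "structure", "mfe")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      mc_stop("format_error", "precursor TSV missing column(s): %s",
              paste(miss, collapse = ", "))
    if (is.null(tab$n_genome_hits)) tab$n_genome_hits <- 1L
    lapply(seq_len(nrow(tab)), function(i)
      precursor(tab$id[i], tab$sequence[i], tab$structure[i], tab$mfe[i],
                tab$n_genome_hits[i]))
  } else {
    seqs <- Biostrings::readBStringSet(path)
    ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    lines <- readLines(structure_file)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) %% 3L != 0L)
      mc_stop("format_error", "structure file is not 3 lines per record")
    recs <- split(lines, rep(seq_len(length(lines) / 3L), each = 3L))
    out <- lapply(recs, function(r) {
      id <- sub("^>", "", strsplit(trimws(r[1]), "\\s+")[[1]][1])
      mfe <- as.numeric(sub("^mfe=", "", trimws(r[3])))
      if (is.na(mfe))
        mc_stop("format_error", "bad mfe line for record '%s'", id)
      k <- match(id, ids)
      if (is.na(k))
        mc_stop("format_error", "structure record '%s' has no FASTA sequence", id)
      precursor(id, as.character(seqs[[k]]), trimws(r[2]), mfe)
    })
    unname(out)
  }
}

#' Read aligned small-RNA stacks from a TSV
#'
#' Canonical columns: \code{precursor_id}, \code{library_id}, \code{start}
#' (1-based on the precursor), \code{sequence}, \code{count}.
#'
#' @param path TSV path.
#' @return Named list of [read_stack()]s, keyed by precursor id.
#' @export
read_stacks <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("precursor_id", "library_id", "start", "sequence", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    mc_stop("format_error", "stack TSV missing column(s): %s",
            paste(miss, collapse = ", "))
  by_prec <- split(tab, tab$precursor_id)
  lapply(by_prec, function(x)
    read_stack(x$precursor_id[1], x[c("library_id", "start", "sequence", "count")]))
}

#' Read a sample sheet
#'
#' Columns: \code{sample_id}, \code{stage}, \code{replicate},
#' \code{genome_mapped_reads}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "replicate", "genome_mapped_reads")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    mc_stop("format_error", "sample sheet missing column(s): %s",
            paste(miss, collapse = ", "))
  tab
}

# Deterministic TSV writer (fixed column order, no quoting surprises).
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
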