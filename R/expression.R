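#' Windowed read counting for one miRNA
#'
#' Sums, per library, counts of reads lying within the mature interval
#' extended by 2 nt upstream and 5 nt downstream, allowing one mismatch
#' against the precursor (the miRDeep2-quantifier convention).
#'
#' @param stack A [read_stack()].
#' @param precursor_seq Precursor sequence.
#' @param mature Mature interval.
#' @param window_up,window_down Window sizes in nt.
#' @param max_mm Maximum mismatches per read (default 1).
#' @param libraries Optional character vector fixing the output order;
#'   libraries absent from the stack report 0.
#' @return Named integer vector of per-library counts.
#' @export
quantify <- function(stack, precursor_seq, mature,
                     window_up = 2L, window_down = 5L, max_mm = 1L,
                     libraries = NULL) {
  if (is.null(libraries))
    libraries <- sort(unique(as.character(stack$library_id)))
  out <- stats::setNames(integer(length(libraries)), libraries)
  if (nrow(stack) == 0L) return(out)
  asn <- assign_arm(stack, mature, NULL, window_up, window_down)
  mm <- stack_mismatch_counts(stack, precursor_seq)
  keep <- !is.na(asn) & mm <= max_mm
  if (any(keep)) {
    agg <- tapply(stack$count[keep], as.character(stack$library_id)[keep], sum)
    hit <- intersect(names(agg), libraries)
    out[hit] <- as.integer(agg[hit])
  }
  out
}

#' TPM normalization against genome-mapped totals
#'
#' \code{tpm[i, s] = counts[i, s] * 1e6 / genome_mapped_reads[s]}. Note the
#' denominator is the sample's genome-mapped read total (as published), not
#' the miRNA-mapped total, so columns do not generally sum to 1e6.
#'
#' @param counts Integer matrix, miRNAs x samples.
#' @param genome_mapped_reads Positive totals, one per sample (recycled by
#'   column name when named).
#' @return Numeric matrix of TPM values.
#' @export
tpm <- function(counts, genome_mapped_reads) {
  counts <- as.matrix(counts)
  g <- genome_mapped_reads
  if (!is.null(names(g)) && !is.null(colnames(counts)))
    g <- g[colnames(counts)]
  if (length(g) != ncol(counts))
    mc_stop("parameter_error", "need one genome-mapped total per sample")
  if (any(!is.finite(g)) || any(g <= 0))
    mc_stop("parameter_error", "genome-mapped read totals must be > 0")
  sweep(counts, 2, g, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' DESeq-style: each sample's factor is the median ratio of its counts to the
#' per-row geometric means, over rows with all-positive counts. When no row
#' is all-positive the factors fall back to total-count ratios. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts miRNAs x samples count matrix.
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    lgm <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2,
                function(col) exp(stats::median(log(col) - lgm)))
  } else {
    tot <- colSums(counts)
    if (any(tot == 0))
      mc_stop("parameter_error", "sample with zero total count")
    sf <- tot
  }
  sf / exp(mean(log(sf)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{padj[i] = min_{j: p(j) >= p(i)} (n * p(j) / rank(j))}, capped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Negative-binomial Wald test between two stages
#'
#' A simplified DESeq2-like test, with no claim of numerical equivalence to
#' DESeq2: counts are normalized by median-of-ratios size factors, a pooled
#' method-of-moments dispersion is estimated per miRNA (floored at 1e-8), and
#' a Wald statistic on the log ratio of group means is referred to a t
#' distribution with \code{nA + nB - 2} degrees of freedom. P-values are
#' BH-adjusted; a miRNA is flagged significant when |log2 fold change| > 1
#' and adjusted p < 0.05.
#'
#' @param counts miRNAs x samples count matrix (raw counts).
#' @param cols_a,cols_b Column indices or names of the two groups (each with
#'   >= 2 replicates); fold changes are B over A.
#' @param sf Optional size factors for all columns of \code{counts}
#'   (computed from the full matrix when omitted).
#' @param lfc_threshold,alpha Significance thresholds.
#' @return data.frame: \code{id}, \code{base_mean_a}, \code{base_mean_b},
#'   \code{log2fc}, \code{dispersion}, \code{p}, \code{padj},
#'   \code{significant}.
#' @export
nb_test <- function(counts, cols_a, cols_b, sf = NULL,
                    lfc_threshold = 1, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- norm[, cols_a, drop = FALSE]
  b <- norm[, cols_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L)
    mc_stop("parameter_error", "each stage needs >= 2 replicates")
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  var_a <- apply(a, 1, stats::var); var_b <- apply(b, 1, stats::var)

  # pooled method-of-moments dispersion: alpha = (s^2 - mu) / mu^2 per group,
  # pooled by within-group df, floored
  disp_g <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  da <- disp_g(var_a, mu_a); db <- disp_g(var_b, mu_b)
  w_a <- ifelse(is.na(da), 0, na - 1L); w_b <- ifelse(is.na(db), 0, nb - 1L)
  disp_num <- ifelse(is.na(da), 0, da) * w_a + ifelse(is.na(db), 0, db) * w_b
  disp <- ifelse(w_a + w_b > 0, disp_num / (w_a + w_b), 0)
  disp <- pmax(disp, 1e-8)

  # zero-mean groups: pseudo-count for a defined log ratio
  zero <- mu_a == 0 | mu_b == 0
  mu_a_t <- ifelse(zero, mu_a + 0.5, mu_a)
  mu_b_t <- ifelse(zero, mu_b + 0.5, mu_b)
  v_a <- (mu_a_t + disp * mu_a_t^2) / (na * mu_a_t^2)  # var of log mean
  v_b <- (mu_b_t + disp * mu_b_t^2) / (nb * mu_b_t^2)
  wald <- (log(mu_b_t) - log(mu_a_t)) / sqrt(v_a + v_b)
  p <- 2 * stats::pt(-abs(wald), df = na + nb - 2L)
  allzero <- mu_a == 0 & mu_b == 0
  p[allzero] <- 1
  log2fc <- log2(mu_b_t / mu_a_t)
  log2fc[allzero] <- 0
  padj <- bh_adjust(p)
  data.frame(
    id = if (!is.null(rownames(counts))) rownames(counts) else
      as.character(seq_len(nrow(counts))),
    base_mean_a = mu_a, base_mean_b = mu_b, log2fc = log2fc,
    dispersion = disp, p = p, padj = padj,
    significant = abs(log2fc) > lfc_threshold & padj < alpha,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression across three developmental stages
#'
#' Runs [nb_test()] on the three pairwise contrasts (intermediate vs young,
#' mature vs intermediate, mature vs young) with size factors estimated once
#' from the full matrix; a miRNA is differentially expressed when significant
#' in at least one contrast.
#'
#' @param counts miRNAs x samples count matrix.
#' @param sample_sheet data.frame with \code{sample_id} and \code{stage}
#'   (values \code{young}, \code{intermediate}, \code{mature}).
#' @param lfc_threshold,alpha Passed to [nb_test()].
#' @return List with \code{contrasts} (named list of [nb_test()] tables for
#'   \code{I_vs_Y}, \code{M_vs_I}, \code{M_vs_Y}) and \code{flags}
#'   (data.frame \code{id}, \code{differentially_expressed}).
#' @export
de_stages <- function(counts, sample_sheet, lfc_threshold = 1, alpha = 0.05) {
  counts <- as.matrix(counts)
  stage_cols <- function(stage) {
    ids <- sample_sheet$sample_id[sample_sheet$stage == stage]
    match(ids, colnames(counts))
  }
  y <- stage_cols("young"); i <- stage_cols("intermediate")
  m <- stage_cols("mature")
  if (anyNA(c(y, i, m)))
    mc_stop("config_error", "sample sheet references samples absent from the count matrix")
  sf <- size_factors(counts)
  contrasts <- list(
    I_vs_Y = nb_test(counts, y, i, sf, lfc_threshold, alpha),
    M_vs_I = nb_test(counts, i, m, sf, lfc_threshold, alpha),
    M_vs_Y = nb_test(counts, y, m, sf, lfc_threshold, alpha))
  sig <- Reduce(`|`, lapply(contrasts, function(x) x$significant))
  list(contrasts = contrasts,
       flags = data.frame(id = contrasts[[1]]$id,
                          differentially_expressed = sig,
                          stringsAsFactors = FALSE))
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in the
#'   case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in the
#'   control sample (e.g. young seeds, 5.8S reference).
#' @return Relative expression \code{2^-((dCt_case) - (dCt_ctrl))}.
#' @examples
#' ddct(25, 20, 24, 20)  # 0.5
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}
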