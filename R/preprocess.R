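#' Sum transcript-level counts to gene level
#'
#' @param transcript_counts Samples x transcripts count matrix.
#' @param tx2gene Data frame with columns `transcript_id`, `gene_id`
#'   (each transcript maps to at most one gene).
#' @return Samples x genes count matrix; transcripts absent from the map
#'   are dropped with a message.
#' @export
sum_transcripts_to_genes <- function(transcript_counts, tx2gene) {
  stopifnot(all(c("transcript_id", "gene_id") %in% names(tx2gene)))
  if (anyDuplicated(tx2gene$transcript_id))
    stop("duplicated transcript rows in tx2gene map")
  tx <- colnames(transcript_counts)
  hit <- match(tx, tx2gene$transcript_id)
  dropped <- sum(is.na(hit))
  if (dropped > 0)
    message(dropped, " transcript(s) without a gene mapping dropped")
  keep <- !is.na(hit)
  genes <- tx2gene$gene_id[hit[keep]]
  out <- t(rowsum(t(transcript_counts[, keep, drop = FALSE]), group = genes))
  out[, unique(genes), drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample normalization for count
#' libraries (computed with edgeR). The reference sample is the one whose
#' 75th-percentile count fraction is closest to the mean; each sample's
#' factor is 2 to the weighted trimmed mean of gene-wise log2 ratios,
#' using genes positive in both libraries, trimming `trim_m` of M values
#' and `trim_a` of A values, with inverse approximate-binomial-variance
#' weights; factors are rescaled to geometric mean 1.
#'
#' @param counts Samples x genes count matrix (>= 2 samples, no all-zero
#'   sample).
#' @param trim_m,trim_a Trim fractions for M and A values.
#' @param a_cutoff Lower cutoff on A values.
#' @return Data frame with `sample_id`, `factor`, `lib_size`,
#'   `eff_lib_size` (= lib_size * factor).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        a_cutoff = -1e10) {
  if (nrow(counts) < 2) stop("TMM requires at least 2 samples")
  lib <- rowSums(counts)
  if (any(lib == 0)) stop("all-zero sample(s): ",
                          paste(rownames(counts)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(t(counts), method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a,
                              Acutoff = a_cutoff)
  data.frame(sample_id = rownames(counts), factor = unname(f),
             lib_size = unname(lib), eff_lib_size = unname(lib * f),
             stringsAsFactors = FALSE)
}

#' Log-CPM transform (variance-stabilizing log of normalized counts)
#'
#' `log2((count + prior) / (lib_size * factor + 1) * 1e6)` — the logCPM
#' used by voom, without its per-observation precision weights (the
#' downstream mixed-model scan is homoscedastic Gaussian).
#'
#' @param counts Samples x genes count matrix.
#' @param factors Output of [tmm_factors()] (or NULL for factor 1).
#' @param prior_count Prior count added to each observation.
#' @return Samples x genes log2-CPM matrix with attribute
#'   `provenance = "raw-logcpm"`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  lib <- rowSums(counts)
  f <- if (is.null(factors)) rep(1, nrow(counts)) else
    factors$factor[match(rownames(counts), factors$sample_id)]
  eff <- lib * f
  out <- log2((counts + prior_count) / (eff + 1) * 1e6)
  attr(out, "provenance") <- "raw-logcpm"
  out
}

#' Flag sex-chromosome aneuploidies from X/Y expression
#'
#' Per-sample X and Y scores are means over the given gene sets; robust
#' z-scores are computed within annotated sex (median/MAD). A female with
#' X-z below `-mad_k` is flagged `X0-like`; a male with X-z above
#' `+mad_k` whose Y score exceeds the female Y median is flagged
#' `XXY-like`. Flagged samples are marked for exclusion from mapping.
#'
#' @param expr Samples x genes log-scale expression.
#' @param covariates Covariate table with annotated `sex`.
#' @param x_gene_ids,y_gene_ids Non-empty X/Y gene sets.
#' @param mad_k Robust z threshold (default 4).
#' @return QC data frame: `sample_id`, `sex`, `x_score`, `y_score`,
#'   `x_z`, `flag` (`ok`/`X0-like`/`XXY-like`), `exclude`.
#' @export
detect_sex_anomalies <- function(expr, covariates, x_gene_ids, y_gene_ids,
                                 mad_k = 4) {
  if (!length(x_gene_ids) || !length(y_gene_ids))
    stop("x_gene_ids and y_gene_ids must be non-empty")
  stopifnot(identical(rownames(expr), covariates$sample_id))
  xs <- rowMeans(expr[, x_gene_ids, drop = FALSE])
  ys <- rowMeans(expr[, y_gene_ids, drop = FALSE])
  sex <- covariates$sex
  xz <- rep(NA_real_, length(xs))
  for (s in unique(sex)) {
    i <- sex == s
    m <- stats::median(xs[i]); md <- stats::mad(xs[i])
    xz[i] <- if (md > 0) (xs[i] - m) / md else 0
  }
  fem_y_med <- stats::median(ys[sex == "F"])
  flag <- rep("ok", length(xs))
  flag[sex == "F" & xz < -mad_k] <- "X0-like"
  flag[sex == "M" & xz > mad_k & ys > fem_y_med] <- "XXY-like"
  data.frame(sample_id = covariates$sample_id, sex = sex,
             x_score = xs, y_score = ys, x_z = xz, flag = flag,
             exclude = flag != "ok", stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample contamination scores from marker genes
#'
#' The contamination score of a sample is the mean of its (log-scale)
#' expression over the marker genes of the contaminating tissue — the
#' Kl/Ttr log-mean of a choroid-plexus check.
#'
#' @param expr Samples x genes log-scale expression.
#' @param marker_gene_ids Marker gene columns.
#' @return Named numeric vector of scores.
#' @export
contamination_scores <- function(expr, marker_gene_ids) {
  stopifnot(length(marker_gene_ids) >= 1,
            all(marker_gene_ids %in% colnames(expr)))
  rowMeans(expr[, marker_gene_ids, drop = FALSE])
}

#' Residualize expression on a covariate
#'
#' Replaces each gene by its OLS residual on an intercept plus the given
#' covariate(s); the result is orthogonal to the covariate per gene.
#' This is how contamination is remediated before scanning.
#'
#' @param expr Samples x genes matrix.
#' @param covariate Numeric vector or matrix aligned with samples.
#' @return Residualized matrix, `provenance = "residualized"`.
#' @export
residualize <- function(expr, covariate) {
  X <- cbind(1, as.matrix(covariate))
  stopifnot(nrow(X) == nrow(expr))
  qx <- qr(X)
  out <- qr.resid(qx, expr)
  dimnames(out) <- dimnames(expr)
  attr(out, "provenance") <- "residualized"
  out
}

#' Correlate two sets of haplotype probabilities across samples
#'
#' Entry (a, b) is the Pearson correlation between the flattened
#' founder-probability vectors (all 8 founders at the common markers) of
#' sample a in set A and sample b in set B — the fingerprint used to pair
#' expression-derived and array-derived genotypes.
#'
#' @param probsA,probsB `founder_probs` objects on compatible maps.
#' @param common_markers Marker ids to use (default: all markers shared
#'   by both sets).
#' @return nA x nB correlation matrix. Zero-variance fingerprints yield
#'   NA entries with a warning.
#' @export
correlate_haplotype_probs <- function(probsA, probsB, common_markers = NULL) {
  mA <- unlist(lapply(probsA, function(a) dimnames(a)[[3]]), use.names = FALSE)
  mB <- unlist(lapply(probsB, function(a) dimnames(a)[[3]]), use.names = FALSE)
  if (is.null(common_markers)) common_markers <- intersect(mA, mB)
  if (!length(common_markers)) stop("no common markers between probability sets")
  FA <- fp_flatten(probsA, common_markers)
  FB <- fp_flatten(probsB, common_markers)
  degen <- c(rownames(FA)[apply(FA, 1, stats::sd) == 0],
             rownames(FB)[apply(FB, 1, stats::sd) == 0])
  if (length(degen))
    warning("zero-variance probability fingerprint for sample(s): ",
            paste(unique(degen), collapse = ", "))
  suppressWarnings(stats::cor(t(FA), t(FB)))
}

#' Resolve sample mix-ups by maximum-correlation assignment
#'
#' Finds the bijection between expression and genotype labels that
#' maximizes total haplotype-probability correlation (Hungarian
#' algorithm), i.e. reassigns expression and genotypes to their best
#' mutual match. Ties are broken in favor of the annotated pairing (a
#' small diagonal bonus), so samples are never reassigned without
#' evidence. Assignments with correlation below `min_accept_r` are
#' reported as low-correlation rather than silently trusted.
#'
#' @param corr_matrix Square correlation matrix (expression x genotype)
#'   with dimnames.
#' @param min_accept_r Acceptance threshold on the assigned correlation.
#' @return An `assignment_result` list: `assignment` data frame
#'   (`expression_id`, `genotype_id`, `r`, `swapped`, `low_correlation`),
#'   `swaps` (the reassigned pairs), `total_r` (optimal total),
#'   `annotated_r` (total along the diagonal).
#' @export
resolve_sample_mixups <- function(corr_matrix, min_accept_r = 0.8) {
  if (nrow(corr_matrix) != ncol(corr_matrix))
    stop("correlation matrix must be square (one expression per genotype)")
  n <- nrow(corr_matrix)
  cm <- corr_matrix
  cm[!is.finite(cm)] <- -1
  # conservative tie-break: prefer the annotated (diagonal) pairing
  diag(cm) <- diag(cm) + 1e-9
  sol <- clue::solve_LSAP(cm - min(cm) + 1, maximum = TRUE)
  j <- as.integer(sol)
  eid <- rownames(corr_matrix); gid <- colnames(corr_matrix)
  r <- corr_matrix[cbind(seq_len(n), j)]
  assignment <- data.frame(
    expression_id = eid, genotype_id = gid[j], r = r,
    swapped = j != seq_len(n), low_correlation = r < min_accept_r,
    stringsAsFactors = FALSE)
  out <- list(assignment = assignment,
              swaps = assignment[assignment$swapped, , drop = FALSE],
              total_r = sum(r),
              annotated_r = sum(diag(corr_matrix)))
  class(out) <- "assignment_result"
  out
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("sample assignment:", nrow(x$assignment), "samples,",
      nrow(x$swaps), "reassigned,",
      sum(x$assignment$low_correlation), "low-correlation\n")
  cat(sprintf("total r (assigned) %.3f vs annotated %.3f\n",
              x$total_r, x$annotated_r))
  invisible(x)
}
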