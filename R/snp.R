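#' Build a strain-distribution-pattern (SDP) table
#'
#' An SDP assigns each of the 8 founders an allele (0/1) at a SNP,
#' encoded as an 8-bit integer (bit j = founder j's allele, founder A =
#' bit 1). Monomorphic patterns (0 and 255) are rejected.
#'
#' @param snp_id Character vector of SNP ids.
#' @param chromosome,position_bp SNP coordinates (1-based bp).
#' @param sdp Integer SDP codes in 1..254.
#' @return Validated SDP data frame.
#' @export
sdp_table <- function(snp_id, chromosome, position_bp, sdp) {
  stopifnot(length(snp_id) == length(sdp))
  if (anyDuplicated(snp_id)) stop("duplicated SNP ids")
  if (any(sdp < 1 | sdp > 254))
    stop("monomorphic or out-of-range SDP (must be in 1..254)")
  data.frame(snp_id = snp_id, chromosome = as.character(chromosome),
             position_bp = position_bp, sdp = as.integer(sdp),
             stringsAsFactors = FALSE)
}

# founder allele vector (length 8, 0/1) for an SDP code
sdp_alleles <- function(sdp) {
  vapply(1:8, function(j) bitwAnd(bitwShiftR(sdp, j - 1L), 1L), integer(1))
}

# Interpolate founder probabilities at an arbitrary bp position on a
# chromosome: linear in bp between the flanking markers (constant beyond
# the ends).
interpolate_probs <- function(probs, chrom, bp) {
  arr <- probs[[chrom]]
  map <- fp_map(probs)
  mbp <- map$position_bp[map$chromosome == chrom]
  if (bp <= mbp[1]) return(arr[, , 1])
  M <- length(mbp)
  if (bp >= mbp[M]) return(arr[, , M])
  i <- findInterval(bp, mbp)
  t <- (bp - mbp[i]) / (mbp[i + 1] - mbp[i])
  (1 - t) * arr[, , i] + t * arr[, , i + 1]
}

#' SNP association scan within a region
#'
#' Collapses founder probabilities into SNP dosages via strain
#' distribution patterns — the dosage of sample i is its interpolated
#' founder-probability vector at the SNP position dotted with the SDP's
#' allele vector — then runs a 1-df GLS scan (same mixed model and LOD as
#' the haplotype scan) over all SNPs in the region.
#'
#' @param y Phenotype vector.
#' @param probs `founder_probs`.
#' @param snp_tab SDP table from [sdp_table()].
#' @param region List/vector with `chromosome`, `start_bp`, `end_bp`
#'   (inclusive).
#' @param covariate_design Covariate design matrix.
#' @param kinship Kinship set/matrix/NULL.
#' @param reml Use REML in the null fit.
#' @return Data frame `snp_id`, `position_bp`, `dosage_var`, `lod`.
#' @export
snp_association <- function(y, probs, snp_tab, region, covariate_design,
                            kinship = NULL, reml = TRUE) {
  ch <- as.character(region$chromosome)
  sel <- snp_tab$chromosome == ch &
    snp_tab$position_bp >= region$start_bp &
    snp_tab$position_bp <= region$end_bp
  snps <- snp_tab[sel, , drop = FALSE]
  if (!nrow(snps))
    return(data.frame(snp_id = character(0), position_bp = numeric(0),
                      dosage_var = numeric(0), lod = numeric(0)))
  Kc <- kinship_for_chrom(kinship, ch)
  dec <- if (is.null(Kc)) NULL else kinship_decomp(Kc)
  X <- as.matrix(covariate_design)
  lod <- dv <- numeric(nrow(snps))
  for (k in seq_len(nrow(snps))) {
    P <- interpolate_probs(probs, ch, snps$position_bp[k])
    d <- drop(P %*% sdp_alleles(snps$sdp[k]))
    dv[k] <- stats::var(d)
    lod[k] <- marker_gls(y, X, matrix(d, ncol = 1), dec, reml = reml)$lod
  }
  data.frame(snp_id = snps$snp_id, position_bp = snps$position_bp,
             dosage_var = dv, lod = lod, stringsAsFactors = FALSE)
}
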