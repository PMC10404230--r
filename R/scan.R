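#' Genome scan by founder-haplotype regression
#'
#' For each trait and each chromosome, fits the covariates-only mixed
#' model against that chromosome's LOCO kinship (polygenic variance
#' fraction estimated once per trait x chromosome and held fixed across
#' markers), then at every marker adds 7 founder-probability columns (the
#' 8th founder is the reference absorbed by the intercept) and computes
#' `LOD = (n/2) * log10(RSS_null / RSS_marker)` on the eigen-rotated,
#' variance-weighted data. With `kinship = NULL` this reduces to the
#' ordinary least-squares haplotype scan.
#'
#' Markers whose probabilities are degenerate (identical across samples)
#' contribute no fittable columns and get LOD 0; they are listed in the
#' `degenerate_markers` attribute.
#'
#' @param y Phenotype vector or samples x traits matrix (rows aligned
#'   with `probs`).
#' @param probs `founder_probs` genotype probabilities.
#' @param covariate_design Full-rank design including intercept.
#' @param kinship A `kinship_set` (LOCO used per chromosome), a single
#'   kinship matrix, or NULL for no polygenic term.
#' @param reml Use REML for the per-chromosome null fits (default TRUE).
#' @return A markers x traits LOD matrix of class `lod_curve`, with the
#'   marker map in attribute `map`.
#' @export
scan_haplotypes <- function(y, probs, covariate_design, kinship = NULL,
                            reml = TRUE) {
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1, dimnames = list(names(y), "trait"))
  n <- nrow(Y)
  stopifnot(n == dim(probs[[1]])[1])
  X <- as.matrix(covariate_design)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank deficient")
  map <- fp_map(probs)
  G <- ncol(Y)
  lod <- matrix(0, fp_n_markers(probs), G,
                dimnames = list(unlist(lapply(probs, function(a) dimnames(a)[[3]]),
                                       use.names = FALSE),
                                colnames(Y)))
  degen <- character(0)
  row0 <- 0
  for (ch in names(probs)) {
    arr <- probs[[ch]]
    M <- dim(arr)[3]
    Kc <- kinship_for_chrom(kinship, ch)
    if (!is.null(Kc)) {
      dec <- kinship_decomp(Kc)
      Xr <- crossprod(dec$U, X)
      Pr <- crossprod(dec$U, matrix(arr, nrow = n))   # n x (8M), rotated
      Yr <- crossprod(dec$U, Y)
    } else {
      dec <- NULL; Xr <- X; Pr <- matrix(arr, nrow = n); Yr <- Y
    }
    # degenerate markers: zero probability variance across samples
    pv <- vapply(seq_len(M), function(m)
      sum(apply(arr[, , m, drop = FALSE], 2, stats::var)), numeric(1))
    degen <- c(degen, dimnames(arr)[[3]][pv < 1e-14])
    for (g in seq_len(G)) {
      yr <- Yr[, g]
      if (!is.null(dec)) {
        nf <- fit_null(Y[, g], X, dec, reml = reml)
        sw <- sqrt(1 / (nf$hsq * dec$lambda + (1 - nf$hsq)))
      } else {
        sw <- rep(1, n)
      }
      Xw <- Xr * sw; yw <- yr * sw
      rss0 <- sum(stats::lm.fit(Xw, yw)$residuals^2)
      for (m in seq_len(M)) {
        Pm <- Pr[, (m - 1) * 8 + (1:7), drop = FALSE] * sw
        rss1 <- sum(.lm.fit(cbind(Xw, Pm), yw)$residuals^2)
        lod[row0 + m, g] <- max(0, n / 2 * log10(rss0 / rss1))
      }
    }
    row0 <- row0 + M
  }
  structure(lod, map = map, class = c("lod_curve", "matrix"),
            degenerate_markers = degen)
}

#' Find LOD peaks above a threshold
#'
#' One peak per chromosome per trait: the marker with the maximum LOD,
#' reported only if its LOD strictly exceeds the threshold; ties are
#' broken toward the smallest bp position.
#'
#' @param lod `lod_curve` from [scan_haplotypes()] (markers x traits).
#' @param map Marker map (default: taken from the scan object).
#' @param threshold LOD threshold; peaks must be strictly greater
#'   (default 7).
#' @return Data frame: `gene_id`, `chromosome`, `peak_marker`, `peak_bp`,
#'   `lod`.
#' @export
find_peaks <- function(lod, map = attr(lod, "map"), threshold = 7.0) {
  stopifnot(!is.null(map))
  idx <- match(rownames(lod), map$marker_id)
  stopifnot(!anyNA(idx))
  chrom <- map$chromosome[idx]
  bp <- map$position_bp[idx]
  out <- list()
  for (g in colnames(lod)) {
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      # map rows are bp-sorted, so which.max lands on the smallest-bp tie
      best <- i[which.max(lod[i, g])]
      if (lod[best, g] > threshold)
        out[[length(out) + 1]] <- data.frame(
          gene_id = g, chromosome = ch,
          peak_marker = rownames(lod)[best], peak_bp = bp[best],
          lod = unname(lod[best, g]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      peak_marker = character(0), peak_bp = integer(0),
                      lod = numeric(0)))
  do.call(rbind, out)
}

#' Classify eQTL peaks as cis or trans
#'
#' A peak is cis iff it lies on the gene's own chromosome and within
#' `window_bp` of the transcription start site, boundary inclusive
#' (exactly `window_bp` away is still cis); everything else, including
#' any peak on another chromosome, is trans.
#'
#' @param peaks Peak table from [find_peaks()].
#' @param gene_annotation Data frame with `gene_id`, `chromosome`,
#'   `tss_bp`.
#' @param window_bp Cis window around the TSS (default 2 Mb).
#' @return The peak table with a `cis_trans` column added.
#' @export
classify_cis_trans <- function(peaks, gene_annotation, window_bp = 2e6) {
  i <- match(peaks$gene_id, gene_annotation$gene_id)
  if (anyNA(i)) stop("peaks reference unannotated gene(s): ",
                     paste(peaks$gene_id[is.na(i)], collapse = ", "))
  same <- peaks$chromosome == gene_annotation$chromosome[i]
  near <- abs(peaks$peak_bp - gene_annotation$tss_bp[i]) <= window_bp
  peaks$cis_trans <- ifelse(same & near, "cis", "trans")
  peaks
}

# Single-marker GLS fit shared by founder effects, SNP association and
# mediation: refits the null at this chromosome's kinship, fixes hsq,
# and returns weighted RSSs, LOD and the locus coefficients.
marker_gls <- function(y, X, locus_cols, dec, reml = TRUE) {
  n <- length(y)
  if (!is.null(dec)) {
    nf <- fit_null(y, X, dec, reml = reml)
    sw <- sqrt(1 / (nf$hsq * dec$lambda + (1 - nf$hsq)))
    Xw <- crossprod(dec$U, X) * sw
    yw <- crossprod(dec$U, y)[, 1] * sw
    Lw <- crossprod(dec$U, locus_cols) * sw
    hsq <- nf$hsq
  } else {
    Xw <- X; yw <- y; Lw <- locus_cols; hsq <- 0
  }
  rss0 <- sum(stats::lm.fit(Xw, yw)$residuals^2)
  fit1 <- stats::lm.fit(cbind(Xw, Lw), yw)
  rss1 <- sum(fit1$residuals^2)
  beta <- fit1$coefficients[ncol(Xw) + seq_len(ncol(Lw))]
  # degenerate null (covariates explain essentially everything, e.g. a
  # mediator equal to the trait): the locus has nothing left to explain
  tss <- sum((yw - mean(yw))^2)
  lod <- if (rss0 <= 1e-8 * tss) 0 else max(0, n / 2 * log10(rss0 / rss1))
  list(lod = lod, rss0 = rss0, rss1 = rss1, beta = beta, hsq = hsq)
}

#' Founder allele effects at a marker
#'
#' GLS coefficients of the 7 non-reference founder-probability columns at
#' the given marker (reference founder fixed at 0), re-expressed as 8
#' mean-centered allele effects for display — the allele-effect panel of
#' a QTL plot.
#'
#' @param peak_marker Marker id.
#' @param y Phenotype vector.
#' @param probs `founder_probs`.
#' @param covariate_design Covariate design matrix.
#' @param kinship Kinship set/matrix/NULL (LOCO selected by the marker's
#'   chromosome).
#' @param reml Use REML in the null fit.
#' @return Named numeric vector of 8 centered allele effects (A..H).
#' @export
founder_effects_at <- function(peak_marker, y, probs, covariate_design,
                               kinship = NULL, reml = TRUE) {
  loc <- fp_find_marker(probs, peak_marker)
  P8 <- fp_at_marker(probs, peak_marker)
  Kc <- kinship_for_chrom(kinship, loc$chromosome)
  dec <- if (is.null(Kc)) NULL else kinship_decomp(Kc)
  r <- marker_gls(y, as.matrix(covariate_design), P8[, 1:7, drop = FALSE], dec,
                  reml = reml)
  beta <- r$beta
  beta[is.na(beta)] <- 0
  eff <- c(beta, 0)
  names(eff) <- founder_codes()
  eff - mean(eff)
}
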