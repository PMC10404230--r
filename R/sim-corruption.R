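#' Convert latent log2 expression to negative-binomial counts
#'
#' Emulates an RNA-seq count matrix from latent log2 abundances: sample
#' library sizes are drawn log-normally with the requested mean and CV;
#' each gene's expected count is the library size times the sample's
#' relative abundance `2^y_g / sum_g 2^y_g`; counts are negative binomial
#' with dispersion `phi` (`phi = 0` degenerates to Poisson).
#'
#' @param latent Samples x genes latent log2 matrix.
#' @param lib_size_mean Mean library size (default 1e7).
#' @param lib_size_cv Coefficient of variation of library sizes.
#' @param nb_dispersion NB dispersion `phi` (variance = mu + phi mu^2).
#' @param seed RNG seed.
#' @return Integer count matrix, samples x genes.
#' @export
latent_to_counts <- function(latent, lib_size_mean = 1e7, lib_size_cv = 0.2,
                             nb_dispersion = 0.05, seed = 1) {
  stopifnot(nb_dispersion >= 0)
  if (lib_size_mean <= 0) stop("library size must be positive")
  set.seed(seed)
  n <- nrow(latent)
  sdlog <- sqrt(log(1 + lib_size_cv^2))
  libs <- stats::rlnorm(n, log(lib_size_mean) - sdlog^2 / 2, sdlog)
  rel <- 2^latent
  rel <- rel / rowSums(rel)
  mu <- rel * libs
  counts <- if (nb_dispersion == 0) {
    matrix(stats::rpois(length(mu), mu), n)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion), n)
  }
  dimnames(counts) <- dimnames(latent)
  counts
}

#' Inject tissue-contamination signal into latent expression
#'
#' Emulates partial contamination by a second tissue (e.g. choroid plexus
#' in striatal dissections): each sample gets a non-negative contamination
#' score `lambda_i ~ |N(0, lambda_sd)|`; designated marker genes
#' (unambiguous markers of the contaminating tissue, playing the role of
#' Kl/Ttr) are shifted by `lambda_i * marker_loading`, and any other gene
#' with a nonzero loading by `lambda_i * loading_g`.
#'
#' @param latent Samples x genes latent matrix.
#' @param marker_gene_ids Columns acting as contamination marker genes.
#' @param lambda_sd SD of the half-normal contamination scores.
#' @param loadings Named per-gene loading vector for non-marker genes
#'   (default: none).
#' @param marker_loading Loading applied to marker genes (default 10:
#'   marker genes of the contaminating tissue are essentially absent in
#'   the target tissue, so even mild contamination shifts them by
#'   several log2 units per unit of contamination score).
#' @param seed RNG seed.
#' @return List with `expression` and the true `lambda` per sample.
#' @export
inject_contamination <- function(latent, marker_gene_ids, lambda_sd = 0.5,
                                 loadings = NULL, marker_loading = 10, seed = 1) {
  stopifnot(all(marker_gene_ids %in% colnames(latent)))
  set.seed(seed)
  lambda <- abs(stats::rnorm(nrow(latent), 0, lambda_sd))
  names(lambda) <- rownames(latent)
  out <- latent
  for (g in marker_gene_ids) out[, g] <- out[, g] + lambda * marker_loading
  if (!is.null(loadings)) {
    loadings <- loadings[setdiff(names(loadings), marker_gene_ids)]
    for (g in names(loadings)[loadings != 0])
      out[, g] <- out[, g] + lambda * loadings[[g]]
  }
  list(expression = out, lambda = lambda)
}

#' Inject sex-chromosome aneuploidy expression shifts
#'
#' X0 females have X-linked expression scaled toward the one-copy level
#' (default -1 in log2 units); partial XXY males gain X dosage
#' (+log2(1.5)) while retaining Y expression. Magnitudes are configurable
#' defaults, not estimates.
#'
#' @param latent Samples x genes latent matrix.
#' @param covariates Covariate table with annotated `sex`.
#' @param x_gene_ids,y_gene_ids X- and Y-linked gene columns.
#' @param anomaly_list Data frame with `sample_id` and `type`
#'   (`"X0"`/`"XXY"`); may be empty.
#' @param x0_shift,xxy_x_shift,xxy_y_shift Log2 shifts applied.
#' @return List with shifted `expression` and the `anomaly_list`.
#' @export
inject_sex_anomalies <- function(latent, covariates, x_gene_ids, y_gene_ids,
                                 anomaly_list, x0_shift = -1,
                                 xxy_x_shift = log2(1.5), xxy_y_shift = 0) {
  out <- latent
  if (nrow(anomaly_list)) {
    stopifnot(all(anomaly_list$sample_id %in% rownames(latent)),
              all(anomaly_list$type %in% c("X0", "XXY")))
    for (k in seq_len(nrow(anomaly_list))) {
      s <- anomaly_list$sample_id[k]
      if (anomaly_list$type[k] == "X0") {
        out[s, x_gene_ids] <- out[s, x_gene_ids] + x0_shift
      } else {
        out[s, x_gene_ids] <- out[s, x_gene_ids] + xxy_x_shift
        out[s, y_gene_ids] <- out[s, y_gene_ids] + xxy_y_shift
      }
    }
  }
  list(expression = out, anomaly_list = anomaly_list)
}

#' Inject sample-label swaps into an expression matrix
#'
#' Applies `n_swaps` disjoint transpositions to the expression sample
#' labels only, emulating plating/labelling mix-ups between RNA-seq and
#' genotyping. Genotype labels are untouched; the returned `pairing` maps
#' each expression label to the genotype identity its row truly carries.
#'
#' @param expression Samples x genes matrix with sample-id rownames.
#' @param n_swaps Number of disjoint transpositions.
#' @param seed RNG seed.
#' @return List: `expression` (rows permuted, labels unchanged),
#'   `pairing` (named vector: expression label -> true genotype id),
#'   `swaps` (data frame of the transposed id pairs).
#' @export
inject_swaps <- function(expression, n_swaps, seed = 1) {
  n <- nrow(expression)
  stopifnot(2 * n_swaps <= n)
  ids <- rownames(expression)
  perm <- seq_len(n)          # perm[i] = row whose data sample i's label shows
  set.seed(seed)
  if (n_swaps > 0) {
    chosen <- sample.int(n, 2 * n_swaps)
    a <- chosen[seq_len(n_swaps)]
    b <- chosen[n_swaps + seq_len(n_swaps)]
    perm[a] <- b
    perm[b] <- a
    swaps <- data.frame(sample_a = ids[a], sample_b = ids[b],
                        stringsAsFactors = FALSE)
  } else {
    swaps <- data.frame(sample_a = character(0), sample_b = character(0))
  }
  out <- expression[perm, , drop = FALSE]
  rownames(out) <- ids
  pairing <- stats::setNames(ids[perm], ids)
  list(expression = out, pairing = pairing, swaps = swaps)
}
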