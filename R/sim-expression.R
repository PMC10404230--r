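#' Draw random gene architectures for simulation
#'
#' Convenience generator for the per-gene ground truth consumed by
#' [simulate_expression()]: a flat data frame with one row per gene and
#' columns `gene_id`, `chromosome`, `tss_bp`, `causal_marker_id` (NA for
#' genes without a local QTL), `qtl_var_frac`, `h2_polygenic`,
#' `sex_effect`, `contamination_loading`, `mediator_of`, `mediator_b`,
#' and the eight centered founder-effect columns `eff_A` ... `eff_H`.
#'
#' Genes with a QTL get their TSS placed at the causal marker, so the
#' cis/trans classifier can be scored against truth directly.
#'
#' @param map Marker map.
#' @param n_genes Number of genes.
#' @param p_qtl Fraction of genes given a causal marker.
#' @param qtl_var_frac Variance fraction of the QTL term for QTL genes.
#' @param h2_polygenic Polygenic (kinship-structured) variance fraction.
#' @param sex_effect_sd SD of per-gene additive sex effects (0 = none).
#' @param contamination_sd SD of per-gene contamination loadings (0 = none).
#' @param seed RNG seed.
#' @return Gene-architecture data frame.
#' @export
simulate_architectures <- function(map, n_genes, p_qtl = 1,
                                   qtl_var_frac = 0.2, h2_polygenic = 0.4,
                                   sex_effect_sd = 0, contamination_sd = 0,
                                   seed = 1) {
  stopifnot(qtl_var_frac + h2_polygenic < 1, qtl_var_frac >= 0, h2_polygenic >= 0)
  set.seed(seed)
  has_qtl <- stats::runif(n_genes) < p_qtl
  ci <- sample.int(nrow(map), n_genes, replace = TRUE)
  eff <- matrix(stats::rnorm(n_genes * 8), n_genes, 8)
  eff <- eff - rowMeans(eff)          # identifiability: effects sum to 0
  colnames(eff) <- paste0("eff_", founder_codes())
  arch <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    chromosome = map$chromosome[ci],
    tss_bp = map$position_bp[ci],
    causal_marker_id = ifelse(has_qtl, map$marker_id[ci], NA_character_),
    qtl_var_frac = ifelse(has_qtl, qtl_var_frac, 0),
    h2_polygenic = h2_polygenic,
    sex_effect = if (sex_effect_sd > 0) stats::rnorm(n_genes, 0, sex_effect_sd) else 0,
    contamination_loading = if (contamination_sd > 0)
      stats::rnorm(n_genes, 0, contamination_sd) else 0,
    mediator_of = NA_character_,
    mediator_b = 0,
    stringsAsFactors = FALSE
  )
  eff[!has_qtl, ] <- 0
  cbind(arch, eff)
}

#' Simulate a covariate table (sex and outbreeding generation)
#'
#' @param n_samples Number of samples.
#' @param generations Generation labels to cycle through.
#' @param seed RNG seed.
#' @return Data frame with `sample_id`, `sex` (`F`/`M`), `generation`.
#' @export
simulate_covariates <- function(n_samples, generations = c("G21", "G22", "G23"),
                                seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    sex = sample(c("F", "M"), n_samples, replace = TRUE),
    generation = sample(generations, n_samples, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Covariate design matrix (intercept + sex + generation dummies)
#'
#' @param covariates Covariate table (`sample_id`, `sex`, `generation`).
#' @return Numeric design matrix with rownames = sample ids.
#' @export
covariate_design <- function(covariates) {
  df <- data.frame(sex = factor(covariates$sex),
                   generation = factor(covariates$generation))
  form <- if (nlevels(df$sex) > 1 && nlevels(df$generation) > 1) ~ sex + generation
          else if (nlevels(df$sex) > 1) ~ sex
          else if (nlevels(df$generation) > 1) ~ generation
          else ~ 1
  X <- stats::model.matrix(form, df)
  rownames(X) <- covariates$sample_id
  X
}

# scale a component to an exact target sample SD; zero components stay zero
scale_to_sd <- function(v, target_sd) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) return(v * 0)
  v / s * target_sd
}

#' Simulate latent log-scale expression with known genetic architecture
#'
#' The generative twin of the mapping model: for each gene,
#' `y_i = sex_i * b_s + gen_i * b_gen + sum_j g_ij * b_j + gamma_i + eps_i`,
#' where `g_ij` are founder probabilities at the gene's causal marker,
#' `gamma ~ MVN(0, sigma_g^2 K)` with `K` the realized kinship of the
#' simulated genomes, and `eps` iid Gaussian noise. The QTL, polygenic and
#' noise components are each rescaled to their exact requested share of
#' the latent variance (`qtl_var_frac`, `h2_polygenic`, and the
#' remainder), so the realized variance decomposition matches the
#' architecture. Total latent SD is `noise_sd`.
#'
#' Mediation chains: a gene with `mediator_of = <gene_id>` receives
#' `mediator_b` times that gene's finished expression added to its own
#' components, creating a complete-mediation path through the named gene.
#'
#' @param probs `founder_probs` genomes.
#' @param architectures Gene-architecture data frame
#'   ([simulate_architectures()]).
#' @param covariates Covariate table aligned with the samples.
#' @param noise_sd Total latent SD per gene (default 1).
#' @param seed RNG seed.
#' @return List with `expression` (samples x genes matrix) and `truth`, a
#'   `sim_truth` list recording architectures, the kinship used, sample
#'   pairing, and slots for later corruption records.
#' @export
simulate_expression <- function(probs, architectures, covariates,
                                noise_sd = 1, seed = 1) {
  stopifnot(identical(fp_samples(probs), covariates$sample_id))
  bad <- architectures$qtl_var_frac + architectures$h2_polygenic >= 1
  if (any(bad)) stop("qtl_var_frac + h2_polygenic must be < 1")
  known <- unlist(lapply(probs, function(a) dimnames(a)[[3]]))
  cm <- architectures$causal_marker_id
  if (any(!is.na(cm) & !(cm %in% known)))
    stop("architecture references unknown marker(s): ",
         paste(setdiff(cm[!is.na(cm)], known), collapse = ", "))

  set.seed(seed)
  n <- length(fp_samples(probs))
  G <- nrow(architectures)
  K <- kinship_from_probs(probs, loco = FALSE)$overall
  L <- NULL
  if (any(architectures$h2_polygenic > 0)) {
    eg <- eigen(K, symmetric = TRUE)
    L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  }

  sexM <- as.numeric(covariates$sex == "M")
  gen_f <- factor(covariates$generation)
  gen_cols <- paste0("gen_eff_", levels(gen_f))
  has_gen <- all(gen_cols %in% names(architectures))

  effm <- as.matrix(architectures[, paste0("eff_", founder_codes())])
  Y <- matrix(0, n, G, dimnames = list(fp_samples(probs), architectures$gene_id))
  for (g in seq_len(G)) {
    vq <- architectures$qtl_var_frac[g]
    h2 <- architectures$h2_polygenic[g]
    q <- if (!is.na(cm[g]) && vq > 0)
      scale_to_sd(drop(fp_at_marker(probs, cm[g]) %*% effm[g, ]), noise_sd * sqrt(vq))
    else 0
    gam <- if (h2 > 0) scale_to_sd(drop(L %*% stats::rnorm(n)), noise_sd * sqrt(h2)) else 0
    eps <- scale_to_sd(stats::rnorm(n), noise_sd * sqrt(max(1 - vq - h2, 0)))
    y <- q + gam + eps + sexM * architectures$sex_effect[g]
    if (has_gen)
      y <- y + as.matrix(architectures[g, gen_cols])[1, as.integer(gen_f)]
    Y[, g] <- y
  }
  # mediation chains: add the finished mediator signal into its target
  med <- which(!is.na(architectures$mediator_of))
  for (g in med) {
    z <- architectures$mediator_of[g]
    if (!z %in% colnames(Y)) stop("mediator_of references unknown gene: ", z)
    Y[, g] <- Y[, g] + architectures$mediator_b[g] * Y[, z]
  }
  truth <- list(architectures = architectures, kinship = K,
                pairing = stats::setNames(fp_samples(probs), fp_samples(probs)),
                swaps = NULL, aneuploidy = NULL, lambda = NULL, seed = seed)
  class(truth) <- "sim_truth"
  list(expression = Y, truth = truth)
}
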