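# End-to-end synthetic pipeline: simulate -> corrupt -> counts ->
# preprocess -> QC -> mixup repair -> scan -> peaks -> mediation ->
# networks -> bundle. Every stage is a thin call into the module
# functions; the pipeline exists so the whole chain can be run (and
# re-run byte-identically) from one seed.

fp_subset <- function(probs, ids) {
  out <- lapply(probs, function(a) a[ids, , , drop = FALSE])
  structure(out, map = attr(probs, "map"), class = c("founder_probs", "list"))
}

fp_permute <- function(probs, perm) {
  ids <- fp_samples(probs)
  out <- lapply(probs, function(a) {
    b <- a[perm, , , drop = FALSE]
    dimnames(b)[[1]] <- ids
    b
  })
  structure(out, map = attr(probs, "map"), class = c("founder_probs", "list"))
}

#' Repair sample labels according to an assignment
#'
#' Reassigns expression rows to the genotype identities chosen by
#' [resolve_sample_mixups()], so downstream stages see correctly paired
#' data.
#'
#' @param expression Samples x genes matrix (expression labels).
#' @param assignment `assignment_result` object.
#' @return Matrix with rows relabelled/reordered to genotype ids.
#' @export
apply_assignment <- function(expression, assignment) {
  a <- assignment$assignment
  out <- expression[a$expression_id, , drop = FALSE]
  rownames(out) <- a$genotype_id
  out[sort(rownames(out)), , drop = FALSE]
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a mosaic population with known truth, corrupts it
#' (contamination, sex-chromosome aneuploidies, sample swaps), converts
#' to counts, and runs the complete analysis: TMM + logCPM,
#' aneuploidy flagging and exclusion, contamination residualization,
#' sample-mixup resolution and repair, LOCO-kinship haplotype scans, LOD
#' peaks with cis/trans labels and founder effects, a mediation analysis
#' of the planted mediation chain, soft-threshold selection, module
#' detection and paraclique extraction, and finally a validated analysis
#' bundle plus TSV sidecar outputs under `outdir`.
#'
#' @param config Configuration from [default_config()].
#' @param outdir Output directory.
#' @return Invisible list of all in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- config$seed

  ## ---- simulate ----
  map <- make_marker_map(config$n_chromosomes, config$chrom_length_mb,
                         config$markers_per_chromosome)
  probs <- simulate_founder_mosaics(map, config$n_samples,
                                    config$crossover_density,
                                    config$prob_blur_alpha, seed = seed)
  covar <- simulate_covariates(config$n_samples, seed = seed + 1)
  arch <- simulate_architectures(map, config$n_genes, p_qtl = config$p_qtl,
                                 qtl_var_frac = config$qtl_var_frac,
                                 h2_polygenic = config$h2_polygenic,
                                 contamination_sd = 0.3, seed = seed + 2)
  # plant one complete mediation chain among the QTL genes
  qtl_genes <- which(!is.na(arch$causal_marker_id))
  if (length(qtl_genes) >= 2) {
    z <- qtl_genes[1]; tgt <- qtl_genes[2]
    arch$causal_marker_id[tgt] <- NA
    arch$qtl_var_frac[tgt] <- 0
    arch[tgt, paste0("eff_", founder_codes())] <- 0
    arch$mediator_of[tgt] <- arch$gene_id[z]
    arch$mediator_b[tgt] <- 0.8
  }
  # sex-linked sentinel genes: a block of X genes and of Y genes (scores
  # average over a whole-chromosome block, so the block must be sizeable)
  n_x <- 100; n_y <- 20
  sex_arch <- arch[rep(1, n_x + n_y), ]
  sex_arch$gene_id <- c(sprintf("XG%03d", 1:n_x), sprintf("YG%03d", 1:n_y))
  sex_arch$chromosome <- rep(c("X", "Y"), c(n_x, n_y))
  sex_arch$tss_bp <- seq_len(n_x + n_y) * 1e6
  sex_arch$causal_marker_id <- NA
  sex_arch$qtl_var_frac <- 0
  sex_arch$h2_polygenic <- 0
  sex_arch[, paste0("eff_", founder_codes())] <- 0
  sex_arch$contamination_loading <- 0
  sex_arch$mediator_of <- NA
  sex_arch$sex_effect <- rep(c(-0.3, 3), c(n_x, n_y))
  # contamination marker genes (the Kl/Ttr role)
  cont_arch <- sex_arch[1:2, ]
  cont_arch$gene_id <- c("CPM1", "CPM2")
  cont_arch$chromosome <- "1"
  cont_arch$sex_effect <- 0
  # filler transcriptome: pure-noise genes that are counted but not
  # scanned, so sentinel blocks stay a realistically small fraction of
  # the library mass
  n_fill <- if (is.null(config$n_filler_genes)) 400 else config$n_filler_genes
  fill_arch <- cont_arch[rep(1, n_fill), ]
  fill_arch$gene_id <- sprintf("FG%04d", seq_len(n_fill))
  arch_all <- rbind(arch, sex_arch, cont_arch, fill_arch)

  sim <- simulate_expression(probs, arch_all, covar, seed = seed + 3)
  x_genes <- sex_arch$gene_id[1:n_x]
  y_genes <- sex_arch$gene_id[n_x + 1:n_y]
  cont_genes <- cont_arch$gene_id

  ## ---- corrupt ----
  loadings <- stats::setNames(arch$contamination_loading, arch$gene_id)
  cont <- inject_contamination(sim$expression, cont_genes, lambda_sd = 0.5,
                               loadings = loadings, seed = seed + 4)
  females <- covar$sample_id[covar$sex == "F"]
  males <- covar$sample_id[covar$sex == "M"]
  anomalies <- data.frame(sample_id = c(females[1], males[1]),
                          type = c("X0", "XXY"), stringsAsFactors = FALSE)
  anom <- inject_sex_anomalies(cont$expression, covar, x_genes, y_genes,
                               anomalies)
  swapped <- inject_swaps(anom$expression, n_swaps = 4, seed = seed + 5)
  truth <- sim$truth
  truth$lambda <- cont$lambda
  truth$aneuploidy <- anomalies
  truth$swaps <- swapped$swaps
  truth$pairing <- swapped$pairing
  counts <- latent_to_counts(swapped$expression, seed = seed + 6)

  ## ---- preprocess ----
  factors <- tmm_factors(counts)
  logcpm <- log_cpm(counts, factors)
  # expression-side haplotype fingerprints carry the same label swaps
  perm <- match(swapped$pairing, fp_samples(probs))
  probs_expr <- fp_permute(simulate_founder_mosaics(
    map, config$n_samples, config$crossover_density,
    prob_blur_alpha = 0.1, seed = seed), perm)
  hap_cor <- correlate_haplotype_probs(probs_expr, probs)
  assignment <- resolve_sample_mixups(hap_cor, config$min_accept_r)
  logcpm <- apply_assignment(logcpm, assignment)
  # remediate contamination before QC: the marker-gene load otherwise
  # shifts whole-library composition and masks the X/Y dosage signal
  c_scores <- contamination_scores(logcpm, cont_genes)
  resid_expr <- residualize(logcpm, c_scores)
  qc <- detect_sex_anomalies(resid_expr, covar, x_genes, y_genes)
  keep <- qc$sample_id[!qc$exclude]
  expr <- resid_expr[keep, arch$gene_id, drop = FALSE]
  probs_kept <- fp_subset(probs, keep)
  covar_kept <- covar[covar$sample_id %in% keep, , drop = FALSE]
  X <- covariate_design(covar_kept)

  ## ---- map ----
  kinship <- kinship_from_probs(probs_kept, loco = TRUE)
  lod <- scan_haplotypes(expr, probs_kept, X, kinship)
  peaks <- find_peaks(lod, map, config$lod_threshold)
  annot <- data.frame(gene_id = arch_all$gene_id, symbol = arch_all$gene_id,
                      chromosome = arch_all$chromosome,
                      tss_bp = arch_all$tss_bp, strand = "+",
                      stringsAsFactors = FALSE)
  peaks <- classify_cis_trans(peaks, annot, config$cis_window_bp)
  if (nrow(peaks)) {
    eff <- t(vapply(seq_len(nrow(peaks)), function(i)
      founder_effects_at(peaks$peak_marker[i], expr[, peaks$gene_id[i]],
                         probs_kept, X, kinship), numeric(8)))
    colnames(eff) <- paste0("eff_", founder_codes())
    peaks <- cbind(peaks, eff)
  }
  h2 <- heritability(expr, X, kinship$overall)

  ## ---- mediation of the planted chain ----
  mediation <- NULL
  tgt_id <- arch$gene_id[!is.na(arch$mediator_of)]
  if (length(tgt_id)) {
    tgt_id <- tgt_id[1]
    z_id <- arch$mediator_of[arch$gene_id == tgt_id]
    pk <- arch$causal_marker_id[arch$gene_id == z_id]
    med_pool <- setdiff(arch$gene_id, tgt_id)
    mediation <- mediate(expr[, tgt_id], pk, expr[, med_pool, drop = FALSE],
                         probs_kept, X, kinship)
  }

  ## ---- co-expression ----
  corr <- bicor_matrix(expr)
  sft <- pick_soft_threshold(expr, config$soft_powers, config$r2_target,
                             corr = corr)
  net_power <- if (is.na(sft$selected_power)) max(config$soft_powers) else
    sft$selected_power
  modules <- detect_modules(expr, net_power, config$min_module_size,
                            config$cut_height, corr = corr)
  paracliques <- paraclique_extract(corr, config$paraclique_threshold,
                                    config$min_seed, config$min_size,
                                    config$glom)

  ## ---- write ----
  sets <- export_gene_sets(peaks)
  if (length(sets)) write_gene_sets(sets, file.path(outdir, "gene_sets.gmt"))
  write_peaks(peaks, file.path(outdir, "peaks.tsv"))
  write_table_tsv(qc, file.path(outdir, "qc_report.tsv"))
  write_table_tsv(assignment$assignment, file.path(outdir, "assignment.tsv"))
  write_table_tsv(data.frame(gene_id = names(h2), hsq = unname(h2)),
                  file.path(outdir, "heritability.tsv"))
  if (!is.null(mediation))
    write_table_tsv(mediation$rows, file.path(outdir, "mediation.tsv"))
  write_table_tsv(sft$report, file.path(outdir, "soft_threshold.tsv"))
  write_table_tsv(data.frame(gene_id = names(modules), module = unname(modules)),
                  file.path(outdir, "modules.tsv"))
  if (length(paracliques)) {
    pq <- do.call(rbind, lapply(seq_along(paracliques), function(i)
      data.frame(paraclique = i, size = paracliques[[i]]$size,
                 density = paracliques[[i]]$density,
                 members = paste(paracliques[[i]]$members, collapse = ","))))
    write_table_tsv(pq, file.path(outdir, "paracliques.tsv"))
  }
  write_config(config, file.path(outdir, "config.json"))
  assemble_bundle(file.path(outdir, "bundle"), probs_kept, kinship, map,
                  expr, covar_kept, annot, peaks, config)

  invisible(list(map = map, probs = probs, covariates = covar,
                 architectures = arch_all, truth = truth, counts = counts,
                 qc = qc, assignment = assignment, expression = expr,
                 kinship = kinship, lod = lod, peaks = peaks,
                 heritability = h2, mediation = mediation, corr = corr,
                 soft_threshold = sft, modules = modules,
                 paracliques = paracliques))
}
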