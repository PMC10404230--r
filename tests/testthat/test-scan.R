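scan_sim <- function(n_genes = 5, vq = 0.25, h2 = 0.3, seed = 81) {
  fx <- fix_small()
  arch <- simulate_architectures(fx$map, n_genes, p_qtl = 1, qtl_var_frac = vq,
                                 h2_polygenic = h2, seed = seed)
  sim <- simulate_expression(fx$probs, arch, fx$covar, seed = seed + 1)
  c(fx, list(arch = arch, Y = sim$expression))
}

test_that("the no-kinship scan equals the closed-form OLS LOD oracle", {
  s <- scan_sim(3)
  lod <- scan_haplotypes(s$Y[, 1:3], s$probs, s$X, kinship = NULL)
  for (g in 1:3)
    expect_equal(unname(lod[, g]), unname(ols_lod_oracle(s$Y[, g], s$probs, s$X)),
                 tolerance = 1e-8)
})

test_that("identity kinship reproduces the no-kinship scan", {
  s <- scan_sim(2)
  lod0 <- scan_haplotypes(s$Y[, 1:2], s$probs, s$X, kinship = NULL)
  lodI <- scan_haplotypes(s$Y[, 1:2], s$probs, s$X, kinship = diag(100))
  expect_equal(unclass(lodI)[,], unclass(lod0)[,], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("LOD is invariant under affine transforms of the phenotype", {
  s <- scan_sim(1)
  y <- s$Y[, 1]
  l1 <- scan_haplotypes(y, s$probs, s$X, s$kinship)
  l2 <- scan_haplotypes(-2.5 * y + 7, s$probs, s$X, s$kinship)
  expect_equal(unclass(l1)[,], unclass(l2)[,], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("simulated cis genes peak at or adjacent to the causal marker", {
  fx <- fix_big()
  arch <- simulate_architectures(fx$map, 12, p_qtl = 1, qtl_var_frac = 0.2,
                                 h2_polygenic = 0.4, seed = 82)
  sim <- simulate_expression(fx$probs, arch, fx$covar, seed = 83)
  lod <- scan_haplotypes(sim$expression, fx$probs, fx$X, fx$kinship)
  pk <- find_peaks(lod, fx$map, threshold = 7)
  hits <- 0
  for (g in seq_len(12)) {
    p <- pk[pk$gene_id == arch$gene_id[g] &
              pk$chromosome == arch$chromosome[g], ]
    if (nrow(p) == 1) {
      d <- abs(match(p$peak_marker, fx$map$marker_id) -
                 match(arch$causal_marker_id[g], fx$map$marker_id))
      if (d <= 1) hits <- hits + 1
    }
  }
  expect_gte(hits, 10)
})

test_that("peak calling applies the strict threshold and per-chromosome argmax", {
  fx <- fix_small()
  M <- fp_n_markers(fx$probs)
  lod <- matrix(0, M, 1, dimnames = list(fx$map$marker_id, "g"))
  class(lod) <- c("lod_curve", "matrix")
  attr(lod, "map") <- fx$map
  expect_equal(nrow(find_peaks(lod)), 0)        # all-zero curve
  lod[5, 1] <- 7.0
  expect_equal(nrow(find_peaks(lod)), 0)        # exactly 7 is not > 7
  lod[5, 1] <- 7.01
  lod[30, 1] <- 9.2                              # second chromosome
  pk <- find_peaks(lod)
  expect_equal(nrow(pk), 2)
  # brute-force per-chromosome max oracle
  for (ch in unique(fx$map$chromosome)) {
    rows <- fx$map$marker_id[fx$map$chromosome == ch]
    mx <- max(lod[rows, 1])
    if (mx > 7)
      expect_equal(pk$lod[pk$chromosome == ch], mx)
  }
  # tie broken toward the smallest bp
  lod[31, 1] <- 9.2
  expect_equal(find_peaks(lod)$peak_marker[2], fx$map$marker_id[30])
})

test_that("cis/trans classification applies the inclusive 2 Mb TSS rule", {
  ann <- data.frame(gene_id = c("a", "b", "c", "d"),
                    chromosome = c("1", "1", "1", "2"),
                    tss_bp = c(10e6, 10e6, 10e6, 5e6))
  pk <- data.frame(gene_id = c("a", "b", "c", "d"), chromosome = "1",
                   peak_marker = "m", peak_bp = c(10.5e6, 12e6, 12000001, 5e6),
                   lod = 10)
  out <- classify_cis_trans(pk, ann)
  expect_equal(out$cis_trans, c("cis", "cis", "trans", "trans"))
  expect_error(classify_cis_trans(data.frame(gene_id = "zz", chromosome = "1",
                                             peak_bp = 1, lod = 8), ann),
               "unannotated")
})

test_that("founder effects are recovered and respect the model symmetries", {
  fx <- fix_big()
  arch <- simulate_architectures(fx$map, 8, p_qtl = 1, qtl_var_frac = 0.25,
                                 h2_polygenic = 0.3, seed = 84)
  sim <- simulate_expression(fx$probs, arch, fx$covar, seed = 85)
  effm <- as.matrix(arch[, paste0("eff_", names(do_founders()))])
  rs <- vapply(1:8, function(g)
    cor(founder_effects_at(arch$causal_marker_id[g], sim$expression[, g],
                           fx$probs, fx$X, fx$kinship),
        effm[g, ]), numeric(1))
  expect_gt(median(rs), 0.9)
  # a null gene has effects within noise of zero
  null_arch <- simulate_architectures(fx$map, 1, p_qtl = 0, h2_polygenic = 0,
                                      seed = 86)
  null_sim <- simulate_expression(fx$probs, null_arch, fx$covar, seed = 87)
  eff0 <- founder_effects_at(fx$map$marker_id[10], null_sim$expression[, 1],
                             fx$probs, fx$X, fx$kinship)
  expect_lt(max(abs(eff0)), 0.5)
  expect_equal(sum(eff0), 0, tolerance = 1e-10)   # centered
})

test_that("permuting founder columns permutes the allele effects identically", {
  fx <- fix_small()
  s <- scan_sim(1, vq = 0.4, h2 = 0, seed = 88)
  mk <- s$arch$causal_marker_id[1]
  eff <- founder_effects_at(mk, s$Y[, 1], s$probs, s$X, kinship = NULL)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  probs_perm <- lapply(s$probs, function(a) {
    b <- a[, perm, , drop = FALSE]
    dimnames(b)[[2]] <- names(do_founders())
    b
  })
  probs_perm <- structure(probs_perm, map = s$map, class = class(s$probs))
  eff_perm <- founder_effects_at(mk, s$Y[, 1], probs_perm, s$X, kinship = NULL)
  expect_equal(unname(eff_perm), unname(eff[perm]), tolerance = 1e-8)
})

test_that("null scans keep LOD near zero on average with few false peaks", {
  fx <- fix_small()
  arch <- simulate_architectures(fx$map, 30, p_qtl = 0, h2_polygenic = 0,
                                 seed = 89)
  sim <- simulate_expression(fx$probs, arch, fx$covar, seed = 90)
  lod <- scan_haplotypes(sim$expression, fx$probs, fx$X, kinship = NULL)
  expect_lt(mean(lod), 2)
  expect_lte(nrow(find_peaks(lod, fx$map, 7)) / 30, 0.2)
})
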