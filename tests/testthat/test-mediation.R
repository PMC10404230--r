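# one complete-mediation chain plus decoys, built on the big fixture
mediation_fixture <- function() fixture("mediation", function() {
  fx <- fix_big()
  arch <- simulate_architectures(fx$map, 12, p_qtl = 1, qtl_var_frac = 0.3,
                                 h2_polygenic = 0.2, seed = 95)
  # gene 1 = mediator with the QTL; gene 2 = target, complete mediation
  arch$causal_marker_id[2] <- NA
  arch$qtl_var_frac[2] <- 0
  arch[2, paste0("eff_", names(do_founders()))] <- 0
  arch$h2_polygenic[2] <- 0
  arch$mediator_of[2] <- arch$gene_id[1]
  arch$mediator_b[2] <- 0.9
  # genes 3..12 act as decoys
  sim <- simulate_expression(fx$probs, arch, fx$covar, seed = 96)
  c(fx, list(arch = arch, Y = sim$expression))
})

test_that("the true mediator produces the dominant LOD drop", {
  f <- mediation_fixture()
  tgt <- f$arch$gene_id[2]; zid <- f$arch$gene_id[1]
  pk <- f$arch$causal_marker_id[1]
  res <- mediate(f$Y[, tgt], pk, f$Y[, setdiff(colnames(f$Y), tgt)],
                 f$probs, f$X, f$kinship)
  expect_gt(res$baseline_lod, 10)
  expect_equal(res$rows$mediator[1], zid)
  expect_gt(res$rows$lod_drop[1], 0.9 * res$baseline_lod -
              res$rows$lod_drop[2])   # dominant drop
  # decoys barely move the LOD
  expect_lt(median(abs(res$rows$lod_drop[-1])), 1)
})

test_that("conditioning on the target itself collapses the LOD", {
  f <- mediation_fixture()
  tgt <- f$arch$gene_id[2]
  res <- mediate(f$Y[, tgt], f$arch$causal_marker_id[1],
                 f$Y[, tgt, drop = FALSE], f$probs, f$X, f$kinship)
  expect_lt(res$rows$conditioned_lod[1], 0.5)
})

test_that("an orthogonal mediator changes the LOD by less than 0.5 in median", {
  f <- mediation_fixture()
  tgt <- f$arch$gene_id[2]
  set.seed(97)
  noise <- matrix(rnorm(400 * 15), 400, 15,
                  dimnames = list(rownames(f$Y), sprintf("noise%02d", 1:15)))
  res <- mediate(f$Y[, tgt], f$arch$causal_marker_id[1], noise,
                 f$probs, f$X, f$kinship)
  expect_lt(median(abs(res$rows$lod_drop)), 0.5)
})

test_that("mediation is deterministic and flags collinear mediators", {
  f <- mediation_fixture()
  tgt <- f$arch$gene_id[2]
  meds <- cbind(f$Y[, f$arch$gene_id[3], drop = FALSE],
                bad = f$X[, 2])   # duplicate of a covariate column
  r1 <- mediate(f$Y[, tgt], f$arch$causal_marker_id[1], meds, f$probs,
                f$X, f$kinship)
  r2 <- mediate(f$Y[, tgt], f$arch$causal_marker_id[1], meds, f$probs,
                f$X, f$kinship)
  expect_identical(r1$rows, r2$rows)
  expect_true(r1$rows$collinear[r1$rows$mediator == "bad"])
  expect_true(is.na(r1$rows$conditioned_lod[r1$rows$mediator == "bad"]))
})

test_that("the positional mediator filter keeps only local candidates", {
  f <- mediation_fixture()
  tgt <- f$arch$gene_id[2]
  pk <- f$arch$causal_marker_id[1]
  loc <- mosaiceqtl:::fp_find_marker(f$probs, pk)
  ann <- data.frame(gene_id = f$arch$gene_id, chromosome = f$arch$chromosome,
                    tss_bp = f$arch$tss_bp)
  res <- mediate(f$Y[, tgt], pk, f$Y[, setdiff(colnames(f$Y), tgt)],
                 f$probs, f$X, f$kinship, mediator_annot = ann,
                 window_bp = 10e6)
  keep <- ann$gene_id[ann$chromosome == loc$chromosome &
                        abs(ann$tss_bp - loc$bp) <= 10e6 &
                        ann$gene_id != tgt]
  expect_setequal(res$rows$mediator, keep)
})
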