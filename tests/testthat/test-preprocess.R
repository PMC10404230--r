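test_that("transcript-to-gene summation matches an independent group-by oracle", {
  set.seed(31)
  tx <- matrix(rpois(8 * 50, 20), 8, 50,
               dimnames = list(sprintf("S%d", 1:8), sprintf("tx%02d", 1:50)))
  map <- data.frame(transcript_id = sprintf("tx%02d", 1:50),
                    gene_id = sprintf("gene%d", sample(1:12, 50, replace = TRUE)))
  gc <- sum_transcripts_to_genes(tx, map)
  for (g in unique(map$gene_id)) {
    members <- map$transcript_id[map$gene_id == g]
    expect_equal(gc[, g], rowSums(tx[, members, drop = FALSE]))
  }
  # single transcript is the identity; two transcripts add
  one <- sum_transcripts_to_genes(tx[, 1, drop = FALSE],
                                  map[1, , drop = FALSE])
  expect_equal(unname(one[, 1]), unname(tx[, 1]))
  expect_error(sum_transcripts_to_genes(tx, rbind(map, map[1, ])), "duplicated")
  expect_message(sum_transcripts_to_genes(tx, map[-1, ]), "dropped")
})

test_that("TMM factors: identical columns give 1, scaling a library cancels", {
  base <- matrix(rpois(6 * 200, 50), 6, 200,
                 dimnames = list(sprintf("S%d", 1:6), sprintf("g%03d", 1:200)))
  same <- matrix(rep(base[1, ], each = 6), 6)
  rownames(same) <- rownames(base)
  expect_equal(tmm_factors(same)$factor, rep(1, 6), tolerance = 1e-12)
  doubled <- base
  doubled[3, ] <- base[3, ] * 2L
  f1 <- tmm_factors(base)$factor
  f2 <- tmm_factors(doubled)$factor
  # M ratios are library-size normalized, so doubling cancels up to the
  # small change in the precision weights
  expect_equal(f1, f2, tolerance = 5e-3)
  expect_error(tmm_factors(base[1, , drop = FALSE]), "2 samples")
  expect_error(tmm_factors(rbind(base, S7 = 0L)), "all-zero")
})

test_that("TMM factors agree with the step-by-step hand oracle", {
  set.seed(32)
  toy <- matrix(rnbinom(5 * 20, mu = 40, size = 3) + 1L, 5, 20,
                dimnames = list(sprintf("S%d", 1:5), sprintf("g%02d", 1:20)))
  toy[2, ] <- toy[2, ] * 3L   # a larger library with composition drift
  toy[3, 1:4] <- toy[3, 1:4] * 10L
  got <- tmm_factors(toy)
  expect_equal(got$factor, unname(tmm_oracle(toy)), tolerance = 1e-10)
  expect_equal(exp(mean(log(got$factor))), 1, tolerance = 1e-8)
  # permutation equivariance in samples
  perm <- c(3, 1, 5, 2, 4)
  f_perm <- tmm_factors(toy[perm, ])$factor
  expect_equal(f_perm, got$factor[perm], tolerance = 1e-12)
})

test_that("logCPM matches its closed form, hand values and voom", {
  one <- matrix(c(0, 999999), 1, 2,
                dimnames = list("S1", c("gz", "grest")))
  lc <- log_cpm(one, NULL, prior_count = 0.5)
  expect_equal(unname(lc[1, "gz"]), log2(0.5), tolerance = 1e-12)
  m3 <- matrix(c(10, 20, 30, 5, 50, 100, 1, 2, 3), 3, 3,
               dimnames = list(c("a", "b", "c"), c("g1", "g2", "g3")))
  hand <- log2((m3 + 0.5) / (rowSums(m3) + 1) * 1e6)
  expect_equal(unclass(log_cpm(m3))[,], hand, ignore_attr = TRUE)
  # doubling all counts of a sample changes logCPM only via the prior
  big <- matrix(rpois(4 * 100, 1000), 4, 100,
                dimnames = list(sprintf("S%d", 1:4), sprintf("g%03d", 1:100)))
  l1 <- log_cpm(big)
  big2 <- big; big2[1, ] <- big2[1, ] * 2L
  l2 <- log_cpm(big2)
  expect_lt(max(abs(l2[1, ] - l1[1, ])), 0.002)
  # cross-check against limma::voom logCPM on TMM-normalized libraries
  skip_if_not_installed("limma")
  fac <- tmm_factors(big)
  v <- limma::voom(t(big), lib.size = fac$lib_size * fac$factor)
  expect_equal(t(v$E), unclass(log_cpm(big, fac))[,], ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("residualization projects out the covariate exactly and idempotently", {
  set.seed(33)
  expr <- matrix(rnorm(30 * 5), 30, 5,
                 dimnames = list(sprintf("S%02d", 1:30), sprintf("g%d", 1:5)))
  cv <- rnorm(30)
  r <- residualize(expr, cv)
  expect_true(all(abs(apply(r, 2, function(y) cor(y, cv))) < 1e-10))
  # hat-matrix oracle
  X <- cbind(1, cv)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(unclass(r)[,], (diag(30) - H) %*% expr, ignore_attr = TRUE,
               tolerance = 1e-10)
  # gene that is an exact multiple of the covariate vanishes
  expr2 <- cbind(expr, exact = 2 * cv)
  expect_lt(max(abs(residualize(expr2, cv)[, "exact"])), 1e-10)
  # idempotence
  expect_equal(unclass(residualize(r, cv))[,], unclass(r)[,],
               ignore_attr = TRUE, tolerance = 1e-10)
  # covariate orthogonal to a gene: only the mean is removed
  g <- expr[, 1] - mean(expr[, 1])
  go <- g - cv * sum(g * (cv - mean(cv))) / sum((cv - mean(cv))^2)
  ro <- residualize(matrix(go, ncol = 1), cv - mean(cv))
  expect_equal(unclass(ro)[, 1], go - mean(go), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("contamination scores are marker-gene log-means", {
  expr <- matrix(0, 3, 4, dimnames = list(c("a", "b", "c"), c("k", "t", "x", "y")))
  expect_equal(unname(contamination_scores(expr, c("k", "t"))), c(0, 0, 0))
  expr["a", c("k", "t")] <- c(2, 4)
  expect_equal(unname(contamination_scores(expr, c("k", "t"))["a"]), 3)
})
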