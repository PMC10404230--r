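test_that("counts approach latent abundances in the Poisson large-library limit", {
  set.seed(21)
  latent <- matrix(rnorm(40 * 30), 40, 30,
                   dimnames = list(sprintf("S%02d", 1:40), sprintf("g%02d", 1:30)))
  counts <- latent_to_counts(latent, lib_size_mean = 1e8, lib_size_cv = 0,
                             nb_dispersion = 0, seed = 22)
  lc <- log2(counts / rowSums(counts))
  # agreement up to a per-sample constant: center both per sample
  d <- (lc - rowMeans(lc)) - (latent - rowMeans(latent))
  expect_lt(max(abs(d)), 0.05)
})

test_that("count generation is symmetric, reproducible and validated", {
  latent <- matrix(1, 10, 5, dimnames = list(letters[1:10], LETTERS[1:5]))
  c1 <- latent_to_counts(latent, lib_size_mean = 1e5, seed = 1)
  expect_identical(c1, latent_to_counts(latent, lib_size_mean = 1e5, seed = 1))
  # all-equal latent rows: expected CPM identical across genes (Poisson
  # limit keeps the sampling noise small enough to see the symmetry)
  cpois <- latent_to_counts(latent, lib_size_mean = 1e6, nb_dispersion = 0,
                            seed = 1)
  expect_lt(diff(range(colMeans(cpois / rowSums(cpois)))), 0.002)
  expect_error(latent_to_counts(latent, lib_size_mean = -1), "positive")
  expect_error(latent_to_counts(latent, nb_dispersion = -1))
})

test_that("contamination injection records scores that marker genes expose", {
  set.seed(23)
  latent <- matrix(rnorm(200 * 20), 200, 20,
                   dimnames = list(sprintf("S%03d", 1:200), sprintf("g%02d", 1:20)))
  noop <- inject_contamination(latent, c("g01", "g02"), lambda_sd = 0, seed = 2)
  expect_equal(noop$expression, latent)
  loadings <- setNames(c(rep(0, 17), 1.5), paste0("g", sprintf("%02d", 3:20)))[18]
  ct <- inject_contamination(latent, c("g01", "g02"), lambda_sd = 0.5,
                             loadings = setNames(c(1.5, -1), c("g20", "g19")),
                             seed = 3)
  score <- rowMeans(ct$expression[, c("g01", "g02")])
  expect_gt(cor(score, ct$lambda), 0.95)
  expect_gt(cor(ct$expression[, "g20"] - latent[, "g20"], ct$lambda), 0.99)
  expect_lt(cor(ct$expression[, "g19"] - latent[, "g19"], ct$lambda), -0.99)
})

test_that("aneuploidy injection shifts X dosage as configured", {
  fx <- fix_small()
  set.seed(24)
  genes <- c(sprintf("x%02d", 1:10), sprintf("y%02d", 1:3))
  latent <- matrix(rnorm(100 * 13, sd = 0.3), 100, 13,
                   dimnames = list(fx$covar$sample_id, genes))
  empty <- inject_sex_anomalies(latent, fx$covar, genes[1:10], genes[11:13],
                                data.frame(sample_id = character(0), type = character(0)))
  expect_equal(empty$expression, latent)
  fem <- fx$covar$sample_id[fx$covar$sex == "F"]
  an <- inject_sex_anomalies(latent, fx$covar, genes[1:10], genes[11:13],
                             data.frame(sample_id = fem[1], type = "X0"))
  xscore <- rowMeans(an$expression[, 1:10])
  expect_equal(unname(xscore[fem[1]] - rowMeans(latent[, 1:10])[fem[1]]), -1)
})

test_that("swap injection is an involution recorded in the pairing", {
  set.seed(25)
  expr <- matrix(rnorm(20 * 4), 20, 4,
                 dimnames = list(sprintf("S%02d", 1:20), letters[1:4]))
  none <- inject_swaps(expr, 0, seed = 1)
  expect_identical(none$expression, expr)
  expect_identical(unname(none$pairing), rownames(expr))
  sw <- inject_swaps(expr, 3, seed = 2)
  expect_equal(sum(sw$pairing != names(sw$pairing)), 6)
  # applying the recorded pairing inverts the permutation
  restored <- sw$expression[match(rownames(expr), unname(sw$pairing)), ]
  rownames(restored) <- rownames(expr)
  expect_equal(restored, expr)
})
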