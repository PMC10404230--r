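# planted-module expression: n_mod modules of size m with within-module
# correlation ~r, plus optional independent genes
planted_modules <- function(n = 120, n_mod = 3, m = 50, r = 0.7,
                            n_noise = 0, seed = 111) {
  set.seed(seed)
  blocks <- lapply(seq_len(n_mod), function(k) {
    f <- rnorm(n)
    sapply(seq_len(m), function(j) sqrt(r) * f + sqrt(1 - r) * rnorm(n))
  })
  expr <- do.call(cbind, c(blocks, list(matrix(rnorm(n * n_noise), n))))
  colnames(expr) <- sprintf("g%03d", seq_len(ncol(expr)))
  truth <- c(rep(seq_len(n_mod), each = m), rep(0, n_noise))
  list(expr = expr, truth = truth)
}

test_that("signed adjacency has the documented closed forms", {
  C <- matrix(c(1, 1, -1, 0, 1, 1, -1, 0, -1, -1, 1, 0, 0, 0, 0, 1), 4, 4)
  a <- signed_adjacency(C, 3)
  expect_equal(unname(diag(a)), rep(0, 4))
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 4], 0.125)
})

test_that("scale-free fit separates power-law from homogeneous degree structure", {
  # expected-degree (Chung-Lu style) weighted graph whose degrees sit in
  # clusters following an exact power law: freq ~ k^-1.5
  k_levels <- seq(10, 100, by = 10)
  counts <- round(3000 * k_levels^-1.5)
  k <- rep(k_levels, counts)
  K <- sum(k)
  a <- outer(k, k) / K
  diag(a) <- 0
  fit <- scale_free_fit(a, n_bins = 10)
  expect_gt(fit$r2_signed, 0.95)
  expect_true(abs(fit$r2_signed) <= 1)
  # homogeneous (complete) graph: no decaying degree distribution
  b <- matrix(1, 40, 40); diag(b) <- 0
  expect_lt(scale_free_fit(b)$r2_signed, 0.5)
})

test_that("scale-free binning matches a hand computation", {
  a <- matrix(0, 20, 20)
  set.seed(113)
  w <- matrix(runif(400), 20); w <- (w + t(w)) / 2; diag(w) <- 0
  fit <- scale_free_fit(w, n_bins = 5)
  k <- rowSums(w)
  bins <- cut(k, 5)
  freq <- tapply(k, bins, length); km <- tapply(k, bins, mean)
  keep <- !is.na(freq)
  mod <- lm(log10(freq[keep]) ~ log10(km[keep]))
  expect_equal(fit$r2_signed,
               unname(-sign(coef(mod)[2]) * summary(mod)$r.squared),
               tolerance = 1e-12)
  expect_equal(fit$median_k, median(k))
})

test_that("soft-threshold selection picks the lowest qualifying power", {
  pm <- planted_modules(n = 80, n_mod = 5, m = 12, r = 0.6, seed = 114)
  sft <- pick_soft_threshold(pm$expr, powers = 1:8, r2_target = 0.8)
  expect_equal(nrow(sft$report), 8)
  # exhaustive-enumeration oracle over the same candidates
  C <- bicor_matrix(pm$expr)
  r2 <- vapply(1:8, function(p) scale_free_fit(signed_adjacency(C, p))$r2_signed,
               numeric(1))
  oracle <- if (any(r2 >= 0.8)) min(which(r2 >= 0.8)) else NA_integer_
  expect_equal(sft$selected_power, oracle)
  # a vacuous target selects power 1
  expect_equal(pick_soft_threshold(pm$expr, powers = 1:4,
                                   r2_target = 0)$selected_power, 1)
})

test_that("planted modules are recovered with high agreement", {
  skip_if_not_installed("mclust")
  pm <- planted_modules(n = 150, n_mod = 3, m = 50, r = 0.7, seed = 115)
  labels <- detect_modules(pm$expr, power = 12, min_module_size = 30)
  expect_equal(length(unique(labels[labels > 0])), 3)
  ari <- mclust::adjustedRandIndex(labels, pm$truth)
  expect_gt(ari, 0.9)
  # labels ordered by decreasing module size
  sz <- table(labels[labels > 0])
  expect_true(all(diff(as.vector(sz[as.character(sort(unique(labels[labels > 0])))])) <= 0))
})

test_that("independent genes stay unassigned and small clusters are dropped", {
  set.seed(116)
  expr <- matrix(rnorm(100 * 60), 100, 60,
                 dimnames = list(NULL, sprintf("g%02d", 1:60)))
  labels <- detect_modules(expr, power = 6, min_module_size = 30,
                           cut_height = 0.95)
  expect_true(all(labels == 0))
  # no module below the minimum size is ever emitted
  pm <- planted_modules(n = 100, n_mod = 2, m = 20, r = 0.8, n_noise = 20,
                        seed = 117)
  lab2 <- detect_modules(pm$expr, power = 12, min_module_size = 30)
  if (any(lab2 > 0)) expect_true(all(table(lab2[lab2 > 0]) >= 30))
})
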