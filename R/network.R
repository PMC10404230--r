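#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2) ^ power`, diagonal set to 0. The signed
#' transform keeps negatively correlated genes apart instead of folding
#' them together.
#'
#' @param corr Gene x gene correlation matrix.
#' @param power Soft-thresholding power.
#' @return Adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
signed_adjacency <- function(corr, power) {
  stopifnot(power > 0)
  a <- ((1 + corr) / 2)^power
  diag(a) <- 0
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Connectivities `k_i = sum_j a_ij` are binned into `n_bins` equal-width
#' bins; `log10(frequency)` is regressed on `log10(mean k)` over
#' non-empty bins, and the signed fit index is `-sign(slope) * R^2`
#' (positive when the degree distribution decays, as scale-free topology
#' requires).
#'
#' @param adjacency Weighted adjacency matrix (zero diagonal).
#' @param n_bins Number of connectivity bins (default 10).
#' @return List: `r2_signed`, `slope`, `mean_k`, `median_k`, `max_k`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- rowSums(adjacency)
  stats_out <- list(mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  if (stats::sd(k) == 0 || all(k == 0))
    return(c(list(r2_signed = 0, slope = NA_real_), stats_out))
  bins <- cut(k, n_bins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 2)
    return(c(list(r2_signed = 0, slope = NA_real_), stats_out))
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  c(list(r2_signed = unname(-sign(slope) * r2), slope = slope), stats_out)
}

#' Choose the soft-thresholding power for a signed bicor network
#'
#' Evaluates the scale-free topology fit of the signed bicor adjacency at
#' each candidate power and selects the lowest power whose signed R^2
#' meets the target (the standard pick: the smallest power achieving
#' approximate scale-free topology while retaining maximal connectivity).
#'
#' @param expr Samples x genes expression matrix.
#' @param powers Candidate powers (default 1..20).
#' @param r2_target Signed R^2 target (default 0.9).
#' @param n_bins Connectivity histogram bins.
#' @param corr Optional precomputed correlation matrix.
#' @return A `soft_threshold_report`: data frame `report` (power,
#'   r2_signed, slope, mean_k, median_k) and `selected_power` (NA if no
#'   candidate qualifies).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.9,
                                n_bins = 10, corr = NULL) {
  if (is.null(corr)) corr <- bicor_matrix(expr)
  rows <- lapply(powers, function(p) {
    f <- scale_free_fit(signed_adjacency(corr, p), n_bins)
    data.frame(power = p, r2_signed = f$r2_signed, slope = f$slope,
               mean_k = f$mean_k, median_k = f$median_k)
  })
  report <- do.call(rbind, rows)
  # a non-positive target is vacuous: every candidate qualifies
  ok <- if (r2_target <= 0) seq_len(nrow(report)) else
    which(report$r2_signed >= r2_target)
  structure(list(report = report,
                 selected_power = if (length(ok)) report$power[min(ok)] else NA_integer_,
                 r2_target = r2_target),
            class = "soft_threshold_report")
}

#' @export
print.soft_threshold_report <- function(x, ...) {
  cat("soft-threshold selection (target signed R^2 >=", x$r2_target, "):",
      if (is.na(x$selected_power)) "no power qualified"
      else paste("power", x$selected_power), "\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

# Topological overlap matrix of a weighted adjacency
tom_similarity <- function(a) {
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules (TOM clustering with a static cut)
#'
#' Builds the signed bicor adjacency at the given power, converts it to
#' topological overlap dissimilarity `1 - TOM`, clusters by
#' average-linkage hierarchical clustering, and cuts the tree at a fixed
#' height. Clusters of at least `min_module_size` genes become modules
#' labelled 1, 2, ... by decreasing size; all other genes get label 0
#' (unassigned). This static cut is a deliberately simple replacement
#' for dynamic tree cutting; `cut_height` is exposed for tuning.
#'
#' @param expr Samples x genes expression matrix.
#' @param power Soft-thresholding power.
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Static tree-cut height on 1 - TOM (default 0.99).
#' @param corr Optional precomputed correlation matrix.
#' @return Named integer vector: gene -> module label (0 = unassigned).
#' @export
detect_modules <- function(expr, power, min_module_size = 30,
                           cut_height = 0.99, corr = NULL) {
  if (is.null(corr)) corr <- bicor_matrix(expr)
  a <- signed_adjacency(corr, power)
  d <- 1 - tom_similarity(a)
  hc <- stats::hclust(stats::as.dist((d + t(d)) / 2), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- stats::setNames(rep(0L, ncol(expr)), colnames(expr))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) labels[cl == as.integer(ord[i])] <- i
  }
  labels
}
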