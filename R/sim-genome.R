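#' Simulate founder-haplotype mosaic genomes
#'
#' Generates per-sample founder haplotype probabilities the way a
#' multiparent (Diversity Outbred style) genome looks after many outbred
#' generations: each chromosome of each sample carries two chromatids,
#' each partitioned into segments by a Poisson number of uniformly placed
#' breakpoints, with an independent uniform founder label per segment.
#' The probability vector at a marker is half the sum of the two
#' chromatid indicator vectors (so it is 1 for a homozygous founder and
#' 0.5/0.5 for a heterozygous pair), then optionally blurred toward the
#' uniform simplex to emulate reconstruction uncertainty:
#' `p <- (1 - alpha) * p + alpha / 8`.
#'
#' @param map Marker map from [make_marker_map()].
#' @param n_samples Number of samples.
#' @param crossover_density_per_morgan Expected breakpoints per Morgan per
#'   chromatid. The default 30 reflects the accumulated historical
#'   recombination of a many-generation outbred stock, giving mosaic
#'   blocks of a few cM.
#' @param prob_blur_alpha Mixture weight toward the uniform simplex in
#'   `[0, 1)`; default 0.05 emulates mild haplotype-reconstruction
#'   uncertainty.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `founder_probs`: a named list with one
#'   `n_samples x 8 x n_markers` array per chromosome, with a `map`
#'   attribute carrying the marker map.
#' @export
#' @examples
#' map <- make_marker_map(1, 50, 20)
#' fp <- simulate_founder_mosaics(map, n_samples = 4, seed = 1)
#' dim(fp[["1"]])
simulate_founder_mosaics <- function(map, n_samples,
                                     crossover_density_per_morgan = 30,
                                     prob_blur_alpha = 0.05, seed = 1) {
  validate_marker_map(map)
  if (nrow(map) == 0) stop("empty marker map")
  stopifnot(n_samples >= 1, crossover_density_per_morgan > 0,
            prob_blur_alpha >= 0, prob_blur_alpha < 1)
  set.seed(seed)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  chroms <- map_chromosomes(map)
  by_chr <- map_split(map)
  probs <- vector("list", length(chroms))
  names(probs) <- chroms
  for (ch in chroms) {
    cm <- by_chr[[ch]]$position_cM
    lo <- min(cm); hi <- max(cm)
    morgans <- (hi - lo) / 100
    M <- length(cm)
    arr <- array(0, dim = c(n_samples, 8, M),
                 dimnames = list(sample_ids, founder_codes(),
                                 by_chr[[ch]]$marker_id))
    for (i in seq_len(n_samples)) {
      for (chromatid in 1:2) {
        n_bk <- stats::rpois(1, crossover_density_per_morgan * morgans)
        breaks <- sort(stats::runif(n_bk, lo, hi))
        labels <- sample.int(8, n_bk + 1, replace = TRUE)
        seg <- findInterval(cm, breaks) + 1L  # segment index per marker
        lab <- labels[seg]
        arr[cbind(i, lab, seq_len(M))] <- arr[cbind(i, lab, seq_len(M))] + 0.5
      }
    }
    if (prob_blur_alpha > 0)
      arr <- (1 - prob_blur_alpha) * arr + prob_blur_alpha / 8
    probs[[ch]] <- arr
  }
  structure(probs, map = map, class = c("founder_probs", "list"))
}

#' @export
print.founder_probs <- function(x, ...) {
  n <- dim(x[[1]])[1]
  m <- sum(vapply(x, function(a) dim(a)[3], integer(1)))
  cat("founder_probs:", n, "samples x 8 founders x", m, "markers on",
      length(x), "chromosome(s)\n")
  invisible(x)
}

fp_samples <- function(probs) dimnames(probs[[1]])[[1]]

fp_map <- function(probs) attr(probs, "map")

fp_n_markers <- function(probs) sum(vapply(probs, function(a) dim(a)[3], integer(1)))

# Locate a marker: returns list(chromosome, index, bp)
fp_find_marker <- function(probs, marker_id) {
  for (ch in names(probs)) {
    idx <- match(marker_id, dimnames(probs[[ch]])[[3]])
    if (!is.na(idx)) {
      map <- fp_map(probs)
      bp <- map$position_bp[map$marker_id == marker_id]
      return(list(chromosome = ch, index = idx, bp = bp))
    }
  }
  stop("marker not found in founder probabilities: ", marker_id)
}

# n x 8 slice of probabilities at a single marker
fp_at_marker <- function(probs, marker_id) {
  loc <- fp_find_marker(probs, marker_id)
  probs[[loc$chromosome]][, , loc$index, drop = TRUE]
}

# Flatten to a samples x (8 * n_markers) matrix, optionally restricted to
# a marker-id subset (used for haplotype-correlation fingerprinting).
fp_flatten <- function(probs, markers = NULL) {
  pieces <- lapply(probs, function(a) {
    keep <- if (is.null(markers)) seq_len(dim(a)[3]) else
      which(dimnames(a)[[3]] %in% markers)
    if (!length(keep)) return(NULL)
    matrix(a[, , keep, drop = FALSE], nrow = dim(a)[1])
  })
  out <- do.call(cbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(out) <- fp_samples(probs)
  out
}

# Relabel/reorder samples (used by swap injection and mixup repair)
fp_set_samples <- function(probs, ids) {
  for (ch in names(probs)) dimnames(probs[[ch]])[[1]] <- ids
  probs
}
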