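#' Realized kinship from founder haplotype probabilities
#'
#' `K[a, b] = (1/M) * sum over markers m and founders j of
#' p[a, j, m] * p[b, j, m]` — the expected founder-allele sharing between
#' samples. With `loco = TRUE`, also returns one leave-one-chromosome-out
#' matrix per chromosome, computed from all markers except that
#' chromosome's (used to keep the polygenic term from absorbing the
#' scanned locus).
#'
#' @param probs `founder_probs` object.
#' @param loco Compute LOCO matrices as well?
#' @return A `kinship_set` list: `overall` (n x n), and if requested
#'   `loco`, a named list of n x n matrices.
#' @export
kinship_from_probs <- function(probs, loco = TRUE) {
  chroms <- names(probs)
  if (loco && length(chroms) < 2)
    stop("LOCO kinship needs at least 2 chromosomes (complement would be empty)")
  n <- dim(probs[[1]])[1]
  per_chr <- lapply(probs, function(a) {
    A <- matrix(a, nrow = dim(a)[1])    # n x (8 * M_c)
    tcrossprod(A)
  })
  m_chr <- vapply(probs, function(a) dim(a)[3], numeric(1))
  total <- Reduce(`+`, per_chr)
  M <- sum(m_chr)
  K <- (total + t(total)) / (2 * M)     # enforce exact symmetry
  dimnames(K) <- list(fp_samples(probs), fp_samples(probs))
  out <- list(overall = K)
  if (loco) {
    out$loco <- lapply(chroms, function(ch) {
      S <- total - per_chr[[ch]]
      Kc <- (S + t(S)) / (2 * (M - m_chr[[ch]]))
      dimnames(Kc) <- dimnames(K)
      Kc
    })
    names(out$loco) <- chroms
  }
  class(out) <- "kinship_set"
  out
}

# Accept a kinship_set, a plain matrix, or NULL, and return the matrix to
# use when scanning chromosome `chrom` (NULL means no polygenic term).
kinship_for_chrom <- function(kinship, chrom) {
  if (is.null(kinship)) return(NULL)
  if (is.matrix(kinship)) return(kinship)
  if (inherits(kinship, "kinship_set") || is.list(kinship)) {
    if (!is.null(kinship$loco) && chrom %in% names(kinship$loco))
      return(kinship$loco[[chrom]])
    return(kinship$overall)
  }
  stop("unrecognized kinship argument")
}

# Eigen-decomposition cache for a kinship matrix, with the normalization
# that makes hsq a phenotypic-variance fraction: K is scaled by
# kappa = (tr(K) - sum(K)/n)/n, the mean diagonal of the centered kinship,
# a pure reparameterization of the variance components.
kinship_decomp <- function(K) {
  n <- nrow(K)
  kap <- (sum(diag(K)) - sum(K) / n) / n
  if (!is.finite(kap) || kap <= 0) kap <- 1
  eg <- eigen(K / kap, symmetric = TRUE)
  list(U = eg$vectors, lambda = pmax(eg$values, 0), kappa = kap, n = n)
}
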