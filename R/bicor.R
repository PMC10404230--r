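# Biweight midcorrelation: a robust correlation built on median/MAD
# Tukey biweights. For each variable, u_i = (x_i - med) / (9 * MAD) with
# MAD the raw median absolute deviation; weights w_i = (1 - u_i^2)^2 for
# |u_i| < 1, else 0; and bicor is the cosine of the weighted, median-
# centered vectors.

# weighted, normalized column for bicor; NULL if MAD = 0
bicor_column <- function(x) {
  med <- stats::median(x)
  madv <- stats::median(abs(x - med))
  if (madv == 0) return(NULL)
  u <- (x - med) / (9 * madv)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  xt <- (x - med) * w
  nrm <- sqrt(sum(xt^2))
  if (nrm == 0) return(NULL)
  xt / nrm
}

# Pearson-normalized column (fallback); NULL if constant
pearson_column <- function(x) {
  xc <- x - mean(x)
  nrm <- sqrt(sum(xc^2))
  if (nrm == 0) return(NULL)
  xc / nrm
}

#' Biweight midcorrelation of two vectors
#'
#' Falls back to Pearson for a variable whose MAD is zero (with a
#' message); returns NA with a warning if a variable is constant.
#'
#' @param x,y Numeric vectors (n >= 4).
#' @return Correlation in `[-1, 1]`, or NA.
#' @export
#' @examples
#' set.seed(1); a <- rnorm(50)
#' bicor(a, 2 * a + 1)
bicor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  cx <- bicor_column(x); cy <- bicor_column(y)
  if (is.null(cx) || is.null(cy))
    message("MAD = 0: falling back to Pearson weighting for the affected variable")
  if (is.null(cx)) cx <- pearson_column(x)
  if (is.null(cy)) cy <- pearson_column(y)
  if (is.null(cx) || is.null(cy)) {
    warning("constant vector: correlation undefined, returning NA")
    return(NA_real_)
  }
  min(1, max(-1, sum(cx * cy)))
}

#' Biweight midcorrelation matrix of an expression matrix
#'
#' Columns (genes) with zero MAD use Pearson normalization for the pairs
#' involving them (the hybrid fallback); constant columns give NA rows
#' with a warning.
#'
#' @param expr Samples x genes matrix (n >= 4).
#' @return Symmetric gene x gene correlation matrix with unit diagonal;
#'   attribute `method = "bicor"` and `pearson_fallback` listing
#'   fallback genes.
#' @export
bicor_matrix <- function(expr) {
  stopifnot(nrow(expr) >= 4)
  G <- ncol(expr)
  cols <- matrix(0, nrow(expr), G, dimnames = dimnames(expr))
  fallback <- character(0)
  bad <- character(0)
  for (g in seq_len(G)) {
    cg <- bicor_column(expr[, g])
    if (is.null(cg)) {
      fallback <- c(fallback, colnames(expr)[g])
      cg <- pearson_column(expr[, g])
      if (is.null(cg)) { bad <- c(bad, colnames(expr)[g]); cg <- rep(NA_real_, nrow(expr)) }
    }
    cols[, g] <- cg
  }
  if (length(bad))
    warning("constant gene(s), correlations undefined: ",
            paste(bad, collapse = ", "))
  C <- crossprod(cols)
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- ifelse(colnames(expr) %in% bad, NA_real_, 1)
  attr(C, "method") <- "bicor"
  attr(C, "pearson_fallback") <- setdiff(fallback, bad)
  C
}
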