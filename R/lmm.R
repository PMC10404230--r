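# Linear mixed model machinery for the haplotype scan.
#
# Model: y = X beta + gamma + eps, gamma ~ N(0, sg2 K), eps ~ N(0, se2 I),
# hsq = sg2 / (sg2 + se2). After eigendecomposing K = U L U' and rotating
# by U', observations are independent with variance hsq*lambda_k + (1-hsq)
# (up to total scale), so every fit is weighted least squares.

# Weighted RSS of rotated data at a given hsq; returns rss and the fit.
rotated_wls <- function(yr, Xr, lambda, hsq) {
  w <- 1 / (hsq * lambda + (1 - hsq))
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xr * sw, yr * sw)
  list(rss = sum(fit$residuals^2), fit = fit, logdetV = -sum(log(w)))
}

# Profile log-likelihood in hsq (ML or REML) for rotated data.
profile_loglik <- function(hsq, yr, Xr, lambda, reml = TRUE) {
  n <- length(yr)
  p <- ncol(Xr)
  r <- rotated_wls(yr, Xr, lambda, hsq)
  if (reml) {
    s2 <- r$rss / (n - p)
    w <- 1 / (hsq * lambda + (1 - hsq))
    XtWX <- crossprod(Xr * sqrt(w))
    XtX <- crossprod(Xr)
    -0.5 * ((n - p) * log(2 * pi * s2) + r$logdetV +
              determinant(XtWX, logarithm = TRUE)$modulus -
              determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  } else {
    s2 <- r$rss / n
    -0.5 * (n * log(2 * pi * s2) + r$logdetV + n)
  }
}

#' Fit the covariates-only (null) mixed model
#'
#' Eigendecomposes the kinship once, rotates the data, and maximizes the
#' profile (restricted) log-likelihood over the polygenic variance
#' fraction `hsq` by Brent's bounded scalar optimization on
#' `[0, 1 - 1e-6]`. Internally the kinship is rescaled so that `hsq` is
#' directly the fraction of phenotypic variance carried by the polygenic
#' term (a pure reparameterization; LOD scores are unaffected).
#'
#' @param y Phenotype vector (length n).
#' @param covariate_design Full-rank n x p design (include the
#'   intercept), e.g. from [covariate_design()].
#' @param K Kinship matrix, or a pre-computed decomposition from the
#'   internal cache.
#' @param reml Use REML (default) rather than ML for the profile.
#' @return A `null_fit` list: `hsq`, `sigma2` (total variance), `loglik`,
#'   `coefficients` (GLS at the optimum), plus the decomposition and
#'   rotated data for reuse.
#' @export
fit_null <- function(y, covariate_design, K, reml = TRUE) {
  X <- as.matrix(covariate_design)
  stopifnot(length(y) == nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  dec <- if (is.matrix(K)) kinship_decomp(K) else K
  yr <- crossprod(dec$U, y)
  Xr <- crossprod(dec$U, X)
  opt <- stats::optimize(profile_loglik, c(0, 1 - 1e-6), maximum = TRUE,
                         yr = yr, Xr = Xr, lambda = dec$lambda, reml = reml,
                         tol = 1e-8)
  # guard the boundaries: Brent can miss an endpoint optimum
  cand_h <- c(opt$maximum, 0, 1 - 1e-6)
  cand_ll <- c(opt$objective,
               profile_loglik(0, yr, Xr, dec$lambda, reml),
               profile_loglik(1 - 1e-6, yr, Xr, dec$lambda, reml))
  best <- which.max(cand_ll)
  hsq <- cand_h[best]
  r <- rotated_wls(yr, Xr, dec$lambda, hsq)
  n <- length(y)
  structure(list(hsq = hsq, sigma2 = r$rss / if (reml) (n - ncol(X)) else n,
                 loglik = cand_ll[best],
                 coefficients = stats::setNames(r$fit$coefficients, colnames(X)),
                 rss = r$rss, reml = reml,
                 decomp = dec, yr = yr, Xr = Xr),
            class = "null_fit")
}

#' Heritability of a trait (or of each column of a trait matrix)
#'
#' The polygenic variance fraction `hsq` from the null mixed-model fit
#' against the overall (all-chromosome) kinship.
#'
#' @param y Phenotype vector, or samples x genes matrix.
#' @param covariate_design Covariate design matrix.
#' @param K_overall Overall kinship matrix.
#' @param reml Use REML (default TRUE).
#' @return Numeric `hsq` in `[0, 1)`, one value per trait.
#' @export
heritability <- function(y, covariate_design, K_overall, reml = TRUE) {
  dec <- kinship_decomp(K_overall)
  if (is.matrix(y)) {
    apply(y, 2, function(yy) fit_null(yy, covariate_design, dec, reml)$hsq)
  } else {
    fit_null(y, covariate_design, dec, reml)$hsq
  }
}
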