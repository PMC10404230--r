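# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small mapping fixture: 100 samples, 3 chromosomes x 20 markers
fix_small <- function() fixture("small", function() {
  map <- make_marker_map(3, 100, 20)
  probs <- simulate_founder_mosaics(map, 100, seed = 42)
  covar <- simulate_covariates(100, seed = 43)
  list(map = map, probs = probs, covar = covar, X = covariate_design(covar),
       kinship = kinship_from_probs(probs, loco = TRUE))
})

# larger mapping fixture shared by the recovery-style tests
fix_big <- function() fixture("big", function() {
  map <- make_marker_map(3, 100, 50)
  probs <- simulate_founder_mosaics(map, 400, seed = 7)
  covar <- simulate_covariates(400, seed = 8)
  list(map = map, probs = probs, covar = covar, X = covariate_design(covar),
       kinship = kinship_from_probs(probs, loco = TRUE))
})

# independent straight-line OLS LOD oracle: per marker, full regression
# via lm(), LOD = (n/2) log10(RSS0 / RSS1)
ols_lod_oracle <- function(y, probs, X) {
  n <- length(y)
  rss0 <- sum(stats::resid(stats::lm(y ~ X + 0))^2)
  unlist(lapply(names(probs), function(ch) {
    arr <- probs[[ch]]
    vapply(seq_len(dim(arr)[3]), function(m) {
      P <- arr[, 1:7, m]
      rss1 <- sum(stats::resid(stats::lm(y ~ X + P + 0))^2)
      max(0, n / 2 * log10(rss0 / rss1))
    }, numeric(1))
  }))
}

# independent Hungarian oracle: exhaustive enumeration over permutations
perm_enumerate <- function(n) {
  if (n == 1) return(list(1L))
  sub <- perm_enumerate(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) for (pos in 0:(n - 1)) {
    k <- k + 1
    out[[k]] <- append(p, n, after = pos)
  }
  out
}

best_assignment_bruteforce <- function(cm) {
  n <- nrow(cm)
  perms <- perm_enumerate(n)
  scores <- vapply(perms, function(p) sum(cm[cbind(seq_len(n), p)]), numeric(1))
  perms[[which.max(scores)]]
}

# exhaustive paraclique oracle on tiny graphs: bitmask max clique +
# simulated glom accretion, mirroring the documented tie-break
paraclique_oracle <- function(adj, min_seed, min_size, glom) {
  stopifnot(nrow(adj) <= 16)
  out <- list()
  alive <- seq_len(nrow(adj))
  while (length(alive) >= min_seed) {
    sub <- adj[alive, alive, drop = FALSE]
    nv <- nrow(sub)
    # enumerate every subset, keep cliques, take max size then lex order
    best <- NULL
    for (mask in seq_len(2^nv - 1)) {
      vs <- which(bitwAnd(mask, 2^(seq_len(nv) - 1)) > 0)
      if (!is.null(best) && length(vs) < length(best)) next
      ok <- TRUE
      if (length(vs) > 1)
        for (a in seq_along(vs)[-length(vs)]) {
          if (!all(sub[vs[a], vs[(a + 1):length(vs)]])) { ok <- FALSE; break }
        }
      if (!ok) next
      if (is.null(best) || length(vs) > length(best)) best <- vs
      else if (length(vs) == length(best)) {
        d <- which(vs != best)
        if (length(d) && vs[d[1]] < best[d[1]]) best <- vs
      }
    }
    if (length(best) < min_seed) break
    members <- best
    repeat {
      outside <- setdiff(seq_len(nv), members)
      if (!length(outside)) break
      need <- ceiling((1 - glom) * length(members))
      cnt <- vapply(outside, function(v) sum(sub[members, v]), numeric(1))
      ok <- cnt >= need
      if (!any(ok)) break
      members <- sort(c(members, outside[ok][which.max(cnt[ok])]))
    }
    gm <- alive[members]
    if (length(gm) >= min_size) {
      edges <- sum(adj[gm, gm]) / 2
      out[[length(out) + 1]] <- list(members = gm, size = length(gm),
                                     density = edges / choose(length(gm), 2))
    }
    alive <- setdiff(alive, gm)
  }
  out
}

# straight-line reimplementation of the published TMM formula, used as an
# independent oracle for tmm_factors()
tmm_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05, a_cutoff = -1e10) {
  lib <- rowSums(counts)
  f75 <- apply(counts, 1, quantile, p = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(nrow(counts))
  for (s in seq_len(nrow(counts))) {
    ys <- counts[s, ]; yr <- counts[ref, ]
    Ns <- lib[s]; Nr <- lib[ref]
    keep <- ys > 0 & yr > 0
    ys <- ys[keep]; yr <- yr[keep]
    M <- log2((ys / Ns) / (yr / Nr))
    A <- 0.5 * log2((ys / Ns) * (yr / Nr))
    ok <- is.finite(M) & is.finite(A) & A > a_cutoff
    M <- M[ok]; A <- A[ok]; ys <- ys[ok]; yr <- yr[ok]
    if (max(abs(M)) < 1e-6) { f[s] <- 1; next }
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    w <- 1 / ((Ns - ys) / (Ns * ys) + (Nr - yr) / (Nr * yr))
    f[s] <- 2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  }
  f / exp(mean(log(f)))
}

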