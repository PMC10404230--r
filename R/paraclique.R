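# Paraclique extraction from a thresholded correlation graph.
#
# A paraclique is grown from an exact maximum clique (the seed) by
# "glomming": repeatedly admitting an outside vertex adjacent to enough
# of the current members, until no vertex qualifies. Members are then
# removed from the graph and the process repeats while the remaining
# maximum clique is large enough.

# lexicographically smallest of a list of sorted integer vectors
lex_smallest <- function(sets) {
  sets <- lapply(sets, sort)
  best <- sets[[1]]
  for (s in sets[-1]) {
    n <- min(length(best), length(s))
    cmp <- which(s[seq_len(n)] != best[seq_len(n)])
    if (length(cmp)) {
      if (s[cmp[1]] < best[cmp[1]]) best <- s
    } else if (length(s) < length(best)) best <- s
  }
  best
}

# Sequential glom accretion on a logical adjacency matrix: one vertex per
# step, the qualifying outside vertex with the most edges into the
# current members (ties to the lowest index). Admitting one vertex at a
# time is what makes the emitted density >= 1 - glom a theorem: each
# admission contributes at least ceiling((1 - glom) * |P|) of its |P|
# possible edges. Members/candidates are integer vertex indices.
accrete <- function(adj, members, glom, rule = c("proportional", "missed_edges")) {
  rule <- match.arg(rule)
  repeat {
    outside <- setdiff(seq_len(nrow(adj)), members)
    if (!length(outside)) break
    deg_in <- colSums(adj[members, outside, drop = FALSE])
    need <- if (rule == "proportional") ceiling((1 - glom) * length(members))
            else length(members) - floor(glom * length(members))
    ok <- deg_in >= need
    if (!any(ok)) break
    members <- c(members, outside[ok][which.max(deg_in[ok])])
  }
  sort(members)
}

#' Extract paracliques from a correlation matrix
#'
#' Builds an unsigned graph with an edge wherever `|corr| >= threshold`,
#' then repeatedly: finds an exact maximum clique (Bron-Kerbosch with
#' pivoting via igraph; ties broken toward the lexicographically
#' smallest vertex set); stops if it is smaller than `min_seed`; grows it
#' by sequential glomming — while any outside vertex is adjacent to at
#' least `ceiling((1 - glom) * |P|)` current members, the qualifying
#' vertex with the most member edges (ties to the lowest index) is
#' admitted and `|P|` grows by one; emits the result if it has at least
#' `min_size` members; and removes the members from the graph. One
#' vertex per step guarantees every emitted paraclique has edge density
#' at least `1 - glom`.
#'
#' With `rule = "missed_edges"` the admission requirement is instead
#' `|P| - floor(glom * |P|)` neighbors (admission by missed-edge count);
#' the two rules differ on rounding boundaries.
#'
#' Maximum clique is exact, so instances are guarded by `max_vertices`;
#' pre-filter the gene set (e.g. to the most variable or connected genes)
#' rather than raising the bound blindly.
#'
#' @param corr Symmetric correlation matrix (genes x genes).
#' @param threshold Absolute-correlation edge threshold (default 0.5).
#' @param min_seed Minimum seed (maximum) clique size to continue
#'   (default 5).
#' @param min_size Minimum finished paraclique size to emit (default 10).
#' @param glom Proportional glom factor in `[0, 1)` (default 0.2).
#' @param max_vertices Guard on instance size for exact max-clique.
#' @param rule Glom admission rule (see Details).
#' @return List of paracliques, each a list with `members` (gene ids),
#'   `seed_size`, `size`, `density`.
#' @export
paraclique_extract <- function(corr, threshold = 0.5, min_seed = 5,
                               min_size = 10, glom = 0.2,
                               max_vertices = 5000,
                               rule = c("proportional", "missed_edges")) {
  rule <- match.arg(rule)
  stopifnot(isSymmetric(unname(corr)), glom >= 0, glom < 1)
  G <- nrow(corr)
  if (G > max_vertices)
    stop("graph has ", G, " vertices; exact maximum clique is guarded at ",
         max_vertices, " — pre-filter the gene set before extraction")
  ids <- colnames(corr)
  if (is.null(ids)) ids <- as.character(seq_len(G))
  adj <- abs(corr) >= threshold
  diag(adj) <- FALSE
  alive <- seq_len(G)
  out <- list()
  while (length(alive) >= min_seed) {
    sub <- adj[alive, alive, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    cl <- igraph::largest_cliques(g)
    if (!length(cl)) break
    seed_local <- lex_smallest(lapply(cl, as.integer))
    if (length(seed_local) < min_seed) break
    members_local <- accrete(sub, seed_local, glom, rule)
    members <- alive[members_local]
    m <- length(members)
    if (m >= min_size) {
      edges <- sum(adj[members, members]) / 2
      out[[length(out) + 1]] <- list(
        members = ids[members], seed_size = length(seed_local),
        size = m, density = edges / choose(m, 2))
    }
    alive <- setdiff(alive, members)
  }
  out
}
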