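# Independent oracles used across the suite. Each is a deliberately
# naive re-derivation (direct scan, exhaustive enumeration, plain loop)
# kept separate from the package's own code paths.

# Benjamini-Hochberg step-up by direct scan of the definition:
# fdr_(i) = min_{j >= i} m p_(j) / j, capped at 1, back in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  fdr_sorted <- numeric(m)
  for (i in seq_len(m)) {
    fdr_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- fdr_sorted
  out
}

# Upper-tail hypergeometric P(X >= k) by exhaustive combinatorial sum.
hyper_oracle <- function(k, K, N, n) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

# GSEA running-sum enrichment score by a plain element-wise loop.
es_oracle <- function(ranked, members, q = 1) {
  ids <- names(ranked)
  hit <- ids %in% members
  ranked <- unname(ranked)
  N <- length(ids); K <- sum(hit)
  denom_hit <- sum(abs(ranked[hit])^q)
  rs <- 0
  best <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (hit[i]) abs(ranked[i])^q / denom_hit else -1 / (N - K)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# Sample relative standard deviation (n - 1 denominator).
rsd_of <- function(x) stats::sd(x) / mean(x)

# Small random interaction network plus a random module assignment, for
# contraction-oracle sweeps.
random_instance <- function(n_nodes = 50, n_modules = 6, edge_p = 0.1,
                            policy = "unique_lexicographic",
                            multi_frac = 0.3, unannotated_frac = 0.1,
                            seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  draw <- stats::runif(ncol(pairs)) < edge_p
  net <- interaction_network(
    data.frame(from = pairs[1, draw], to = pairs[2, draw],
               stringsAsFactors = FALSE),
    nodes = nodes)
  pathways <- sprintf("P%02d", seq_len(n_modules))
  annotated <- nodes[stats::runif(n_nodes) >= unannotated_frac]
  membership <- lapply(annotated, function(nd) {
    k <- if (stats::runif(1) < multi_frac) 2L else 1L
    sample(pathways, k)
  })
  names(membership) <- annotated
  sets <- membership_to_gene_sets(membership)
  assignment <- assign_modules(nodes, sets, policy = policy)
  list(net = net, assignment = assignment, sets = sets)
}

# feature -> pathways list into a gene_sets collection (test-side copy).
membership_to_gene_sets <- function(membership) {
  pw <- unlist(membership, use.names = FALSE)
  ft <- rep(names(membership), lengths(membership))
  gene_sets(lapply(split(ft, pw), function(m)
    list(description = "", members = sort(unique(m)))))
}

# Tiny omics_matrix builder for hand-constructed examples.
toy_matrix <- function(values, layer = "protein", stage = "raw",
                       features = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  rownames(values) <- features %||% sprintf("f%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  omics_matrix(values, layer = layer, stage = stage)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
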