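#' Over-representation analysis (hypergeometric test)
#'
#' Tests each pathway for over-representation of a selected feature set
#' within a universe: with `N = |universe|`, `K = |set in universe|`,
#' `n = |selected|` and `k = |overlap|`, the p-value is the upper-tail
#' hypergeometric probability `P(X >= k)`. Sets are intersected with the
#' universe before testing; p-values are BH-adjusted across the tested
#' sets.
#'
#' @param selected character vector, a subset of `universe`.
#' @param universe character vector: all features eligible for selection
#'   (here, the features present in the layer after preprocessing).
#' @param sets a [gene_sets()] collection.
#' @return data frame with one row per set having a nonzero presence in
#'   the universe: `set_id`, `description`, `k`, `K`, `n`, `N`, `p`,
#'   `fdr`, ordered by `p`.
#' @export
hypergeom_enrich <- function(selected, universe, sets) {
  assert_that(all(selected %in% universe),
              "selected features must be a subset of the universe")
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(selected) == 0) {
    warning("empty selected set; no enrichment computed")
    return(data.frame(set_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]]$members, universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, selected))
    # upper tail P(X >= k); phyper is P(X <= q), so use q = k - 1
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, description = sets[[id]]$description,
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pre-ranked gene-set enrichment score
#'
#' The weighted Kolmogorov-Smirnov-style running-sum statistic: walking
#' down the ranked list, the sum increases by
#' `|score|^weight_exponent / sum(|score_members|^weight_exponent)` at
#' each set member and decreases by `1 / (N - K)` at each non-member; the
#' enrichment score (ES) is the signed maximum deviation from zero and
#' lies in `[-1, 1]`. With `weight_exponent = 0` every member contributes
#' equally (the classic unweighted statistic).
#'
#' @param ranked named numeric vector: ranking scores in list order
#'   (highest-ranked first); names are unique feature ids.
#' @param members character vector: the gene set (must intersect the
#'   ranked list).
#' @param weight_exponent nonnegative weight on `|score|` (default 1).
#' @return the enrichment score (numeric scalar); attribute
#'   `"running_sum"` holds the full running-sum vector.
#' @export
gsea_es <- function(ranked, members, weight_exponent = 1) {
  ids <- names(ranked)
  assert_that(!is.null(ids) && !anyDuplicated(ids),
              "ranked list must have unique feature names")
  hit <- ids %in% members
  if (!any(hit)) stop("gene set is disjoint from the ranked list",
                      call. = FALSE)
  N <- length(ranked); K <- sum(hit)
  if (N == K) {
    # degenerate: every feature is a member; running sum is monotone to 1
    rs <- cumsum(abs(ranked)^weight_exponent /
                   sum(abs(ranked)^weight_exponent))
    es <- 1
    attr(es, "running_sum") <- rs
    return(es)
  }
  w <- abs(ranked)^weight_exponent
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - K))
  rs <- cumsum(inc)
  es <- rs[which.max(abs(rs))]
  es <- unname(es)
  attr(es, "running_sum") <- unname(rs)
  es
}

#' Permutation p-value for a GSEA enrichment score
#'
#' Gene-label permutation null: the set's positions in the ranked list
#' are re-drawn uniformly `n_perm` times and the two-sided permutation
#' p-value is `(1 + #{|ES*| >= |ES|}) / (1 + n_perm)`.
#'
#' @param ranked named numeric vector (see [gsea_es()]).
#' @param members character vector: the gene set.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed (deterministic for a fixed seed).
#' @param weight_exponent weight on `|score|`.
#' @return list with `es`, `perm_p`, `n_perm`.
#' @export
gsea_permutation_p <- function(ranked, members, n_perm = 999, seed = 1L,
                               weight_exponent = 1) {
  assert_that(n_perm >= 100, "n_perm must be >= 100")
  es <- as.numeric(gsea_es(ranked, members, weight_exponent))
  ids <- names(ranked)
  K <- sum(ids %in% members)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm_members <- sample(ids, K)
    es_b <- as.numeric(gsea_es(ranked, perm_members, weight_exponent))
    if (abs(es_b) >= abs(es)) exceed <- exceed + 1L
  }
  list(es = es, perm_p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}
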