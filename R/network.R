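#' Undirected feature-level interaction network
#'
#' A light container for a protein-protein (or generic feature-level)
#' interaction network: a node set and an undirected edge table with an
#' optional confidence score in `[0, 1]`. Edges are stored in canonical
#' form (`from < to`, sorted); self-edges and duplicate edges are
#' rejected.
#'
#' @param edges data frame with columns `from`, `to` and optionally
#'   `score`; may be `NULL` for an edgeless network.
#' @param nodes character vector of node ids; defaults to the union of
#'   edge endpoints. Extra isolated nodes are allowed.
#' @return an `interaction_network`.
#' @export
interaction_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  }
  if (is.null(edges$score)) edges$score <- rep(NA_real_, nrow(edges))
  assert_that(!any(edges$from == edges$to), "self-edges are not permitted")
  edges <- canonical_edges(edges$from, edges$to,
                           data.frame(score = edges$score))
  key <- paste(edges$from, edges$to, sep = "\r")
  assert_that(!anyDuplicated(key), "duplicate edges are not permitted")
  sc <- edges$score[!is.na(edges$score)]
  assert_that(all(sc >= 0 & sc <= 1), "edge scores must lie in [0, 1]")
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  assert_that(all(c(edges$from, edges$to) %in% nodes),
              "every edge endpoint must be a node")
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read / write an interaction network as a 3-column TSV edge list
#'
#' Columns `from`, `to`, `score`.
#'
#' @param net an [interaction_network()].
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network` an
#'   `interaction_network`.
#' @export
write_network <- function(net, path) {
  write_tsv(net$edges, path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  interaction_network(read_tsv(path))
}

#' Induced differential subnetwork
#'
#' Restricts an interaction network to the union of differentially
#' expressed genes and proteins, keeping only edges whose confidence
#' score reaches `min_score` (edges without a score always pass).
#' Selected nodes present in the network but left without any passing
#' edge are retained and flagged in the `"isolated"` attribute.
#'
#' @param net an [interaction_network()].
#' @param deg,dep character vectors of differential transcript / protein
#'   feature ids (already on a common id space; see [concordant_nodes()]).
#' @param min_score minimum edge confidence in `[0, 1]`.
#' @return an `interaction_network` on `deg` U `dep`; attribute
#'   `"isolated"` lists retained nodes with degree 0.
#' @export
differential_subnetwork <- function(net, deg, dep, min_score = 0.4) {
  assert_that(min_score >= 0 && min_score <= 1,
              "min_score must lie in [0, 1]")
  sel <- union(deg, dep)
  if (length(sel) == 0) {
    warning("empty differential set; returning an empty network")
    return(interaction_network())
  }
  nodes <- intersect(net$nodes, sel)
  e <- net$edges
  keep <- e$from %in% nodes & e$to %in% nodes &
    (is.na(e$score) | e$score >= min_score)
  sub <- interaction_network(e[keep, , drop = FALSE], nodes = nodes)
  deg_tab <- node_degree(sub)
  attr(sub, "isolated") <- names(deg_tab)[deg_tab == 0]
  sub
}

#' Features differential at both transcript and protein level
#'
#' Intersects a differential-gene set with a differential-protein set
#' after translating protein ids onto transcript ids through a mapping
#' table. These concordant features act as the central nodes of the
#' integrated network. Protein ids without a mapping entry are reported
#' in the `"unmapped"` attribute and excluded.
#'
#' @param deg character vector of differential transcript ids.
#' @param dep character vector of differential protein ids.
#' @param mapping optional data frame with columns `protein_id`,
#'   `transcript_id`; `NULL` means identity mapping.
#' @return character vector of concordant (transcript-space) ids, with an
#'   `"unmapped"` attribute.
#' @export
concordant_nodes <- function(deg, dep, mapping = NULL) {
  if (is.null(mapping)) {
    mapped <- dep
    unmapped <- character(0)
  } else {
    idx <- match(dep, mapping$protein_id)
    unmapped <- dep[is.na(idx)]
    mapped <- mapping$transcript_id[idx[!is.na(idx)]]
    if (length(unmapped)) {
      warning(length(unmapped), " protein id(s) without a transcript mapping",
              " were excluded")
    }
  }
  out <- sort(intersect(deg, mapped))
  attr(out, "unmapped") <- unmapped
  out
}

#' Node degrees of an interaction network
#'
#' Number of distinct neighbours per node; isolated nodes report 0. The
#' degrees satisfy the handshake identity: their sum is twice the edge
#' count.
#'
#' @param net an [interaction_network()].
#' @return named integer vector over all nodes.
#' @export
node_degree <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$from, net$edges$to))
    d[names(tab)] <- as.integer(tab)
  }
  d
}
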