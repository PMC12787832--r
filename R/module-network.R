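#' Assign network nodes to pathway modules
#'
#' Maps each node of an interaction network onto KEGG-style pathway
#' modules from a [gene_sets()] annotation. Three policies:
#' * `unique_lexicographic`: a multi-pathway node takes the
#'   lexicographically smallest pathway id (deterministic default);
#' * `unique_smallest_set`: it takes its smallest annotated pathway
#'   (ties broken lexicographically);
#' * `multi`: all annotated pathways are kept.
#' Nodes without any annotation are listed in `unassigned`.
#'
#' @param nodes character vector of node ids.
#' @param annotation a [gene_sets()] collection.
#' @param policy assignment policy.
#' @return a `module_assignment`: list with `mapping` (named list node ->
#'   character vector of pathway ids; length 1 under unique policies),
#'   `policy`, `unassigned`.
#' @export
assign_modules <- function(nodes, annotation,
                           policy = c("unique_lexicographic",
                                      "unique_smallest_set", "multi")) {
  policy <- match.arg(policy)
  inv <- membership_of(annotation)
  sizes <- vapply(set_members(annotation), length, integer(1))
  mapping <- list()
  unassigned <- character(0)
  for (nd in nodes) {
    pw <- inv[[nd]]
    if (is.null(pw) || length(pw) == 0) {
      unassigned <- c(unassigned, nd)
      next
    }
    pw <- sort(unique(pw))
    mapping[[nd]] <- switch(policy,
      unique_lexicographic = pw[1],
      unique_smallest_set = pw[order(sizes[pw], pw)][1],
      multi = pw)
  }
  structure(list(mapping = mapping, policy = policy,
                 unassigned = sort(unassigned)),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> policy=%s: %d assigned, %d unassigned\n",
              x$policy, length(x$mapping), length(x$unassigned)))
  invisible(x)
}

# Build a module_network object from raw support counts.
new_module_network <- function(modules, cross, self_support, dropped) {
  edges <- if (length(cross)) {
    parts <- strsplit(names(cross), "\r", fixed = TRUE)
    canonical_edges(vapply(parts, `[[`, character(1), 1),
                    vapply(parts, `[[`, character(1), 2),
                    data.frame(weight = as.integer(unname(cross))))
  } else {
    data.frame(from = character(0), to = character(0), weight = integer(0))
  }
  modules <- sort(modules)
  degree <- stats::setNames(integer(length(modules)), modules)
  if (nrow(edges)) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  ss <- stats::setNames(integer(length(modules)), modules)
  if (length(self_support)) ss[names(self_support)] <- as.integer(self_support)
  structure(list(modules = modules, edges = edges, self_support = ss,
                 degree = degree, dropped_edges = dropped),
            class = "module_network")
}

#' Contract an interaction network into a functional-module network
#'
#' The quotient-graph construction: every node of the interaction
#' network is replaced by its pathway module, and two modules are
#' connected if at least one node-level edge joins a constituent of one
#' to a constituent of the other. Parallel (redundant) module edges are
#' collapsed into a single edge whose `weight` counts the supporting
#' node-level edges; within-module node edges are tallied separately as
#' `self_support` rather than drawn as self-loops. Under the `multi`
#' policy a node edge contributes one unit of support to module pair
#' `{P, Q}` for every ordered pathway combination `(p_u, p_v)` with
#' `{p_u, p_v} = {P, Q}`. Node edges with an unassigned endpoint are
#' dropped and counted in `dropped_edges`.
#'
#' Module degree is the number of distinct neighbouring modules
#' (self-support does not contribute), so the degree sum equals twice
#' the module edge count.
#'
#' @param net an [interaction_network()].
#' @param assignment a [assign_modules()] result.
#' @return a `module_network`: list with `modules`, `edges`
#'   (`from`/`to`/`weight`), `self_support`, `degree`, `dropped_edges`.
#' @export
contract <- function(net, assignment) {
  map <- assignment$mapping
  cross <- integer(0)
  self_support <- integer(0)
  dropped <- 0L
  e <- net$edges
  if (nrow(e)) {
    mu <- map[e$from]
    mv <- map[e$to]
    assigned <- !vapply(mu, is.null, logical(1)) &
                !vapply(mv, is.null, logical(1))
    dropped <- sum(!assigned)
    mu <- mu[assigned]; mv <- mv[assigned]
    if (length(mu)) {
      # expand each node edge into its ordered pathway combinations
      reps_u <- lengths(mu); reps_v <- lengths(mv)
      pu <- unlist(mapply(function(p, k) rep(p, each = k), mu, reps_v,
                          SIMPLIFY = FALSE), use.names = FALSE)
      pv <- unlist(mapply(function(p, k) rep(p, times = k), mv, reps_u,
                          SIMPLIFY = FALSE), use.names = FALSE)
      same <- pu == pv
      if (any(same)) {
        tab <- table(pu[same])
        self_support <- stats::setNames(as.integer(tab), names(tab))
      }
      if (any(!same)) {
        a <- pmin(pu[!same], pv[!same])
        b <- pmax(pu[!same], pv[!same])
        tab <- table(paste(a, b, sep = "\r"))
        cross <- stats::setNames(as.integer(tab), names(tab))
      }
    }
  }
  modules <- unique(unlist(map, use.names = FALSE)) %||% character(0)
  new_module_network(modules, cross, self_support, dropped)
}

#' Brute-force contraction oracle
#'
#' Independent verifier for [contract()]: for every unordered module
#' pair it scans all node-level edges and counts the ones connecting the
#' two modules, and likewise tallies within-module support per module,
#' by direct pairwise enumeration. Intended for test-scale networks
#' (up to a few hundred nodes); must agree with [contract()] exactly.
#'
#' @inheritParams contract
#' @return a `module_network`.
#' @export
contraction_oracle <- function(net, assignment) {
  map <- assignment$mapping
  modules <- sort(unique(unlist(map, use.names = FALSE)) %||% character(0))
  e <- net$edges
  dropped <- 0L
  cross <- integer(0)
  self_support <- stats::setNames(integer(length(modules)), modules)
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      mu <- map[[e$from[i]]]
      mv <- map[[e$to[i]]]
      if (is.null(mu) || is.null(mv)) dropped <- dropped + 1L
    }
  }
  if (length(modules)) {
    # within-module support: scan every edge for each module, counting the
    # ordered pathway combination (P, P)
    for (P in modules) {
      cnt <- 0L
      if (nrow(e)) for (i in seq_len(nrow(e))) {
        mu <- map[[e$from[i]]]; mv <- map[[e$to[i]]]
        if (is.null(mu) || is.null(mv)) next
        cnt <- cnt + (P %in% mu) * (P %in% mv)
      }
      self_support[P] <- cnt
    }
    # cross-module support: scan every unordered module pair
    if (length(modules) >= 2) {
      for (ii in seq_len(length(modules) - 1)) {
        for (jj in (ii + 1):length(modules)) {
          P <- modules[ii]; Q <- modules[jj]
          cnt <- 0L
          if (nrow(e)) for (i in seq_len(nrow(e))) {
            mu <- map[[e$from[i]]]; mv <- map[[e$to[i]]]
            if (is.null(mu) || is.null(mv)) next
            cnt <- cnt + (P %in% mu) * (Q %in% mv) + (Q %in% mu) * (P %in% mv)
          }
          if (cnt > 0) cross[paste(P, Q, sep = "\r")] <- cnt
        }
      }
    }
  }
  new_module_network(modules, cross, self_support, dropped)
}

#' @export
print.module_network <- function(x, ...) {
  cat(sprintf(
    "<module_network> %d modules, %d edges (%d dropped node edges)\n",
    length(x$modules), nrow(x$edges), x$dropped_edges))
  invisible(x)
}

#' Rank modules by connectivity degree
#'
#' Orders the modules of a contracted network by decreasing connectivity:
#' either the unweighted degree (number of distinct neighbouring modules)
#' or the weighted degree (sum of incident edge weights, i.e. supporting
#' node-level cross edges). Ties are broken by lexicographic module id,
#' making the ranking deterministic.
#'
#' @param mn a `module_network` from [contract()].
#' @param by `"degree"` or `"weighted_degree"`.
#' @return data frame `module`, `value` in rank order.
#' @export
rank_modules <- function(mn, by = c("degree", "weighted_degree")) {
  by <- match.arg(by)
  if (by == "degree") {
    val <- mn$degree
  } else {
    val <- stats::setNames(numeric(length(mn$modules)), mn$modules)
    if (nrow(mn$edges)) {
      for (i in seq_len(nrow(mn$edges))) {
        val[mn$edges$from[i]] <- val[mn$edges$from[i]] + mn$edges$weight[i]
        val[mn$edges$to[i]] <- val[mn$edges$to[i]] + mn$edges$weight[i]
      }
    }
  }
  ord <- order(-val, names(val))
  out <- data.frame(module = names(val)[ord], value = unname(val[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a module network to TSV files
#'
#' Writes the module edge list (`module_a`, `module_b`, `weight`) and a
#' degree table (`module`, `degree`, `weighted_degree`, `self_support`).
#'
#' @param mn a `module_network`.
#' @param edges_path,degree_path output file paths.
#' @return invisibly, a list of the two paths.
#' @export
write_module_network <- function(mn, edges_path, degree_path) {
  e <- mn$edges
  names(e) <- c("module_a", "module_b", "weight")
  write_tsv(e, edges_path)
  wd <- rank_modules(mn, "weighted_degree")
  wmap <- stats::setNames(wd$value, wd$module)
  deg <- data.frame(module = mn$modules,
                    degree = unname(mn$degree[mn$modules]),
                    weighted_degree = unname(wmap[mn$modules]),
                    self_support = unname(mn$self_support[mn$modules]),
                    stringsAsFactors = FALSE)
  write_tsv(deg, degree_path)
  invisible(list(edges = edges_path, degree = degree_path))
}
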