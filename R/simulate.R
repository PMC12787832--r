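#' Planted ground truth for synthetic multi-omics data
#'
#' Records everything downstream recovery tests need to know about a
#' simulated dataset: which features carry a differential effect in each
#' contrast (and its signed log2 magnitude), which pathway modules each
#' feature belongs to, the intra- and inter-module edge densities of the
#' interaction network, and which module is planted as the
#' high-connectivity hub.
#'
#' @param feature_ids character vector: the feature universe.
#' @param de named list, one element per contrast (name `"T2_vs_T0"`
#'   style); each element a named numeric vector of nonzero signed log2
#'   effect sizes, names being feature ids.
#' @param membership named list feature id -> character vector of pathway
#'   ids (features absent from the list are unannotated).
#' @param intra_density,inter_density edge probabilities in `[0, 1]` for
#'   feature pairs that do / do not share a pathway.
#' @param hub_module pathway id planted to receive elevated inter-module
#'   connectivity, or `NULL`.
#' @param hub_factor multiplier applied to `inter_density` for edges
#'   touching hub-module members.
#' @return a `synthetic_truth` object.
#' @export
synthetic_truth <- function(feature_ids, de = list(), membership = list(),
                            intra_density = 0.3, inter_density = 0.05,
                            hub_module = NULL, hub_factor = 3) {
  for (eff in de) {
    assert_that(all(eff != 0), "planted effect sizes must be nonzero")
    assert_that(all(names(eff) %in% feature_ids),
                "DE features must belong to the feature universe")
  }
  assert_that(intra_density >= 0 && intra_density <= 1 &&
              inter_density >= 0 && inter_density <= 1,
              "edge densities must lie in [0, 1]")
  assert_that(all(names(membership) %in% feature_ids),
              "membership keys must belong to the feature universe")
  if (!is.null(hub_module)) {
    assert_that(hub_module %in% unlist(membership, use.names = FALSE),
                "hub_module must appear among the membership pathways")
  }
  structure(list(feature_ids = feature_ids, de = de, membership = membership,
                 intra_density = intra_density, inter_density = inter_density,
                 hub_module = hub_module, hub_factor = hub_factor),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d features, %d contrasts with planted effects, %d annotated\n",
    length(x$feature_ids), length(x$de), length(x$membership)))
  invisible(x)
}

#' Generate a random planted truth
#'
#' Draws a feature universe, assigns a block of features to equally sized
#' pathway modules (optionally giving a fraction of them a second
#' pathway), plants signed differential effects per contrast, and
#' designates one module as the connectivity hub.
#'
#' @param n_features size of the feature universe.
#' @param prefix feature id prefix.
#' @param contrasts list of 2-vectors `c(test, reference)`.
#' @param n_de number of DE features planted per contrast.
#' @param effect_size absolute log2 effect of planted features.
#' @param n_modules,module_size pathway-module layout; modules partition
#'   the first `n_modules * module_size` features.
#' @param multi_frac fraction of annotated features given a second pathway.
#' @param intra_density,inter_density,hub_factor see [synthetic_truth()].
#' @param plant_hub if `TRUE`, a random module becomes the hub.
#' @param de_include_hub if `TRUE` (and a hub is planted), the hub
#'   module's members are part of every contrast's planted DE set, so the
#'   high-connectivity module is carried by differential features — the
#'   structure that makes concordant differential nodes central in the
#'   integrated network.
#' @param seed integer seed.
#' @return a [synthetic_truth()].
#' @export
simulate_truth <- function(n_features = 500, prefix = "g",
                           contrasts = list(c("T2", "T0"), c("T4", "T0")),
                           n_de = 50, effect_size = 2,
                           n_modules = 8, module_size = 12,
                           multi_frac = 0, intra_density = 0.3,
                           inter_density = 0.05, hub_factor = 3,
                           plant_hub = TRUE, de_include_hub = TRUE,
                           seed = 1L) {
  assert_that(n_modules * module_size <= n_features,
              "module layout exceeds the feature universe")
  set.seed(seed)
  ids <- sprintf("%s%05d", prefix, seq_len(n_features))
  pathways <- sprintf("Map%05d", seq_len(n_modules))
  membership <- list()
  if (n_modules > 0) {
    assigned <- ids[seq_len(n_modules * module_size)]
    primary <- rep(pathways, each = module_size)
    membership <- stats::setNames(as.list(primary), assigned)
    if (multi_frac > 0) {
      extra <- assigned[stats::runif(length(assigned)) < multi_frac]
      for (f in extra) {
        other <- setdiff(pathways, membership[[f]])
        if (length(other)) {
          membership[[f]] <- c(membership[[f]], sample(other, 1L))
        }
      }
    }
  }
  hub <- if (plant_hub && n_modules > 0) sample(pathways, 1L) else NULL
  hub_members <- if (!is.null(hub) && de_include_hub) {
    names(membership)[vapply(membership, function(pw) hub %in% pw,
                             logical(1))]
  } else character(0)
  de <- list()
  for (ct in contrasts) {
    n_extra <- max(0L, min(n_de, n_features) - length(hub_members))
    feats <- c(hub_members, sample(setdiff(ids, hub_members), n_extra))
    eff <- effect_size * sample(c(-1, 1), length(feats), replace = TRUE)
    de[[paste0(ct[1], "_vs_", ct[2])]] <- stats::setNames(eff, feats)
  }
  synthetic_truth(ids, de = de, membership = membership,
                  intra_density = intra_density,
                  inter_density = inter_density,
                  hub_module = hub, hub_factor = hub_factor)
}

# Expected (noise-free) log2 level of every feature in every group:
# per-feature baseline plus the planted effect of any contrast whose test
# group is that group (effects are expressed against the reference
# baseline shared by all groups).
expected_log2 <- function(truth, groups, base_log2) {
  out <- matrix(rep(base_log2, length(groups)),
                nrow = length(truth$feature_ids),
                dimnames = list(truth$feature_ids, groups))
  for (ct in names(truth$de)) {
    parts <- strsplit(ct, "_vs_", fixed = TRUE)[[1]]
    test <- parts[1]
    if (test %in% groups) {
      eff <- truth$de[[ct]]
      out[names(eff), test] <- out[names(eff), test] + eff
    }
  }
  out
}

#' Simulate one omics layer
#'
#' Draws a feature-by-sample matrix consistent with a planted truth.
#' Transcripts are overdispersed counts (negative binomial in the
#' mean/dispersion parameterization); proteins and metabolites are
#' mean-exact log-normal intensities with a given coefficient of
#' variation, so the expected group-mean ratio of a planted feature equals
#' its planted fold change exactly. Pooled-QC injections are technical
#' replicates of the grand mean across groups with their own (small) CV.
#' Metabolite matrices may contain missing values at a stated overall
#' rate, preferentially at low intensity.
#'
#' @param design a [sample_design()].
#' @param truth a [synthetic_truth()].
#' @param n_features number of features to simulate (>= number of planted
#'   DE features); defaults to the truth's full universe.
#' @param noise list of noise settings: `dispersion` (transcript NB
#'   dispersion; 0 gives Poisson), `cv` (protein/metabolite biological
#'   CV), `qc_cv` (QC technical CV), `missing_rate` (metabolite overall
#'   missingness in `[0, 1)`), `base_log2_mean`, `base_log2_sd` (baseline
#'   abundance distribution), `frac_unstable` and `unstable_cv` (fraction
#'   of features given an inflated QC CV, and that CV).
#' @param seed integer seed.
#' @return an [omics_matrix()] at stage `"raw"`. Attributes:
#'   `"unstable_features"` (ids planted with inflated QC CV) and
#'   `"base_log2"` (baseline vector).
#' @export
simulate_layer <- function(design, truth, n_features = NULL,
                           noise = list(), seed = 1L) {
  layer <- attr(design, "layer")
  defaults <- list(dispersion = 0.1, cv = 0.2, qc_cv = 0.05,
                   missing_rate = 0,
                   base_log2_mean = switch(layer, transcript = 6,
                                           protein = 20, metabolite = 16),
                   base_log2_sd = 1.5, frac_unstable = 0, unstable_cv = 1.0)
  noise <- utils::modifyList(defaults, noise)
  n_de <- length(unique(unlist(lapply(truth$de, names))))
  n_features <- n_features %||% length(truth$feature_ids)
  assert_that(n_features >= n_de,
              "n_features must cover all planted DE features")
  if (noise$missing_rate < 0 || noise$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  ids <- truth$feature_ids
  if (n_features < length(ids)) {
    # keep every DE feature, then truncate the tail of the universe
    de_ids <- unique(unlist(lapply(truth$de, names)))
    keep <- unique(c(de_ids, ids))[seq_len(n_features)]
    ids <- ids[ids %in% keep]
  } else if (n_features > length(ids)) {
    ids <- c(ids, sprintf("x%05d", seq_len(n_features - length(ids))))
  }
  truth_local <- truth
  truth_local$feature_ids <- ids
  groups <- unique(stats::na.omit(design$group))
  base <- stats::rnorm(length(ids), noise$base_log2_mean, noise$base_log2_sd)
  mu_log2 <- expected_log2(truth_local, groups, base)   # features x groups
  mu <- 2^mu_log2

  samples <- design$sample_id
  vals <- matrix(NA_real_, length(ids), length(samples),
                 dimnames = list(ids, samples))
  unstable <- character(0)
  if (noise$frac_unstable > 0) {
    unstable <- ids[stats::runif(length(ids)) < noise$frac_unstable]
  }
  qc_cv_vec <- rep(noise$qc_cv, length(ids))
  qc_cv_vec[ids %in% unstable] <- noise$unstable_cv

  lognorm <- function(mean_val, cv) {
    # mean-exact multiplicative noise: E[value] = mean_val for any cv
    if (all(cv == 0)) return(mean_val)
    s <- sqrt(log(1 + cv^2))
    mean_val * exp(stats::rnorm(length(mean_val), -s^2 / 2, s))
  }

  for (s in samples) {
    i <- match(s, design$sample_id)
    if (design$is_qc[i]) {
      grand <- rowMeans(mu)
      vals[, s] <- lognorm(grand, qc_cv_vec)
    } else {
      m_g <- mu[, design$group[i]]
      if (layer == "transcript") {
        vals[, s] <- if (noise$dispersion > 0) {
          stats::rnbinom(length(m_g), mu = m_g, size = 1 / noise$dispersion)
        } else {
          stats::rpois(length(m_g), m_g)
        }
      } else {
        vals[, s] <- lognorm(m_g, noise$cv)
      }
    }
  }

  if (layer == "metabolite" && noise$missing_rate > 0) {
    # missingness decreasing with intensity: probability proportional to
    # 1 - empirical rank, scaled to the requested overall rate
    u <- rank(vals, ties.method = "average") / (length(vals) + 1)
    p_miss <- pmin(0.999, 2 * noise$missing_rate * (1 - u))
    vals[stats::runif(length(vals)) < p_miss] <- NA_real_
  }

  out <- omics_matrix(vals, layer = layer, stage = "raw")
  attr(out, "unstable_features") <- unstable
  attr(out, "base_log2") <- stats::setNames(base, ids)
  out
}

#' Simulate an interaction network with planted module structure
#'
#' Draws an undirected feature-level network: each feature pair receives
#' an edge independently with probability `intra_density` if the two
#' features share a pathway and `inter_density` otherwise; pairs touching
#' a member of the planted hub module (without sharing a pathway) use
#' `inter_density * hub_factor`, capped at 1. Edges carry a uniform
#' confidence score in `[0, 1]`. No self-edges, no duplicate edges.
#'
#' @param truth a [synthetic_truth()].
#' @param n_features optional number of features (defaults to the truth's
#'   universe; must not exceed it).
#' @param seed integer seed.
#' @return list with elements `network` (an [interaction_network()]) and
#'   `gene_sets` (the pathway annotation as a [gene_sets()] collection).
#' @export
simulate_network <- function(truth, n_features = NULL, seed = 1L) {
  set.seed(seed)
  ids <- truth$feature_ids
  if (!is.null(n_features)) {
    assert_that(n_features <= length(ids),
                "n_features exceeds the truth's feature universe")
    ids <- ids[seq_len(n_features)]
  }
  mem <- truth$membership[names(truth$membership) %in% ids]
  gs <- membership_to_sets(mem)
  if (length(ids) < 2) {
    return(list(network = interaction_network(nodes = ids), gene_sets = gs))
  }
  pairs <- utils::combn(ids, 2)
  a <- pairs[1, ]; b <- pairs[2, ]
  shares <- mapply(function(u, v) {
    pu <- mem[[u]]; pv <- mem[[v]]
    length(pu) > 0 && length(pv) > 0 && length(intersect(pu, pv)) > 0
  }, a, b, USE.NAMES = FALSE)
  p <- ifelse(shares, truth$intra_density, truth$inter_density)
  if (!is.null(truth$hub_module)) {
    hub_members <- names(mem)[vapply(mem, function(pw)
      truth$hub_module %in% pw, logical(1))]
    touches_hub <- (a %in% hub_members) | (b %in% hub_members)
    boost <- touches_hub & !shares
    p[boost] <- pmin(1, p[boost] * truth$hub_factor)
  }
  draw <- stats::runif(length(p)) < p
  score <- round(stats::runif(sum(draw)), 3)
  net <- interaction_network(
    edges = data.frame(from = a[draw], to = b[draw], score = score,
                       stringsAsFactors = FALSE),
    nodes = ids)
  list(network = net, gene_sets = gs)
}

# feature -> pathways list into a gene_sets collection (empty sets dropped)
membership_to_sets <- function(membership) {
  if (length(membership) == 0) return(gene_sets(list()))
  pw <- unlist(membership, use.names = FALSE)
  ft <- rep(names(membership), lengths(membership))
  by_pw <- split(ft, pw)
  gene_sets(lapply(by_pw, function(m)
    list(description = "simulated pathway module", members = sort(unique(m)))))
}
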