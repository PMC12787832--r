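#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full synthetic
#' multi-omics run: the group design, the calling thresholds (defaults
#' are the standard literature thresholds used throughout the package:
#' |log2FC| >= 1, FDR < 0.05 for transcripts, raw p < 0.05 for proteins,
#' VIP > 1 with p < 0.05 for metabolites), the preprocessing thresholds
#' (presence >= 0.8, QC RSD <= 0.30), the network confidence cutoff, the
#' module-assignment policy and the simulation settings.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param groups group labels; the first is the reference.
#' @param contrasts list of `c(test, reference)` pairs; default all
#'   groups against the reference and successive treatments against each
#'   other.
#' @param thresholds named list overriding any of `log2fc`, `fdr`, `p`,
#'   `vip`, `min_frac`, `max_rsd`, `min_score`.
#' @param policy module-assignment policy (see [assign_modules()]).
#' @param var_equal use the pooled-variance Student t instead of Welch.
#' @param rank_by module ranking statistic (see [rank_modules()]).
#' @param sim named list overriding simulation settings: `n_features`
#'   (per layer), `n_de`, `effect_size`, `n_modules`, `module_size`,
#'   `reps` (transcript/protein), `reps_met`, `n_qc`, `cv`, `dispersion`,
#'   `qc_cv`, `missing_rate`, `intra_density`, `inter_density`,
#'   `hub_factor`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed = 1L, groups = c("T0", "T2", "T4"),
                       contrasts = NULL, thresholds = list(),
                       policy = "unique_lexicographic",
                       var_equal = FALSE, rank_by = "weighted_degree",
                       sim = list()) {
  thr_def <- list(log2fc = 1, fdr = 0.05, p = 0.05, vip = 1,
                  min_frac = 0.8, max_rsd = 0.30, min_score = 0.4)
  thresholds <- utils::modifyList(thr_def, thresholds)
  assert_that(all(unlist(thresholds) >= 0), "thresholds must be nonnegative")
  sim_def <- list(n_features = 600, n_features_met = 500, n_de = 60,
                  effect_size = 2, n_modules = 8, module_size = 12,
                  reps = 3, reps_met = 6, n_qc = 4, cv = 0.2,
                  dispersion = 0.1, qc_cv = 0.05, missing_rate = 0.15,
                  intra_density = 0.3, inter_density = 0.05, hub_factor = 3)
  sim <- utils::modifyList(sim_def, sim)
  if (is.null(contrasts)) {
    ref <- groups[1]
    contrasts <- lapply(groups[-1], function(g) c(g, ref))
    if (length(groups) >= 3) {
      contrasts <- c(contrasts, list(c(groups[length(groups)], groups[2])))
    }
  }
  for (ct in contrasts) {
    if (!all(ct %in% groups)) {
      stop("contrast references unknown group(s): ",
           paste(setdiff(ct, groups), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), groups = groups,
                 contrasts = contrasts, thresholds = thresholds,
                 policy = policy, var_equal = var_equal, rank_by = rank_by,
                 sim = sim),
            class = "run_config")
}

#' Run the full synthetic multi-omics pipeline
#'
#' Executes the integration chain end to end on simulated data:
#' simulate design, truth, the three omics layers and the interaction
#' network; preprocess the metabolite table through the QC cascade; call
#' differential features per layer and contrast; run over-representation
#' and pre-ranked enrichment on the transcript results; build the
#' differential subnetwork with concordant (transcript-and-protein)
#' central nodes; contract it to the functional-module network and rank
#' modules by connectivity. All artifacts are written as TSV/GMT/JSON
#' under `outdir` (if given) with a provenance sidecar, and two runs with
#' the same configuration produce byte-identical files.
#'
#' @param config a [run_config()].
#' @param outdir output directory, or `NULL` to skip writing.
#' @return a `run_report`: list with per-stage counts, top-ranked
#'   modules per contrast, the planted truth, and all in-memory stage
#'   objects under `$objects`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  s <- config$sim
  thr <- config$thresholds
  warnings_seen <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # --- simulate ---------------------------------------------------------
  truth <- simulate_truth(
    n_features = s$n_features, prefix = "g",
    contrasts = config$contrasts, n_de = s$n_de,
    effect_size = s$effect_size, n_modules = s$n_modules,
    module_size = s$module_size, intra_density = s$intra_density,
    inter_density = s$inter_density, hub_factor = s$hub_factor,
    seed = derive_seed(config$seed, "truth"))
  truth_met <- simulate_truth(
    n_features = s$n_features_met, prefix = "m",
    contrasts = config$contrasts, n_de = s$n_de,
    effect_size = s$effect_size, n_modules = 0, module_size = 0,
    plant_hub = FALSE, seed = derive_seed(config$seed, "truth") + 1L)

  design_tx <- simulate_design(config$groups, s$reps, 0, "transcript")
  design_pr <- simulate_design(config$groups, s$reps, 0, "protein")
  design_met <- simulate_design(config$groups, s$reps_met, s$n_qc,
                                "metabolite")

  m_tx <- simulate_layer(design_tx, truth,
                         noise = list(dispersion = s$dispersion),
                         seed = derive_seed(config$seed, "transcript"))
  m_pr <- simulate_layer(design_pr, truth, noise = list(cv = s$cv),
                         seed = derive_seed(config$seed, "protein"))
  m_met <- simulate_layer(design_met, truth_met,
                          noise = list(cv = s$cv, qc_cv = s$qc_cv,
                                       missing_rate = s$missing_rate),
                          seed = derive_seed(config$seed, "metabolite"))
  netgmt <- simulate_network(truth, seed = derive_seed(config$seed, "network"))

  # --- preprocess -------------------------------------------------------
  m_met_final <- wh(preprocess_metabolites(
    m_met, design_met, min_frac = thr$min_frac, max_rsd = thr$max_rsd))

  # --- differential -----------------------------------------------------
  diff_tables <- list()
  for (ct in config$contrasts) {
    key <- paste0(ct[1], "_vs_", ct[2])
    diff_tables[[key]] <- list(
      transcript = wh(differential_analysis(
        m_tx, design_tx, ct, var_equal = config$var_equal,
        lfc = thr$log2fc, alpha = thr$fdr)),
      protein = wh(differential_analysis(
        m_pr, design_pr, ct, var_equal = config$var_equal,
        lfc = thr$log2fc, alpha = thr$p)),
      metabolite = wh(differential_analysis(
        m_met_final, design_met, ct, var_equal = config$var_equal,
        lfc = thr$log2fc, alpha = thr$p, vip_min = thr$vip)))
  }

  # --- enrichment -------------------------------------------------------
  enrich <- list()
  for (key in names(diff_tables)) {
    tx <- diff_tables[[key]]$transcript
    selected <- differential_features(tx)
    universe <- tx$feature
    ora <- if (length(selected)) {
      hypergeom_enrich(selected, universe, netgmt$gene_sets)
    } else NULL
    ranked <- sort(stats::setNames(tx$log2fc, tx$feature),
                   decreasing = TRUE)
    gsea <- lapply(names(netgmt$gene_sets), function(id) {
      members <- netgmt$gene_sets[[id]]$members
      if (!any(names(ranked) %in% members)) return(NULL)
      res <- gsea_permutation_p(ranked, members, n_perm = 199,
                                seed = derive_seed(config$seed, "gsea"))
      data.frame(set_id = id, es = res$es, perm_p = res$perm_p,
                 stringsAsFactors = FALSE)
    })
    gsea <- do.call(rbind, gsea)
    enrich[[key]] <- list(ora = ora, gsea = gsea)
  }

  # --- network integration and contraction ------------------------------
  network_results <- list()
  for (key in names(diff_tables)) {
    deg <- differential_features(diff_tables[[key]]$transcript)
    dep <- differential_features(diff_tables[[key]]$protein)
    subnet <- wh(differential_subnetwork(netgmt$network, deg, dep,
                                         min_score = thr$min_score))
    conc <- concordant_nodes(deg, dep)
    assignment <- assign_modules(subnet$nodes, netgmt$gene_sets,
                                 policy = config$policy)
    mn <- contract(subnet, assignment)
    ranking <- rank_modules(mn, by = config$rank_by)
    network_results[[key]] <- list(subnetwork = subnet, concordant = conc,
                                   assignment = assignment,
                                   module_network = mn, ranking = ranking)
  }

  report <- build_report(config, truth, diff_tables, enrich,
                         network_results, m_met, m_met_final,
                         warnings_seen)
  objects <- list(truth = truth, truth_met = truth_met,
                  designs = list(transcript = design_tx,
                                 protein = design_pr,
                                 metabolite = design_met),
                  matrices = list(transcript = m_tx, protein = m_pr,
                                  metabolite_raw = m_met,
                                  metabolite = m_met_final),
                  network = netgmt$network, gene_sets = netgmt$gene_sets,
                  differential = diff_tables, enrichment = enrich,
                  networks = network_results)
  report$objects <- objects

  if (!is.null(outdir)) write_run_artifacts(report, outdir)
  report
}

build_report <- function(config, truth, diff_tables, enrich,
                         network_results, m_met_raw, m_met_final,
                         warnings_seen) {
  counts <- list()
  for (key in names(diff_tables)) {
    counts[[key]] <- lapply(diff_tables[[key]], function(tb)
      c(up = sum(tb$call == "up"), down = sum(tb$call == "down"),
        total = nrow(tb)))
  }
  top_modules <- lapply(network_results, function(nr)
    utils::head(nr$ranking, 5))
  structure(list(
    config = config,
    counts = counts,
    metabolite_features = c(raw = nrow(m_met_raw$values),
                            final = nrow(m_met_final$values)),
    top_modules = top_modules,
    hub_module = truth$hub_module,
    warnings = warnings_seen), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  metabolite features: %d raw -> %d after QC cascade\n",
              x$metabolite_features["raw"], x$metabolite_features["final"]))
  for (key in names(x$counts)) {
    cc <- x$counts[[key]]
    cat(sprintf("  %s: DEG %d/%d, DEP %d/%d, diff metabolites %d/%d\n",
                key,
                cc$transcript["up"] + cc$transcript["down"], cc$transcript["total"],
                cc$protein["up"] + cc$protein["down"], cc$protein["total"],
                cc$metabolite["up"] + cc$metabolite["down"], cc$metabolite["total"]))
    top <- x$top_modules[[key]]
    cat(sprintf("    top modules: %s\n",
                paste(sprintf("%s(%g)", top$module, top$value), collapse = ", ")))
  }
  if (!is.null(x$hub_module)) {
    cat(sprintf("  planted hub module: %s\n", x$hub_module))
  }
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s) recorded\n", length(x$warnings)))
  }
  invisible(x)
}

write_run_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  obj <- report$objects
  for (ly in names(obj$designs)) {
    write_design(obj$designs[[ly]], file.path(outdir, paste0("design_", ly, ".tsv")))
  }
  write_omics_matrix(obj$matrices$transcript,
                     file.path(outdir, "matrix_transcript.tsv"))
  write_omics_matrix(obj$matrices$protein,
                     file.path(outdir, "matrix_protein.tsv"))
  write_omics_matrix(obj$matrices$metabolite_raw,
                     file.path(outdir, "matrix_metabolite_raw.tsv"))
  write_omics_matrix(obj$matrices$metabolite,
                     file.path(outdir, "matrix_metabolite_processed.tsv"))
  write_network(obj$network, file.path(outdir, "network.tsv"))
  write_gmt(obj$gene_sets, file.path(outdir, "pathways.gmt"))
  prov <- attr(obj$matrices$metabolite, "provenance")
  jsonlite::write_json(prov, file.path(outdir, "preprocess_provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (key in names(obj$differential)) {
    for (ly in names(obj$differential[[key]])) {
      write_tsv(as.data.frame(obj$differential[[key]][[ly]]),
                file.path(outdir, sprintf("differential_%s_%s.tsv", ly, key)))
    }
    nr <- obj$networks[[key]]
    write_network(nr$subnetwork,
                  file.path(outdir, sprintf("subnetwork_%s.tsv", key)))
    write_module_network(nr$module_network,
                         file.path(outdir, sprintf("module_edges_%s.tsv", key)),
                         file.path(outdir, sprintf("module_degree_%s.tsv", key)))
    write_tsv(nr$ranking,
              file.path(outdir, sprintf("module_ranking_%s.tsv", key)))
    en <- obj$enrichment[[key]]
    if (!is.null(en$ora)) {
      write_tsv(en$ora, file.path(outdir, sprintf("ora_%s.tsv", key)))
    }
    if (!is.null(en$gsea)) {
      write_tsv(en$gsea, file.path(outdir, sprintf("gsea_%s.tsv", key)))
    }
  }
  cfg <- report$config
  cfg_out <- list(seed = cfg$seed, groups = cfg$groups,
                  contrasts = cfg$contrasts, thresholds = cfg$thresholds,
                  policy = cfg$policy, var_equal = cfg$var_equal,
                  rank_by = cfg$rank_by, sim = cfg$sim)
  jsonlite::write_json(cfg_out, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  counts_out <- report$counts
  jsonlite::write_json(
    list(counts = counts_out,
         metabolite_features = as.list(report$metabolite_features),
         hub_module = report$hub_module),
    file.path(outdir, "run_report.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
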