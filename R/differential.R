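#' Per-feature log2 fold change
#'
#' Ratio of group means on the raw intensity scale,
#' `log2((mean_test + pseudocount) / (mean_ref + pseudocount))`. For a
#' log10-transformed matrix (stage `"logged"`) the equivalent quantity is
#' computed as the difference of group means divided by `log10(2)`, which
#' is the log2 ratio of the geometric means on the raw scale.
#'
#' @param m an [omics_matrix()].
#' @param design the matching [sample_design()].
#' @param contrast `c(test_group, ref_group)`.
#' @param pseudocount nonnegative stabilizer added to both means (ignored
#'   for logged matrices).
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(m, design, contrast, pseudocount = 0) {
  assert_that(pseudocount >= 0, "pseudocount must be nonnegative")
  ids_test <- intersect(group_samples(design, contrast[1]), colnames(m$values))
  ids_ref <- intersect(group_samples(design, contrast[2]), colnames(m$values))
  assert_that(length(ids_test) >= 2 && length(ids_ref) >= 2,
              "both groups need >= 2 replicates")
  mt <- rowMeans(m$values[, ids_test, drop = FALSE])
  mr <- rowMeans(m$values[, ids_ref, drop = FALSE])
  if (m$stage == "logged") {
    return((mt - mr) / log10(2))
  }
  if (pseudocount == 0 && any(mr == 0 | mt == 0)) {
    stop("zero group mean with pseudocount 0; supply a positive pseudocount",
         call. = FALSE)
  }
  log2((mt + pseudocount) / (mr + pseudocount))
}

#' Row-wise two-sample t-test
#'
#' Vectorized two-sided t-test per feature between two groups, either
#' Welch (default) or pooled-variance Student. Degenerate rows with zero
#' variance in both groups and equal means return p = 1 by convention
#' (with a warning); zero variance with unequal means yields the smallest
#' representable positive p.
#'
#' @param m an [omics_matrix()].
#' @param design the matching [sample_design()].
#' @param contrast `c(test_group, ref_group)`.
#' @param var_equal `FALSE` for Welch (default), `TRUE` for Student.
#' @return named numeric vector of two-sided p-values in (0, 1].
#' @export
welch_t <- function(m, design, contrast, var_equal = FALSE) {
  ids_test <- intersect(group_samples(design, contrast[1]), colnames(m$values))
  ids_ref <- intersect(group_samples(design, contrast[2]), colnames(m$values))
  n1 <- length(ids_test); n2 <- length(ids_ref)
  assert_that(n1 >= 2 && n2 >= 2, "both groups need >= 2 replicates")
  x1 <- m$values[, ids_test, drop = FALSE]
  x2 <- m$values[, ids_ref, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    eq <- degenerate & (m1 == m2)
    if (any(eq)) {
      warning(sum(eq), " feature(s) with zero variance and equal means: ",
              "p = 1 by convention")
      p[eq] <- 1
    }
    p[degenerate & !eq] <- .Machine$double.xmin
  }
  p <- pmax(p, .Machine$double.xmin)
  stats::setNames(p, rownames(m$values))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `fdr_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in the
#' input order (stable under feature reordering). Thin wrapper over
#' `stats::p.adjust(method = "BH")`, the canonical implementation of the
#' step-up procedure; shared by the differential and enrichment modules.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (names preserved).
#' @return numeric vector of adjusted values.
#' @export
bh_adjust <- function(pvals) {
  assert_that(all(pvals >= 0 & pvals <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Differential-feature calling rules
#'
#' Applies the per-layer significance rule to a statistics table:
#' * transcript: up if `log2fc >= lfc` and `fdr < alpha`; down if
#'   `log2fc <= -lfc` and `fdr < alpha` (fold boundary inclusive);
#' * protein: same fold rule with the unadjusted `p < alpha`;
#' * metabolite: up/down by the sign of `log2fc` if `vip > vip_min`
#'   (strict) and `p < alpha`.
#' Everything else is `ns`.
#'
#' @param table data frame with columns `feature`, `log2fc` and the
#'   statistics the layer's rule needs (`fdr`, `p`, `vip`).
#' @param layer `"transcript"`, `"protein"` or `"metabolite"`.
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @param alpha significance threshold (default 0.05).
#' @param vip_min VIP threshold (default 1, strict).
#' @return the table with a `call` factor column (`up`/`down`/`ns`).
#' @export
call_features <- function(table, layer, lfc = 1, alpha = 0.05, vip_min = 1) {
  layer <- match.arg(layer, c("transcript", "protein", "metabolite"))
  need <- switch(layer, transcript = "fdr", protein = "p",
                 metabolite = c("vip", "p"))
  missing_stat <- setdiff(need, names(table))
  if (length(missing_stat)) {
    stop("layer '", layer, "' requires statistic(s): ",
         paste(missing_stat, collapse = ", "), call. = FALSE)
  }
  call <- rep("ns", nrow(table))
  if (layer == "transcript") {
    sig <- table$fdr < alpha
    call[sig & table$log2fc >= lfc] <- "up"
    call[sig & table$log2fc <= -lfc] <- "down"
  } else if (layer == "protein") {
    sig <- table$p < alpha
    call[sig & table$log2fc >= lfc] <- "up"
    call[sig & table$log2fc <= -lfc] <- "down"
  } else {
    sig <- table$vip > vip_min & table$p < alpha
    call[sig & table$log2fc > 0] <- "up"
    call[sig & table$log2fc < 0] <- "down"
  }
  table$call <- factor(call, levels = c("up", "down", "ns"))
  table
}

#' Differential analysis of one layer and one contrast
#'
#' Computes the statistics the layer's calling rule needs and applies
#' [call_features()]:
#' * transcript: t-test on `log2(x + pseudocount)`, fold change with the
#'   same pseudocount, BH FDR within the contrast;
#' * protein: t-test on `log2(x)`, fold change on the raw scale, raw p;
#' * metabolite: expects the logged matrix from the preprocessing
#'   cascade; t-test on the logged values, fold change from logged group
#'   means, VIP from [pls_vip()].
#'
#' @param m an [omics_matrix()].
#' @param design the matching [sample_design()].
#' @param contrast `c(test_group, ref_group)`.
#' @param pseudocount transcript-layer pseudocount (default 1).
#' @param var_equal `FALSE` for Welch (default), `TRUE` for Student.
#' @param n_components PLS components for the metabolite VIP.
#' @param lfc,alpha,vip_min calling thresholds, see [call_features()].
#' @return a `differential_table`: data frame `feature`, `log2fc`, `p`,
#'   `fdr`, `vip`, `call` with attributes `contrast` and `layer`.
#' @export
differential_analysis <- function(m, design, contrast, pseudocount = 1,
                                  var_equal = FALSE, n_components = 2,
                                  lfc = 1, alpha = 0.05, vip_min = 1) {
  layer <- m$layer
  non_qc <- design$sample_id[!design$is_qc]
  if (layer == "transcript") {
    lfc_vec <- log2_fold_change(m, design, contrast, pseudocount)
    mlog <- m
    mlog$values <- log2(m$values + pseudocount)
    p <- welch_t(mlog, design, contrast, var_equal)
    tab <- data.frame(feature = names(lfc_vec), log2fc = unname(lfc_vec),
                      p = unname(p), fdr = unname(bh_adjust(p)),
                      vip = NA_real_, stringsAsFactors = FALSE)
  } else if (layer == "protein") {
    lfc_vec <- log2_fold_change(m, design, contrast, 0)
    mlog <- m
    mlog$values <- log2(m$values)
    p <- welch_t(mlog, design, contrast, var_equal)
    tab <- data.frame(feature = names(lfc_vec), log2fc = unname(lfc_vec),
                      p = unname(p), fdr = unname(bh_adjust(p)),
                      vip = NA_real_, stringsAsFactors = FALSE)
  } else {
    check_stage(m, "logged", "differential_analysis(metabolite)")
    lfc_vec <- log2_fold_change(m, design, contrast)
    p <- welch_t(m, design, contrast, var_equal)
    vip <- pls_vip(m, design, contrast, n_components)$vip
    tab <- data.frame(feature = names(lfc_vec), log2fc = unname(lfc_vec),
                      p = unname(p), fdr = unname(bh_adjust(p)),
                      vip = unname(vip[names(lfc_vec)]),
                      stringsAsFactors = FALSE)
  }
  tab <- call_features(tab, layer, lfc = lfc, alpha = alpha,
                       vip_min = vip_min)
  attr(tab, "contrast") <- contrast
  attr(tab, "layer") <- layer
  class(tab) <- c("differential_table", "data.frame")
  tab
}

#' @export
print.differential_table <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("<differential_table> %s: %s vs %s - %d features: %d up, %d down\n",
              attr(x, "layer"), ct[1], ct[2], nrow(x),
              sum(x$call == "up"), sum(x$call == "down")))
  invisible(x)
}

#' Differential feature ids of a table
#' @param table a `differential_table`.
#' @return character vector of features called up or down.
#' @export
differential_features <- function(table) {
  table$feature[table$call %in% c("up", "down")]
}
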