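#' Sample design table
#'
#' A `sample_design` is a data frame with columns `sample_id`, `group` and
#' `is_qc`, plus a `layer` attribute naming the omics layer it describes.
#' Pooled quality-control (QC) injections are a metabolomics construct:
#' the QC flag is only permitted on metabolite-layer designs. QC samples
#' carry `NA` in `group`.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group group label per sample (`NA` allowed only for QC samples).
#' @param is_qc logical QC flag per sample.
#' @param layer one of `"transcript"`, `"protein"`, `"metabolite"`.
#' @return a `sample_design` data frame.
#' @export
sample_design <- function(sample_id, group, is_qc = FALSE, layer) {
  layer <- match.arg(layer, c("transcript", "protein", "metabolite"))
  is_qc <- rep_len(as.logical(is_qc), length(sample_id))
  group <- as.character(group)
  assert_that(!anyDuplicated(sample_id), "sample_ids must be unique")
  assert_that(!any(is.na(group) & !is_qc),
              "every non-QC sample must have a group")
  if (any(is_qc) && layer != "metabolite") {
    stop("QC samples are only permitted on the metabolite layer, not '",
         layer, "'", call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(sample_id), group = group,
                    is_qc = is_qc, stringsAsFactors = FALSE)
  attr(out, "layer") <- layer
  class(out) <- c("sample_design", "data.frame")
  out
}

#' Simulate a grouped sample design
#'
#' Builds the sample sheet for one omics layer of a multi-group experiment:
#' `reps_per_group` biological replicates for each group label, plus
#' `n_qc` pooled-QC injections on the metabolite layer. Sample identifiers
#' are `<group>_<replicate>` and `QC_<i>`; the layout is deterministic,
#' the `seed` argument is accepted for interface uniformity with the other
#' generators.
#'
#' @param groups character vector of group labels.
#' @param reps_per_group biological replicates per group (>= 2).
#' @param n_qc number of pooled QC injections (metabolite layer only).
#' @param layer omics layer.
#' @param seed integer seed (unused; layout is deterministic).
#' @return a [sample_design()].
#' @examples
#' simulate_design(c("T0", "T2", "T4"), reps_per_group = 3, layer = "transcript")
#' @export
simulate_design <- function(groups, reps_per_group, n_qc = 0, layer, seed = 1L) {
  assert_that(reps_per_group >= 2, "reps_per_group must be >= 2")
  assert_that(n_qc >= 0, "n_qc must be >= 0")
  layer <- match.arg(layer, c("transcript", "protein", "metabolite"))
  if (n_qc > 0 && layer != "metabolite") {
    stop("QC injections (n_qc > 0) are only defined for the metabolite ",
         "layer, not '", layer, "'", call. = FALSE)
  }
  ids <- as.vector(vapply(groups, function(g)
    paste0(g, "_", seq_len(reps_per_group)), character(reps_per_group)))
  grp <- rep(groups, each = reps_per_group)
  qc <- logical(length(ids))
  if (n_qc > 0) {
    ids <- c(ids, paste0("QC_", seq_len(n_qc)))
    grp <- c(grp, rep(NA_character_, n_qc))
    qc <- c(qc, rep(TRUE, n_qc))
  }
  sample_design(ids, grp, qc, layer)
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("<sample_design> layer=%s, %d samples (%d QC), groups: %s\n",
              attr(x, "layer"), nrow(x), sum(x$is_qc),
              paste(unique(stats::na.omit(x$group)), collapse = ", ")))
  NextMethod()
}

#' Write / read a sample design as TSV
#'
#' @param design a [sample_design()].
#' @param path file path.
#' @return `write_design` returns `path` invisibly; `read_design` a
#'   `sample_design`.
#' @export
write_design <- function(design, path) {
  df <- as.data.frame(design)
  df$layer <- attr(design, "layer")
  write_tsv(df, path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- read_tsv(path)
  sample_design(df$sample_id, df$group, as.logical(df$is_qc),
                layer = df$layer[1])
}

# Non-QC sample ids belonging to one group.
group_samples <- function(design, group) {
  design$sample_id[!design$is_qc & !is.na(design$group) & design$group == group]
}

qc_samples <- function(design) design$sample_id[design$is_qc]
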