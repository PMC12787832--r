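#' Omics feature-by-sample matrix
#'
#' Container for one omics layer: a numeric matrix with features in rows
#' and samples in columns, missing measurements stored as `NA`, a `layer`
#' tag and a `stage` tag tracking the preprocessing cascade. Stages move
#' only forward through
#' `raw -> filtered -> imputed -> normalized -> qc_filtered -> logged`;
#' each preprocessing operation checks the stage of its input so that the
#' cascade cannot be silently reordered.
#'
#' @param values numeric matrix; rownames = feature ids, colnames = sample
#'   ids. `NA` marks a missing measurement.
#' @param layer one of `"transcript"`, `"protein"`, `"metabolite"`.
#' @param stage processing stage tag.
#' @return an `omics_matrix`.
#' @export
omics_matrix <- function(values, layer,
                         stage = c("raw", "filtered", "imputed",
                                   "normalized", "qc_filtered", "logged")) {
  stage <- match.arg(stage)
  layer <- match.arg(layer, c("transcript", "protein", "metabolite"))
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  if (nrow(values) > 0) {
    assert_that(!is.null(rownames(values)),
                "values must have feature rownames")
  } else if (is.null(rownames(values))) {
    rownames(values) <- character(0)
  }
  assert_that(ncol(values) == 0 || !is.null(colnames(values)),
              "values must have sample colnames")
  assert_that(!anyDuplicated(rownames(values)), "feature ids must be unique")
  assert_that(!anyDuplicated(colnames(values)), "sample ids must be unique")
  if (stage_index(stage) >= stage_index("imputed") && anyNA(values)) {
    stop("no missing entries permitted at or after stage 'imputed'",
         call. = FALSE)
  }
  structure(list(values = values, layer = layer, stage = stage),
            class = "omics_matrix")
}

stage_order <- c("raw", "filtered", "imputed", "normalized",
                 "qc_filtered", "logged")
stage_index <- function(stage) match(stage, stage_order)

# Guard used by every cascade operation: the input must sit at one of the
# allowed stages, otherwise the call is a contract violation.
check_stage <- function(m, allowed, op) {
  if (!m$stage %in% allowed) {
    stop(sprintf("%s() requires stage %s but input is at stage '%s'",
                 op, paste(sQuote(allowed), collapse = " or "), m$stage),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix> layer=%s stage=%s: %d features x %d samples (%d missing)\n",
    x$layer, x$stage, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an omics matrix
#' @param m an [omics_matrix()].
#' @return character vector of ids.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Write / read an omics matrix as TSV
#'
#' First column `feature_id`, one column per sample; empty cells are
#' missing values.
#'
#' @param m an [omics_matrix()].
#' @param path file path.
#' @param layer,stage tags to attach on read.
#' @return `write_omics_matrix` returns `path` invisibly;
#'   `read_omics_matrix` an `omics_matrix`.
#' @export
write_omics_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_omics_matrix
#' @export
read_omics_matrix <- function(path, layer, stage = "raw") {
  df <- read_tsv(path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- df[[1]]
  omics_matrix(vals, layer = layer, stage = stage)
}

# Subset rows of an omics matrix, preserving tags.
subset_features <- function(m, keep) {
  m$values <- m$values[keep, , drop = FALSE]
  m
}
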