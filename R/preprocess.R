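#' Metabolomics preprocessing cascade
#'
#' The five-stage quality-control cascade applied to a metabolite peak
#' table, in this fixed order:
#' presence filter -> minimum imputation -> sum normalization ->
#' pooled-QC RSD filter -> log10 transform. Each function checks the
#' processing stage of its input; running the stages out of order is an
#' error, not a silent reordering. [preprocess_metabolites()] runs the
#' whole cascade and records per-stage provenance.
#'
#' @name preprocess
NULL

#' Presence filter
#'
#' Retains features detected (non-missing and strictly positive) in at
#' least `min_frac` of all samples. The boundary is inclusive: a feature
#' detected in exactly `min_frac` of samples is kept.
#'
#' @param m an [omics_matrix()] at stage `"raw"` (or `"filtered"`, for
#'   idempotent reapplication).
#' @param min_frac minimum detection fraction in `[0, 1]`.
#' @return filtered `omics_matrix` at stage `"filtered"`; attribute
#'   `"removed"` lists dropped feature ids.
#' @export
presence_filter <- function(m, min_frac = 0.8) {
  check_stage(m, c("raw", "filtered"), "presence_filter")
  if (nrow(m$values) == 0) {
    warning("presence_filter: empty matrix")
    m$stage <- "filtered"
    return(m)
  }
  detected <- !is.na(m$values) & m$values > 0
  frac <- rowMeans(detected)
  keep <- frac >= min_frac
  out <- subset_features(m, keep)
  out$stage <- "filtered"
  attr(out, "removed") <- rownames(m$values)[!keep]
  out
}

#' Minimum imputation
#'
#' Replaces every missing entry by the minimum observed value, either of
#' the feature's own row (`per_feature`) or of the whole matrix
#' (`global`).
#'
#' @param m an [omics_matrix()] at stage `"filtered"`.
#' @param scope `"per_feature"` or `"global"`.
#' @return `omics_matrix` at stage `"imputed"`, free of missing values.
#' @export
impute_min <- function(m, scope = c("per_feature", "global")) {
  scope <- match.arg(scope)
  check_stage(m, "filtered", "impute_min")
  v <- m$values
  if (anyNA(v)) {
    if (scope == "global") {
      fill <- min(v, na.rm = TRUE)
      v[is.na(v)] <- fill
    } else {
      for (i in which(rowSums(is.na(v)) > 0)) {
        obs <- v[i, !is.na(v[i, ])]
        if (length(obs) == 0) {
          stop("impute_min: feature '", rownames(v)[i],
               "' has no observed values under per_feature scope",
               call. = FALSE)
        }
        v[i, is.na(v[i, ])] <- min(obs)
      }
    }
  }
  m$values <- v
  m$stage <- "imputed"
  m
}

#' Sum normalization
#'
#' Divides each sample column by its total so that every column sums to
#' 1. Idempotent on unit-sum input.
#'
#' @param m an [omics_matrix()] at stage `"imputed"`, all values >= 0.
#' @return `omics_matrix` at stage `"normalized"`.
#' @export
sum_normalize <- function(m) {
  check_stage(m, "imputed", "sum_normalize")
  assert_that(all(m$values >= 0), "sum_normalize requires nonnegative values")
  tot <- colSums(m$values)
  zero <- tot == 0
  if (any(zero)) {
    stop("sum_normalize: sample(s) with zero total intensity: ",
         paste(colnames(m$values)[zero], collapse = ", "), call. = FALSE)
  }
  m$values <- sweep(m$values, 2, tot, "/")
  m$stage <- "normalized"
  m
}

#' Pooled-QC RSD filter
#'
#' Computes the relative standard deviation (sample standard deviation /
#' mean, the metabolomics QC convention) of each feature over the
#' pooled-QC columns and removes features with RSD strictly greater than
#' `max_rsd`. The boundary case RSD = `max_rsd` is retained. Features
#' whose QC mean is zero cannot be assessed and are excluded with a
#' warning.
#'
#' @param m an [omics_matrix()] at stage `"normalized"` (or
#'   `"qc_filtered"`, for idempotent reapplication).
#' @param design a metabolite-layer [sample_design()] with >= 2 QC
#'   samples.
#' @param max_rsd maximum tolerated RSD (default 0.30).
#' @return `omics_matrix` at stage `"qc_filtered"`; attributes
#'   `"removed"` (dropped ids) and `"qc_rsd"` (named RSD vector).
#' @export
qc_rsd_filter <- function(m, design, max_rsd = 0.30) {
  check_stage(m, c("normalized", "qc_filtered"), "qc_rsd_filter")
  qc <- intersect(qc_samples(design), colnames(m$values))
  if (length(qc) < 2) {
    stop("qc_rsd_filter requires at least 2 QC samples (found ",
         length(qc), ")", call. = FALSE)
  }
  q <- m$values[, qc, drop = FALSE]
  mu <- rowMeans(q)
  s <- apply(q, 1, stats::sd)
  rsd <- ifelse(mu == 0, NA_real_, s / mu)
  if (any(mu == 0)) {
    warning(sum(mu == 0), " feature(s) with zero QC mean excluded")
  }
  keep <- !is.na(rsd) & rsd <= max_rsd
  out <- subset_features(m, keep)
  out$stage <- "qc_filtered"
  attr(out, "removed") <- rownames(m$values)[!keep]
  attr(out, "qc_rsd") <- stats::setNames(rsd, rownames(m$values))
  out
}

#' Log10 transform
#'
#' Elementwise log10 of a strictly positive matrix; the final stage of
#' the cascade.
#'
#' @param m an [omics_matrix()] at stage `"qc_filtered"`.
#' @return `omics_matrix` at stage `"logged"`.
#' @export
log10_transform <- function(m) {
  check_stage(m, "qc_filtered", "log10_transform")
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "log10_transform: nonpositive value at feature '%s', sample '%s'",
      rownames(m$values)[bad[1, 1]], colnames(m$values)[bad[1, 2]]),
      call. = FALSE)
  }
  m$values <- log10(m$values)
  m$stage <- "logged"
  m
}

#' Run the full metabolomics preprocessing cascade
#'
#' @param m a raw metabolite [omics_matrix()].
#' @param design the matching [sample_design()] (with QC samples).
#' @param min_frac presence threshold (default 0.8).
#' @param max_rsd QC RSD threshold (default 0.30).
#' @param impute_scope minimum-imputation scope.
#' @return the logged `omics_matrix`; attribute `"provenance"` is a list
#'   of per-stage records (operation, parameters, features removed).
#' @export
preprocess_metabolites <- function(m, design, min_frac = 0.8,
                                   max_rsd = 0.30,
                                   impute_scope = "per_feature") {
  prov <- list()
  step <- function(x, op, params) {
    prov[[length(prov) + 1]] <<- list(
      op = op, params = params,
      n_features = nrow(x$values),
      removed = as.character(attr(x, "removed") %||% character(0)))
    x
  }
  m <- step(presence_filter(m, min_frac), "presence_filter",
            list(min_frac = min_frac))
  m <- step(impute_min(m, impute_scope), "impute_min",
            list(scope = impute_scope))
  m <- step(sum_normalize(m), "sum_normalize", list())
  m <- step(qc_rsd_filter(m, design, max_rsd), "qc_rsd_filter",
            list(max_rsd = max_rsd))
  m <- step(log10_transform(m), "log10_transform", list())
  attr(m, "provenance") <- prov
  m
}
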