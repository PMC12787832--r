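#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a two-class partial-least-squares discriminant model on the
#' mean-centred, unit-variance-scaled feature matrix by the NIPALS
#' algorithm (class membership coded +1/-1), optionally after removing a
#' single orthogonal-signal-correction component (the orthogonal variant:
#' class-uncorrelated variation is stripped before the predictive
#' components are extracted). The VIP score of feature j is
#' \deqn{VIP_j = \sqrt{ p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a }}
#' with p the number of (non-constant) features, w_a the component-a
#' weight vector and SSY_a the response variance explained by component
#' a. By construction the mean of the squared VIP over the scored
#' features equals 1.
#'
#' Constant (zero-variance) features cannot be autoscaled; their VIP is
#' set to 0 with a warning and they are excluded from the fit.
#'
#' @param m a logged metabolite [omics_matrix()] (any `omics_matrix` at
#'   stage `"logged"` is accepted).
#' @param design the matching [sample_design()].
#' @param contrast length-2 character vector `c(test_group, ref_group)`.
#' @param n_components number of predictive PLS components (default 2,
#'   truncated to the admissible maximum `min(samples, features) - 1`).
#' @param orthogonal number of orthogonal-signal-correction components to
#'   remove first (0 = plain PLS-DA, 1 = orthogonal variant).
#' @return a `vip_result`: list with `vip` (named score vector over all
#'   features), `n_components`, `contrast`, `weights`, `ssy`.
#' @export
pls_vip <- function(m, design, contrast, n_components = 2, orthogonal = 0) {
  check_stage(m, "logged", "pls_vip")
  assert_that(length(contrast) == 2, "contrast must be c(test, reference)")
  ids_test <- group_samples(design, contrast[1])
  ids_ref <- group_samples(design, contrast[2])
  ids_test <- intersect(ids_test, colnames(m$values))
  ids_ref <- intersect(ids_ref, colnames(m$values))
  assert_that(length(ids_test) >= 2 && length(ids_ref) >= 2,
              "both groups need >= 2 non-QC samples")
  X <- t(m$values[, c(ids_test, ids_ref), drop = FALSE])
  y <- c(rep(1, length(ids_test)), rep(-1, length(ids_ref)))

  sds <- apply(X, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning(sum(constant), " constant feature(s) assigned VIP 0 and ",
            "excluded from the fit")
  }
  Xs <- scale(X[, !constant, drop = FALSE])
  yc <- y - mean(y)
  n <- nrow(Xs); p <- ncol(Xs)
  max_comp <- min(n, p) - 1L
  assert_that(n_components >= 1, "n_components must be >= 1")
  n_components <- min(n_components, max_comp)

  if (orthogonal > 0) {
    for (i in seq_len(orthogonal)) {
      osc <- osc_deflate(Xs, yc)
      if (is.null(osc)) break
      Xs <- osc
    }
  }

  W <- matrix(0, p, n_components)
  ssy <- numeric(n_components)
  Xa <- Xs; ya <- yc
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xa, ya)                      # X'y
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                       # no covariance left
    w <- w / nw
    t_a <- Xa %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - t_a %*% t(p_a)
    ya <- ya - q_a * t_a
    a_used <- a
    W[, a] <- w
    ssy[a] <- q_a^2 * tt                        # response SS explained
  }
  assert_that(a_used >= 1, "PLS fit extracted no components")
  W <- W[, seq_len(a_used), drop = FALSE]
  ssy <- ssy[seq_len(a_used)]

  # weights are unit-norm, so (w_ja/||w_a||)^2 = w_ja^2
  vip_core <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  vip <- stats::setNames(numeric(ncol(X)), colnames(X))
  vip[!constant] <- vip_core
  structure(list(vip = vip, n_components = a_used,
                 contrast = contrast, weights = W, ssy = ssy),
            class = "vip_result")
}

# One orthogonal-signal-correction deflation (single O-PLS orthogonal
# component): remove from X the dominant variation orthogonal to y.
osc_deflate <- function(Xs, yc) {
  w <- crossprod(Xs, yc)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) return(NULL)
  w <- w / nw
  t_pred <- Xs %*% w
  p_pred <- crossprod(Xs, t_pred) / sum(t_pred^2)
  w_orth <- p_pred - as.numeric(crossprod(w, p_pred)) * w
  nwo <- sqrt(sum(w_orth^2))
  if (nwo < 1e-12) return(NULL)
  w_orth <- w_orth / nwo
  t_orth <- Xs %*% w_orth
  p_orth <- crossprod(Xs, t_orth) / sum(t_orth^2)
  Xs - t_orth %*% t(p_orth)
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf(
    "<vip_result> %s vs %s, %d component(s); %d/%d features with VIP > 1\n",
    x$contrast[1], x$contrast[2], x$n_components,
    sum(x$vip > 1), length(x$vip)))
  invisible(x)
}
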