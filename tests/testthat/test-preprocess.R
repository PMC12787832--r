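make_met_matrix <- function(values, features = NULL, samples = NULL,
                            stage = "raw") {
  toy_matrix(values, layer = "metabolite", stage = stage,
             features = features, samples = samples)
}

test_that("presence_filter keeps features detected in at least min_frac of samples", {
  v <- rbind(c(rep(1, 8), NA, NA),    # 8/10 detected: boundary, kept
             c(rep(1, 7), NA, NA, NA),# 7/10: dropped
             rep(1, 10),              # fully detected
             c(rep(1, 9), 0))         # zero counts as undetected: 9/10 kept
  m <- make_met_matrix(v)
  f <- presence_filter(m, 0.8)
  expect_equal(rownames(f$values), c("f01", "f03", "f04"))
  expect_equal(attr(f, "removed"), "f02")
  expect_equal(f$stage, "filtered")

  # identity on fully detected input
  m_full <- make_met_matrix(matrix(1:20, 4, 5) * 1.0)
  f_full <- presence_filter(m_full, 0.8)
  expect_identical(f_full$values, m_full$values)

  # idempotence
  f2 <- presence_filter(f, 0.8)
  expect_identical(f2$values, f$values)

  expect_warning(presence_filter(make_met_matrix(matrix(numeric(0), 0, 3,
    dimnames = list(NULL, c("a", "b", "c"))))), "empty")
})

test_that("impute_min fills missing cells with the per-feature or global minimum", {
  m <- make_met_matrix(rbind(c(5, NA, 7), c(1, 2, 3)), stage = "filtered")
  per <- impute_min(m, "per_feature")
  expect_equal(unname(per$values[1, ]), c(5, 5, 7))
  expect_equal(per$stage, "imputed")
  expect_false(anyNA(per$values))

  glo <- impute_min(m, "global")
  expect_equal(unname(glo$values[1, 2]), 1)

  # identity when nothing is missing
  m2 <- make_met_matrix(rbind(c(5, 6, 7)), stage = "filtered")
  expect_identical(impute_min(m2)$values, m2$values)

  # a feature with no observed value cannot be imputed per feature
  m3 <- make_met_matrix(rbind(c(NA, NA, NA), c(1, 2, 3)), stage = "filtered")
  expect_error(impute_min(m3, "per_feature"), "no observed values")
})

test_that("sum_normalize scales every sample column to total 1", {
  m <- make_met_matrix(cbind(c(2, 3, 5), c(1, 1, 2)), stage = "imputed")
  nm <- sum_normalize(m)
  expect_equal(unname(nm$values[, 1]), c(0.2, 0.3, 0.5))
  expect_true(all(abs(colSums(nm$values) - 1) < 1e-9))
  expect_equal(nm$stage, "normalized")

  # idempotent on unit-sum input (stage reset to rerun the op)
  nm2 <- nm; nm2$stage <- "imputed"
  expect_equal(sum_normalize(nm2)$values, nm$values)

  m0 <- make_met_matrix(cbind(c(1, 2), c(0, 0)), stage = "imputed")
  expect_error(sum_normalize(m0), "s02")
})

test_that("qc_rsd_filter drops features with QC RSD above the threshold", {
  d <- sample_design(c("T0_1", "T0_2", "QC_1", "QC_2", "QC_3"),
                     c("T0", "T0", NA, NA, NA),
                     c(FALSE, FALSE, TRUE, TRUE, TRUE), layer = "metabolite")
  v <- rbind(c(4, 4, 10, 10, 10),  # QC RSD 0: retained
             c(4, 4, 1, 2, 3))     # QC RSD = 1/2 = 0.5 > 0.3: excluded
  m <- make_met_matrix(v, samples = d$sample_id, stage = "normalized")
  expect_equal(rsd_of(c(1, 2, 3)), 0.5)
  f <- qc_rsd_filter(m, d, 0.30)
  expect_equal(rownames(f$values), "f01")
  expect_equal(attr(f, "removed"), "f02")
  expect_equal(f$stage, "qc_filtered")

  # boundary: RSD exactly at the threshold is retained
  f_bound <- qc_rsd_filter(
    make_met_matrix(v, samples = d$sample_id, stage = "normalized"), d, 0.5)
  expect_equal(nrow(f_bound$values), 2)

  # vacuous threshold removes nothing
  f_inf <- qc_rsd_filter(
    make_met_matrix(v, samples = d$sample_id, stage = "normalized"), d, Inf)
  expect_equal(nrow(f_inf$values), 2)

  # idempotence
  expect_equal(nrow(qc_rsd_filter(f, d, 0.30)$values), 1)

  d1 <- sample_design(c("T0_1", "T0_2", "QC_1"), c("T0", "T0", NA),
                      c(FALSE, FALSE, TRUE), layer = "metabolite")
  m1 <- make_met_matrix(v[, 1:3], samples = d1$sample_id,
                        stage = "normalized")
  expect_error(qc_rsd_filter(m1, d1), "at least 2 QC")

  # zero QC mean: excluded with a warning
  v0 <- rbind(c(1, 1, 0, 0, 0), c(1, 1, 2, 2, 2))
  m0 <- make_met_matrix(v0, samples = d$sample_id, stage = "normalized")
  expect_warning(f0 <- qc_rsd_filter(m0, d, 0.3), "zero QC mean")
  expect_equal(rownames(f0$values), "f02")
})

test_that("log10_transform is exact and invertible on positive matrices", {
  m <- make_met_matrix(rbind(c(1, 100, 10)), stage = "qc_filtered")
  lg <- log10_transform(m)
  expect_equal(unname(lg$values[1, ]), c(0, 2, 1))
  expect_equal(lg$stage, "logged")

  set.seed(9)
  v <- matrix(10^runif(20, -3, 3), 4, 5,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
  m2 <- omics_matrix(v, "metabolite", stage = "qc_filtered")
  expect_equal(10^log10_transform(m2)$values, v, tolerance = 1e-12)

  m_bad <- make_met_matrix(rbind(c(1, -2, 3)), stage = "qc_filtered")
  expect_error(log10_transform(m_bad), "feature 'f01', sample 's02'")
})

test_that("cascade stages refuse out-of-order input", {
  m_raw <- make_met_matrix(rbind(c(1, 2, 3)))
  expect_error(impute_min(m_raw), "stage")
  expect_error(sum_normalize(m_raw), "stage")
  expect_error(log10_transform(m_raw), "stage")
  d <- sample_design(c("a", "QC_1", "QC_2"), c("T0", NA, NA),
                     c(FALSE, TRUE, TRUE), layer = "metabolite")
  expect_error(qc_rsd_filter(m_raw, d), "stage")
  m_logged <- make_met_matrix(rbind(c(1, 2, 3)), stage = "logged")
  expect_error(presence_filter(m_logged), "stage")
})

test_that("the full cascade runs in order with non-increasing feature counts", {
  d <- simulate_design(c("T0", "T2", "T4"), 6, n_qc = 4, layer = "metabolite")
  tr <- simulate_truth(n_features = 300, prefix = "m", n_modules = 0,
                       module_size = 0, plant_hub = FALSE, seed = 4)
  m <- simulate_layer(d, tr, noise = list(missing_rate = 0.15,
                                          frac_unstable = 0.1,
                                          unstable_cv = 1.0), seed = 4)
  out <- suppressWarnings(preprocess_metabolites(m, d))
  expect_equal(out$stage, "logged")
  prov <- attr(out, "provenance")
  expect_equal(vapply(prov, `[[`, character(1), "op"),
               c("presence_filter", "impute_min", "sum_normalize",
                 "qc_rsd_filter", "log10_transform"))
  counts <- vapply(prov, `[[`, numeric(1), "n_features")
  expect_true(all(diff(counts) <= 0))
  expect_false(anyNA(out$values))
})
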