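test_that("q-value filtering censors quantities without deleting rows", {
  tab <- toy_table(run_id = rep("r1.raw", 5), condition = "A", replicate = 1,
                   protein_group = "P1",
                   stripped = paste0(c("AAAA", "CCCC", "DDDD", "EEEE", "FFFF"), "K"),
                   quantity = 1:5,
                   pq = c(0.001, 0.05, 0.001, 0.001, 0.001))
  # permissive thresholds: identity
  same <- filter_qvalues(tab, 1, 1)
  expect_equal(same$quantity, tab$quantity)
  # one row above threshold loses its quantity, row retained
  got <- filter_qvalues(tab, 0.01, 0.01)
  expect_equal(nrow(got), 5L)
  expect_true(is.na(got$quantity[got$precursor_qvalue == 0.05]))
  expect_equal(attr(got, "n_censored"), 1L)
  # all rows censored: downstream matrix is empty-with-warning
  allbad <- tab
  allbad$precursor_qvalue <- 0.5
  gone <- filter_qvalues(allbad, 0.01, 0.01)
  expect_true(all(is.na(gone$quantity)))
  des1 <- as_study_design(data.frame(run_id = "r1.raw", condition = "A",
                                     replicate = 1L))
  expect_warning(build_peptide_matrix(gone, des1), "no finite")
})

test_that("oxidized-Met removal drops matching precursors from all runs", {
  tab <- toy_table(run_id = rep(c("r1.raw", "r2.raw"), each = 2),
                   condition = rep(c("A", "B"), each = 2), replicate = 1,
                   protein_group = "P1",
                   stripped = rep(c("AMK", "CCCCK"), 2),
                   modified = rep(c("_AM[Oxidation (M)]K_", "_CCCCK_"), 2),
                   quantity = 1:4)
  got <- remove_oxidized_met(tab)
  expect_equal(nrow(got), 2L)
  expect_false(any(grepl("Oxidation", got$modified_sequence)))
  expect_equal(attr(got, "n_dropped_precursors"), 1L)
  # tags matching nothing: identity with zero count
  same <- remove_oxidized_met(tab, tags = "Phospho (STY)")
  expect_equal(nrow(same), 4L)
  expect_equal(attr(same, "n_dropped_precursors"), 0L)
})

test_that("condition-wise filter keeps rows observed in at least one condition", {
  design <- toy_design(rep(c("A", "B"), each = 3))
  vals <- rbind(
    pep1 = c(1, 2, NA, NA, NA, NA),   # 2/3 in A, 0/3 in B
    pep2 = c(1, NA, NA, 2, NA, NA),   # 1/3 and 1/3
    pep3 = c(NA, NA, NA, NA, NA, NA)) # never observed
  pm <- toy_matrix(vals, design = design)
  kept <- condition_wise_filter(pm, 0.5)
  expect_equal(rownames(kept$values), "pep1")
  expect_equal(attr(kept, "n_dropped"), 2L)
  # min_fraction -> 0+: only all-missing rows dropped
  loose <- condition_wise_filter(pm, 1e-9)
  expect_setequal(rownames(loose$values), c("pep1", "pep2"))
})

test_that("condition-wise filter is monotone in the threshold", {
  study <- generate_study(simulation_config(n_proteins = 40, seed = 8,
                                            dropout_midpoint = 12))
  pm <- build_peptide_matrix(study$table, study$design)
  kept_levels <- lapply(c(0.3, 0.5, 0.8, 1.0), function(f)
    rownames(condition_wise_filter(pm, f)$values))
  for (i in seq_len(length(kept_levels) - 1L)) {
    expect_true(all(kept_levels[[i + 1L]] %in% kept_levels[[i]]))
  }
})

test_that("median normalization equalizes column medians and removes constant shifts", {
  design <- toy_design(c("A", "A", "B"))
  # columns already sharing a common median: offsets all zero
  v0 <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  n0 <- log2_median_normalize(toy_matrix(v0, design = design))
  expect_equal(unname(n0$offsets), c(0, 0, 0))
  expect_equal(n0$values, toy_matrix(v0, design = design)$values)

  # column 2 = column 1 + 1.0: shift removed exactly
  v1 <- cbind(c(1, 5, 9), c(2, 6, 10), c(1, 5, 9))
  n1 <- log2_median_normalize(toy_matrix(v1, design = design))
  expect_equal(unname(n1$offsets[2] - n1$offsets[1]), 1.0)
  expect_equal(unname(n1$values[, 1]), unname(n1$values[, 2]))

  # 3x3 with distinct medians: verify against hand-computed medians
  v2 <- rbind(c(1, 4, 10), c(2, 6, 11), c(3, 8, 15))
  # column medians: 2, 6, 11; reference = median(2,6,11) = 6
  n2 <- log2_median_normalize(toy_matrix(v2, design = design))
  expect_equal(unname(n2$offsets), c(2 - 6, 0, 11 - 6))
  meds <- apply(n2$values, 2, median)
  expect_equal(unname(meds), rep(6, 3), tolerance = 1e-9)

  # all-missing column is a hard error naming the run
  v3 <- rbind(c(1, NA, 3), c(2, NA, 4))
  expect_error(log2_median_normalize(toy_matrix(v3, design = design)), "run2")
})

test_that("median normalization is idempotent", {
  study <- generate_study(simulation_config(n_proteins = 30, seed = 2))
  pm <- build_peptide_matrix(study$table, study$design)
  once <- log2_median_normalize(pm)
  twice <- log2_median_normalize(once)
  expect_lt(max(abs(twice$offsets)), 1e-12)
  expect_equal(twice$values, once$values)
})

test_that("batch adjustment removes additive shifts exactly on noise-free data", {
  cfg <- simulation_config(n_proteins = 25, replicate_noise_sd = 0,
                           peptide_offset_sd = 0.5,
                           batch_shifts = c(b1 = 0, b2 = 2),
                           replicates_per_condition = 4,
                           dropout_midpoint = -Inf,
                           oxidation_fraction = 0, seed = 3)
  study <- generate_study(cfg)
  pm <- build_peptide_matrix(study$table, study$design)
  adj <- adjust_batch_covariates(pm)
  # reference: same generator without the batch shift
  cfg0 <- cfg; cfg0$batch_shifts <- c(b1 = 0, b2 = 0)
  pm0 <- build_peptide_matrix(generate_study(cfg0)$table, study$design)
  common <- intersect(rownames(adj$values), rownames(pm0$values))
  expect_gt(length(common), 0)
  expect_lt(max(abs(adj$values[common, ] - pm0$values[common, ])), 1e-6)
})

test_that("batch adjustment handles single batches, confounding, and sparse rows", {
  # single batch: identity
  design1 <- toy_design(c("A", "A", "B", "B"), batch = rep("b1", 4))
  vals <- matrix(rnorm(20), 5, 4)
  pm1 <- toy_matrix(vals, design = design1)
  expect_equal(adjust_batch_covariates(pm1)$values, pm1$values)

  # batch identical to condition: confounding error
  design2 <- toy_design(c("A", "A", "B", "B"), batch = c("b1", "b1", "b2", "b2"))
  pm2 <- toy_matrix(vals, design = design2)
  expect_error(adjust_batch_covariates(pm2), "confounded")

  # rows with too few observations pass through unadjusted, flagged
  design3 <- toy_design(rep(c("A", "B"), 3), batch = rep(c("b1", "b2"), each = 3))
  v <- matrix(rnorm(12), 2, 6)
  v[1, 4:6] <- NA  # 3 observations <= 4 parameters
  pm3 <- toy_matrix(v, design = design3)
  adj3 <- adjust_batch_covariates(pm3)
  expect_equal(adj3$values[1, ], pm3$values[1, ])
  expect_equal(attr(adj3, "unadjusted_rows"), rownames(pm3$values)[1])
})

test_that("batch adjustment agrees with the established linear-model adjustment on complete data", {
  skip_if_not_installed("limma")
  set.seed(10)
  design <- toy_design(rep(c("A", "B"), 4),
                       batch = rep(c("b1", "b2"), each = 4))
  vals <- matrix(rnorm(80, mean = 10), 10, 8)
  vals[, design$batch == "b2"] <- vals[, design$batch == "b2"] + 1.5
  pm <- toy_matrix(vals, design = design)
  got <- adjust_batch_covariates(pm)$values
  ref <- limma::removeBatchEffect(
    vals, batch = factor(design$batch),
    design = stats::model.matrix(~condition, as.data.frame(design)))
  # both remove the batch contrast; codings differ by a per-row constant
  expect_equal(unname(got - rowMeans(got)), unname(ref - rowMeans(ref)),
               tolerance = 1e-10)
})

test_that("preprocessing preserves row/column metadata alignment", {
  study <- generate_study(simulation_config(n_proteins = 30, seed = 4,
                                            batch_shifts = c(b1 = 0, b2 = 1)))
  pm <- build_peptide_matrix(study$table, study$design)
  for (step in list(function(m) condition_wise_filter(m, 0.5),
                    log2_median_normalize,
                    adjust_batch_covariates)) {
    pm <- step(pm)
    expect_equal(rownames(pm$values), pm$row_meta$precursor_id)
    expect_equal(colnames(pm$values), pm$design$run_id)
  }
})
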