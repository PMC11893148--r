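test_that("peptide t-test matches the reference implementation and edge cases", {
  # identical vectors: t = 0, p = 1, ratio = 0
  r0 <- peptide_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$log2_ratio, 0)
  # pure mean shift
  r1 <- peptide_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r1$log2_ratio, 1.0)
  # pooled t against stats::t.test as independent oracle
  a <- c(5.1, 5.3, 5.2); b <- c(4.0, 4.2, 4.1)
  r2 <- peptide_t_test(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r2$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(r2$df, unname(ref$parameter))
  # Welch variant
  r3 <- peptide_t_test(a, c(b, 3.0), var_equal = FALSE)
  ref3 <- stats::t.test(a, c(b, 3.0), var.equal = FALSE)
  expect_equal(r3$t_statistic, unname(ref3$statistic), tolerance = 1e-10)
  expect_equal(r3$p_value, ref3$p.value, tolerance = 1e-10)
  # fewer than 2 values per group: skipped
  expect_null(peptide_t_test(c(1), c(1, 2)))
  expect_null(peptide_t_test(c(1, NA), c(1, 2)))
})

test_that("vectorized row t-tests agree with the scalar test", {
  set.seed(41)
  ma <- matrix(rnorm(60, 10), 20, 3)
  mb <- matrix(rnorm(80, 10.5), 20, 4)
  ma[sample(60, 6)] <- NA
  rt <- diaquant:::row_t_tests(ma, mb)
  for (i in c(1, 5, 12, 20)) {
    ref <- peptide_t_test(ma[i, ], mb[i, ])
    if (is.null(ref)) {
      expect_false(rt$tested[i])
    } else {
      expect_equal(rt$t_statistic[i], ref$t_statistic, tolerance = 1e-12)
      expect_equal(rt$p_value[i], ref$p_value, tolerance = 1e-12)
      expect_equal(rt$s2[i], ref$s2, tolerance = 1e-12)
    }
  }
})

test_that("moderation parameters are recovered from prior-consistent variances", {
  set.seed(101)
  d0 <- 4; s0 <- 0.05; df <- 4
  n <- 20000
  sigma2 <- d0 * s0 / stats::rchisq(n, d0)          # scaled inverse chi-square
  s2 <- sigma2 * stats::rchisq(n, df) / df          # sampling distribution
  fit <- estimate_moderation(s2, df)
  expect_lt(abs(fit$d0 - d0) / d0, 0.15)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.10)
})

test_that("moderation degenerates gracefully", {
  # homogeneous variances: no excess spread, d0 infinite
  fit <- estimate_moderation(rep(0.04, 50), 4)
  expect_true(is.infinite(fit$d0))
  # log-scale method of moments: log s0^2 = mean(log s^2) - digamma(df/2) + log(df/2)
  expect_equal(fit$s0_sq, exp(log(0.04) - digamma(2) + log(2)),
               tolerance = 1e-9)
  # all-zero variances: hard error
  expect_error(estimate_moderation(rep(0, 20), 4), "degenerate")
  # two variances only: refuses to fit
  expect_error(estimate_moderation(c(0.01, 0.02), 4), "too few")
})

test_that("moderated t reproduces its limit cases and the shrinkage formula", {
  set.seed(55)
  stats_df <- diaquant:::row_t_tests(matrix(rnorm(300, 10), 100, 3),
                                     matrix(rnorm(300, 10), 100, 3))
  stats_df <- stats_df[stats_df$tested, ]
  # d0 = 0: ordinary test untouched
  m0 <- moderated_t(stats_df, list(d0 = 0, s0_sq = 1))
  expect_equal(m0$t_statistic, stats_df$t_statistic, tolerance = 1e-12)
  expect_equal(m0$p_value, stats_df$p_value, tolerance = 1e-12)
  # d0 = Inf: shared variance s0, normal reference, t proportional to ratio
  mi <- moderated_t(stats_df, list(d0 = Inf, s0_sq = 0.05))
  expect_equal(mi$t_statistic,
               stats_df$log2_ratio / sqrt(0.05 * stats_df$se_factor),
               tolerance = 1e-12)
  expect_equal(mi$p_value, 2 * pnorm(-abs(mi$t_statistic)), tolerance = 1e-12)
  # finite d0: hand formula on one row
  d0 <- 4; s0 <- 0.05
  mm <- moderated_t(stats_df, list(d0 = d0, s0_sq = s0))
  i <- 1L
  s2t <- (d0 * s0 + stats_df$df[i] * stats_df$s2[i]) / (d0 + stats_df$df[i])
  tref <- stats_df$log2_ratio[i] / sqrt(s2t * stats_df$se_factor[i])
  expect_equal(mm$t_statistic[i], tref, tolerance = 1e-10)
  expect_equal(mm$p_value[i], 2 * pt(-abs(tref), d0 + stats_df$df[i]),
               tolerance = 1e-10)
})

test_that("moderated t p-values are uniform under the null", {
  set.seed(77)
  n <- 2000; d0 <- 4; s0 <- 0.05
  sigma2 <- d0 * s0 / stats::rchisq(n, d0)
  ma <- matrix(rnorm(n * 3, 0, sqrt(rep(sigma2, 3))), n, 3)
  mb <- matrix(rnorm(n * 3, 0, sqrt(rep(sigma2, 3))), n, 3)
  stats_df <- diaquant:::row_t_tests(ma, mb)
  fit <- estimate_moderation(stats_df$s2, stats_df$df)
  mod <- moderated_t(stats_df, fit)
  ks <- suppressWarnings(stats::ks.test(mod$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("uniform-median distribution function is exact for odd n and convolved for even n", {
  # n = 1: identity on [0,1]
  expect_equal(pmedian_uniform(c(0.2, 0.7), 1), c(0.2, 0.7))
  # n = 3, x = 0.5: Beta(2,2) symmetry
  expect_equal(pmedian_uniform(0.5, 3), 0.5)
  # even n = 2: closed form 2x^2 below 0.5
  expect_equal(pmedian_uniform(0.3, 2), 2 * 0.3^2, tolerance = 1e-9)
  expect_equal(pmedian_uniform(0.5, 2), 0.5, tolerance = 1e-9)
  # even n vs Monte-Carlo oracle
  set.seed(91)
  for (n in c(4, 6)) {
    draws <- matrix(runif(2e5 * n), ncol = n)
    med <- apply(draws, 1, median)
    for (x in c(0.1, 0.5)) {
      mc <- mean(med <= x)
      se <- sqrt(mc * (1 - mc) / length(med))
      expect_lt(abs(pmedian_uniform(x, n) - mc), 4 * se + 1e-4)
    }
  }
  # monotone in x for fixed n
  for (n in 2:8) {
    v <- pmedian_uniform(seq(0.01, 0.99, by = 0.01), n)
    expect_true(all(diff(v) >= 0))
  }
})

test_that("PECA aggregation combines peptide ratios and p-values", {
  # single peptide: protein p equals peptide p
  r1 <- ropeca_aggregate(1.5, 0.07)
  expect_equal(r1$protein_p, 0.07)
  expect_equal(r1$median_log2_ratio, 1.5)
  # n = 3, median p = 0.5: Beta(2,2) symmetry gives 0.5
  r3 <- ropeca_aggregate(c(1, 1.2, 0.8), c(0.4, 0.5, 0.9))
  expect_equal(r3$protein_p, 0.5)
  expect_equal(r3$median_log2_ratio, 1)
  # n = 5, median p = 0.1 vs Monte-Carlo
  set.seed(61)
  med5 <- apply(matrix(runif(5e5 * 5), ncol = 5), 1, median)
  mc <- mean(med5 <= 0.1)
  se <- sqrt(mc * (1 - mc) / length(med5))
  r5 <- ropeca_aggregate(rep(0.5, 5), c(0.05, 0.08, 0.1, 0.5, 0.9))
  expect_equal(r5$median_p, 0.1)
  expect_lt(abs(r5$protein_p - mc), 3 * se)
  # protein_p monotone in median_p for fixed n
  for (n in c(3, 4, 5)) {
    pp <- vapply(seq(0.05, 0.95, by = 0.05), pmedian_uniform, numeric(1), n = n)
    expect_true(all(diff(pp) >= 0))
  }
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(121)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("protein effect size is Cohen's d with degenerate-case flags", {
  expect_equal(protein_effect_size(c(1, 2, 3), c(1, 2, 3)), 0)
  z <- protein_effect_size(c(2, 2), c(0, 0))
  expect_true(is.na(z))
  expect_equal(attr(z, "flag"), "zero_pooled_sd")
  expect_equal(protein_effect_size(c(1, 2, 3), c(0, 1, 2)), 1.0)
})

test_that("differential statistics produce coherent protein tables", {
  study <- generate_study(simulation_config(n_proteins = 50, seed = 19))
  pm <- log2_median_normalize(
    condition_wise_filter(build_peptide_matrix(
      remove_oxidized_met(filter_qvalues(study$table)), study$design)))
  pq <- quantify_proteins(pm, "maxlfq")
  iq <- quantify_proteins(pm, "ibaq", sequences = study$fasta)
  ann <- assign_ibaq_deciles(iq, study$comparisons)
  st <- differential_stats(pm, study$comparisons, protein_quant = pq,
                           deciles = ann)
  df <- st[["B_vs_A"]]
  expect_true(all(df$protein_p >= 0 & df$protein_p <= 1))
  expect_true(all(df$adj_p >= df$protein_p - 1e-12))
  expect_equal(df$adj_p, bh_adjust(df$protein_p))
  expect_true(all(df$n_peptides_tested >= 1))
  expect_true(all(c("decile_num", "decile_den", "code_2d", "effect_size")
                  %in% names(df)))
  # plain-t variant runs and differs only in the peptide statistic
  st_t <- differential_stats(pm, study$comparisons,
                             peptide_statistic = "t")
  expect_equal(st_t[["B_vs_A"]]$protein_group, df$protein_group)
  # unknown condition is rejected
  expect_error(differential_stats(pm, data.frame(numerator = "Z",
                                                 denominator = "A")),
               "unknown condition")
})

test_that("ROPECA with moderated t finds at least as many true positives as plain protein-level t", {
  study <- generate_study(simulation_config(n_proteins = 150, seed = 29,
                                            replicate_noise_sd = 0.4))
  pm <- log2_median_normalize(
    condition_wise_filter(build_peptide_matrix(study$table, study$design)))
  st <- differential_stats(pm, study$comparisons)
  df <- st[["B_vs_A"]]
  truth <- study$truth
  reg <- truth$protein_group[truth$regulated]
  tp_ropeca <- sum(df$protein_group %in% reg & df$adj_p < 0.05)
  # competitor: plain t on per-protein median peptide profiles
  pq <- quantify_proteins(pm, "maxlfq")
  cols_a <- which(study$design$condition == "A")
  cols_b <- which(study$design$condition == "B")
  pvals <- apply(pq$log2_values, 1, function(v) {
    r <- peptide_t_test(v[cols_b], v[cols_a])
    if (is.null(r)) NA_real_ else r$p_value
  })
  padj <- bh_adjust(pvals)
  tp_plain <- sum(names(padj) %in% reg & padj < 0.05, na.rm = TRUE)
  expect_gte(tp_ropeca, tp_plain)
})
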