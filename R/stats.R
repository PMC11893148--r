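#' Two-sample t-test on log2 intensities of one peptide
#'
#' Pooled-variance (default) or Welch two-sided t-test; the log2 ratio is
#' mean(A) - mean(B).
#'
#' @param values_a,values_b numeric log2 intensities (NAs dropped).
#' @param var_equal pooled variance if TRUE (default), Welch otherwise.
#' @return list with `log2_ratio`, `t_statistic`, `df`, `p_value`, `n_a`,
#'   `n_b`, `s2` (residual variance) and `se_factor` (1/n_a + 1/n_b), or
#'   NULL if either group has fewer than 2 finite values.
#' @export
peptide_t_test <- function(values_a, values_b, var_equal = TRUE) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) return(NULL)
  ratio <- mean(a) - mean(b)
  if (var_equal) {
    s2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    df <- na + nb - 2
    se_factor <- 1 / na + 1 / nb
    se <- sqrt(s2 * se_factor)
  } else {
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    s2 <- va + vb
    se_factor <- 1
    se <- sqrt(s2)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  if (se == 0) {
    t_stat <- if (ratio == 0) 0 else sign(ratio) * Inf
    p <- if (ratio == 0) 1 else 0
  } else {
    t_stat <- ratio / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  list(log2_ratio = ratio, t_statistic = t_stat, df = df, p_value = p,
       n_a = na, n_b = nb, s2 = s2, se_factor = se_factor)
}

# vectorized pooled t-tests for all rows of two log2 matrices at once
row_t_tests <- function(mat_a, mat_b) {
  na <- rowSums(is.finite(mat_a))
  nb <- rowSums(is.finite(mat_b))
  ok <- na >= 2L & nb >= 2L
  mean_a <- rowMeans(mat_a, na.rm = TRUE)
  mean_b <- rowMeans(mat_b, na.rm = TRUE)
  ss_a <- rowSums((mat_a - mean_a)^2, na.rm = TRUE)
  ss_b <- rowSums((mat_b - mean_b)^2, na.rm = TRUE)
  df <- na + nb - 2
  s2 <- (ss_a + ss_b) / df
  se_factor <- 1 / na + 1 / nb
  se <- sqrt(s2 * se_factor)
  ratio <- mean_a - mean_b
  t_stat <- ifelse(se > 0, ratio / se,
                   ifelse(ratio == 0, 0, sign(ratio) * Inf))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df),
              ifelse(ratio == 0, 1, 0))
  data.frame(log2_ratio = ratio, t_statistic = t_stat, df = df, p_value = p,
             n_a = na, n_b = nb, s2 = s2, se_factor = se_factor,
             tested = ok)
}

# Newton solve of trigamma(y) = x (x > 0); same iteration family limma uses
# for its F-distribution fit, written here directly
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NA_real_)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate empirical-Bayes variance-moderation parameters
#'
#' Fits a scaled inverse-chi-square prior to observed residual variances by
#' matching the mean and spread of log variances against digamma/trigamma
#' identities (method of moments on the log scale). If the observed spread
#' does not exceed the spread expected from sampling alone, the prior
#' degrees of freedom are infinite (all variances shrink to a common value).
#'
#' @param s2 residual variances (one per peptide).
#' @param df residual degrees of freedom (recycled if length 1).
#' @return list with `d0` (prior df, possibly Inf) and `s0_sq` (prior
#'   variance).
#' @export
estimate_moderation <- function(s2, df) {
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(is.finite(s2) & df >= 1) > 0L && all(s2[is.finite(s2) & df >= 1] == 0))
    abort("degenerate variances: all residual variances are zero")
  s2 <- s2[keep]; df <- df[keep]
  if (length(s2) < 3L)
    abort("too few positive residual variances (%d) to fit a prior", length(s2))
  if (length(s2) < 10L)
    warnf("only %d residual variances: moderation prior is low-confidence", length(s2))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  excess <- stats::var(e) * (length(e) - 1) / length(e) - mean(trigamma(df / 2))
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(e_mean)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics from peptide t-test results
#'
#' Shrinks each peptide's residual variance toward the prior:
#' `s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df)`; the moderated t uses the
#' original standard-error structure with `s2_tilde` and is referred to a t
#' distribution with `d0 + df` degrees of freedom. `d0 = 0` reproduces the
#' ordinary test; `d0 = Inf` fixes all variances at `s0_sq` and uses the
#' normal reference.
#'
#' @param stats_df data.frame from [row_t_tests()]-style columns
#'   (`log2_ratio`, `df`, `s2`, `se_factor`).
#' @param params list with `d0`, `s0_sq` from [estimate_moderation()].
#' @return `stats_df` with `t_statistic`, `df`, `p_value` replaced by their
#'   moderated versions (original values kept as `t_ordinary`,
#'   `df_ordinary`, `p_ordinary`).
#' @export
moderated_t <- function(stats_df, params) {
  d0 <- params$d0; s0 <- params$s0_sq
  out <- stats_df
  out$t_ordinary <- stats_df$t_statistic
  out$df_ordinary <- stats_df$df
  out$p_ordinary <- stats_df$p_value
  if (d0 == 0) return(out)
  s2_tilde <- if (is.infinite(d0)) rep(s0, nrow(stats_df)) else
    (d0 * s0 + stats_df$df * stats_df$s2) / (d0 + stats_df$df)
  se <- sqrt(s2_tilde * stats_df$se_factor)
  t_mod <- ifelse(se > 0, stats_df$log2_ratio / se,
                  ifelse(stats_df$log2_ratio == 0, 0,
                         sign(stats_df$log2_ratio) * Inf))
  df_mod <- d0 + stats_df$df
  p_mod <- ifelse(is.infinite(df_mod),
                  2 * stats::pnorm(-abs(t_mod)),
                  2 * stats::pt(-abs(t_mod), df_mod))
  out$t_statistic <- t_mod
  out$df <- df_mod
  out$p_value <- ifelse(is.finite(t_mod), p_mod,
                        ifelse(stats_df$log2_ratio == 0, 1, 0))
  out
}

#' Distribution function of the sample median of n iid Uniform(0,1)
#'
#' For odd n the median is the central order statistic, Beta(k, n-k+1) with
#' k = (n+1)/2. For even n it is the average of the two central order
#' statistics; its exact CDF is evaluated by reducing the joint density of
#' the order-statistic pair to a one-dimensional integral.
#'
#' @param x evaluation points in `[0, 1]`.
#' @param n sample size (>= 1).
#' @return `P(median of n uniforms <= x)` for each x.
#' @export
pmedian_uniform <- function(x, n) {
  stopifnot(n >= 1L)
  if (n %% 2L == 1L) {
    k <- (n + 1L) / 2L
    return(stats::pbeta(x, k, n - k + 1L))
  }
  k <- n / 2L
  # joint density of (U_(k), U_(k+1)): K u^(k-1) (1-v)^(n-k-1) on u < v
  K <- exp(lgamma(n + 1) - lgamma(k) - lgamma(n - k))
  one <- function(xx) {
    if (xx <= 0) return(0)
    if (xx >= 1) return(1)
    # P(U_(k) + U_(k+1) <= 2x); inner integral over u is closed-form
    f1 <- function(v) (1 - v)^(n - k - 1) * v^k            # v in [0, x]
    f2 <- function(v) (1 - v)^(n - k - 1) * (2 * xx - v)^k # v in [x, min(2x,1)]
    upper <- min(2 * xx, 1)
    i1 <- stats::integrate(f1, 0, xx, rel.tol = 1e-10)$value
    i2 <- if (upper > xx)
      stats::integrate(f2, xx, upper, rel.tol = 1e-10)$value else 0
    min(1, (K / k) * (i1 + i2))
  }
  vapply(x, one, numeric(1))
}

#' PECA aggregation of peptide statistics to one protein
#'
#' The protein log2 ratio is the median of its peptide log2 ratios; the
#' protein p-value is the probability that the median of n iid Uniform(0,1)
#' p-values falls at or below the observed median peptide p-value (beta
#' order-statistic significance).
#'
#' @param log2_ratios,p_values peptide-level values of one protein (equal
#'   length, NAs dropped pairwise).
#' @return list with `n_peptides_tested`, `median_log2_ratio`, `median_p`,
#'   `protein_p`.
#' @export
ropeca_aggregate <- function(log2_ratios, p_values) {
  keep <- !is.na(p_values)
  p <- p_values[keep]; r <- log2_ratios[keep]
  n <- length(p)
  if (n == 0L) abort("no peptide p-values to aggregate")
  med_p <- stats::median(p)
  list(n_peptides_tested = n,
       median_log2_ratio = stats::median(r),
       median_p = med_p,
       protein_p = pmedian_uniform(med_p, n))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a p-value vector
#' (monotone, order-preserving, capped at 1).
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Cohen's d between two per-sample protein profiles
#'
#' @param values_a,values_b per-sample protein log2 values per condition
#'   (NAs dropped).
#' @return Standardized mean difference (pooled SD); NA with
#'   `attr(, "flag") == "zero_pooled_sd"` when the pooled SD is zero, NA
#'   when either group has fewer than 2 values.
#' @export
protein_effect_size <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0)
    return(structure(NA_real_, flag = "zero_pooled_sd"))
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Peptide-centric differential statistics per comparison
#'
#' For each comparison, every precursor with >= 2 finite values per condition
#' is tested (pooled t, optionally moderated by an empirical-Bayes variance
#' prior fitted across all tested peptides of the comparison); peptide
#' results aggregate to protein level by the PECA median rule
#' ([ropeca_aggregate()]), followed by Benjamini-Hochberg adjustment across
#' proteins. Effect sizes are Cohen's d on per-sample protein profiles
#' (MaxLFQ by default), and iBAQ deciles of both conditions are attached
#' when available.
#'
#' @param matrix a `peptide_matrix` (filtered/normalized/adjusted).
#' @param comparisons data.frame with columns `numerator`, `denominator`.
#' @param peptide_statistic `"moderated_t"` (default; the ROPECA-style
#'   pipeline) or `"t"` for the plain pooled t-test.
#' @param protein_quant optional `protein_quant` whose log2 profiles feed
#'   effect sizes.
#' @param deciles optional `ibaq_deciles` annotation.
#' @param alpha significance threshold recorded for reporting (default 0.05).
#' @return A `protein_stats` object: list of per-comparison data.frames with
#'   columns `protein_group`, `n_peptides_tested`, `median_log2_ratio`,
#'   `median_p`, `protein_p`, `adj_p`, `effect_size`, and decile/code columns
#'   when annotation is supplied. Peptide-level tables are in
#'   `attr(, "peptide_stats")`.
#' @export
differential_stats <- function(matrix, comparisons,
                               peptide_statistic = c("moderated_t", "t"),
                               protein_quant = NULL, deciles = NULL,
                               alpha = 0.05) {
  peptide_statistic <- match.arg(peptide_statistic)
  design <- matrix$design
  bad <- setdiff(c(comparisons$numerator, comparisons$denominator),
                 design$condition)
  if (length(bad) > 0L)
    abort("comparison references unknown condition(s): %s",
          paste(unique(bad), collapse = ", "))
  results <- list()
  peptide_tables <- list()
  for (k in seq_len(nrow(comparisons))) {
    ca <- comparisons$numerator[k]; cb <- comparisons$denominator[k]
    cols_a <- which(design$condition == ca)
    cols_b <- which(design$condition == cb)
    if (length(cols_a) < 2L || length(cols_b) < 2L)
      abort("comparison %s vs %s needs >= 2 replicates per condition", ca, cb)
    pep <- row_t_tests(matrix$values[, cols_a, drop = FALSE],
                       matrix$values[, cols_b, drop = FALSE])
    pep$precursor_id <- matrix$row_meta$precursor_id
    pep$protein_group <- matrix$row_meta$protein_group
    pep <- pep[pep$tested, , drop = FALSE]
    if (nrow(pep) == 0L)
      abort("no testable peptides for comparison %s vs %s", ca, cb)
    if (peptide_statistic == "moderated_t") {
      params <- estimate_moderation(pep$s2, pep$df)
      pep <- moderated_t(pep, params)
    } else {
      params <- list(d0 = 0, s0_sq = NA_real_)
    }
    agg <- lapply(split(pep, pep$protein_group), function(d)
      ropeca_aggregate(d$log2_ratio, d$p_value))
    prot <- data.frame(
      protein_group = names(agg),
      n_peptides_tested = vapply(agg, `[[`, numeric(1), "n_peptides_tested"),
      median_log2_ratio = vapply(agg, `[[`, numeric(1), "median_log2_ratio"),
      median_p = vapply(agg, `[[`, numeric(1), "median_p"),
      protein_p = vapply(agg, `[[`, numeric(1), "protein_p"),
      stringsAsFactors = FALSE
    )
    rownames(prot) <- NULL
    prot$adj_p <- bh_adjust(prot$protein_p)
    prot$effect_size <- NA_real_
    if (!is.null(protein_quant)) {
      pq <- protein_quant$log2_values
      idx <- match(prot$protein_group, rownames(pq))
      for (i in which(!is.na(idx))) {
        prot$effect_size[i] <- protein_effect_size(
          pq[idx[i], cols_a], pq[idx[i], cols_b])
      }
    }
    if (!is.null(deciles)) {
      m <- match(prot$protein_group, deciles$protein_group)
      dn <- paste0("decile_", ca); dd <- paste0("decile_", cb)
      if (dn %in% names(deciles)) prot$decile_num <- deciles[[dn]][m]
      if (dd %in% names(deciles)) prot$decile_den <- deciles[[dd]][m]
      if (all(c("decile_num", "decile_den") %in% names(prot)))
        prot$code_2d <- paste(prot$decile_num, prot$decile_den, sep = "|")
    }
    prot <- prot[order(prot$protein_group), , drop = FALSE]
    rownames(prot) <- NULL
    label <- sprintf("%s_vs_%s", ca, cb)
    attr(prot, "moderation") <- params
    results[[label]] <- prot
    peptide_tables[[label]] <- pep
  }
  structure(results, peptide_stats = peptide_tables, alpha = alpha,
            peptide_statistic = peptide_statistic, class = "protein_stats")
}

#' @export
print.protein_stats <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf("protein_stats (%s peptide statistic):\n",
              attr(x, "peptide_statistic")))
  for (nm in names(x)) {
    cat(sprintf("  %s: %d proteins, %d with adj_p < %g\n", nm, nrow(x[[nm]]),
                sum(x[[nm]]$adj_p < alpha, na.rm = TRUE), alpha))
  }
  invisible(x)
}
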