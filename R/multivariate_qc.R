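#' Principal component analysis of a feature x sample matrix
#'
#' Features with any missing value are dropped (complete-case), samples are
#' the observations, features are centered (optionally unit-scaled), and the
#' decomposition is by SVD. Sign convention: each loading vector's
#' largest-magnitude entry is positive, making outputs reproducible across
#' platforms.
#'
#' @param matrix numeric feature x sample matrix (log2 scale expected).
#' @param n_components number of components to keep (default
#'   `min(n_samples - 1, n_complete_features)`).
#' @param scale. unit-scale features before decomposition (default FALSE).
#' @return A `pca_result`: list with `scores` (sample x component),
#'   `loadings` (feature x component), `explained_variance_fraction`, and
#'   `n_features_used`.
#' @export
pca <- function(matrix, n_components = NULL, scale. = FALSE) {
  cc <- stats::complete.cases(matrix)
  m <- matrix[cc, , drop = FALSE]
  if (ncol(m) < 2L) abort("PCA needs >= 2 samples")
  if (nrow(m) < 2L) abort("PCA needs >= 2 complete-case features (have %d)", nrow(m))
  sds <- apply(m, 1L, stats::sd)
  if (all(sds == 0)) abort("PCA input has zero total variance (identical samples)")
  if (scale.) m <- m[sds > 0, , drop = FALSE]
  pr <- stats::prcomp(t(m), center = TRUE, scale. = scale.)
  k_max <- sum(pr$sdev > .Machine$double.eps^0.5 * pr$sdev[1])
  k <- min(n_components %||% k_max, ncol(pr$x))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = ev[seq_len(k)],
                 n_features_used = nrow(m)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components (%d complete features)\n",
              nrow(x$scores), ncol(x$scores), x$n_features_used))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise-complete sample correlation matrix
#'
#' @param matrix feature x sample matrix (missing allowed).
#' @param min_shared minimum shared finite observations per sample pair
#'   (default 3); pairs below it get NA.
#' @return list with `correlation` (sample x sample Pearson, unit diagonal)
#'   and `n_shared` (pairwise-complete observation counts).
#' @export
sample_correlation <- function(matrix, min_shared = 3L) {
  if (ncol(matrix) < 2L) abort("need >= 2 samples")
  n_shared <- crossprod(!is.na(matrix))
  cors <- suppressWarnings(
    stats::cor(matrix, use = "pairwise.complete.obs", method = "pearson"))
  cors[n_shared < min_shared] <- NA_real_
  diag(cors) <- 1
  list(correlation = cors, n_shared = n_shared)
}

#' Coefficient-of-variation summary per condition
#'
#' CV = SD/mean over observed replicates on the linear intensity scale;
#' features with fewer than 2 observations in a condition are excluded.
#'
#' @param linear_matrix feature x sample matrix of linear-scale intensities.
#' @param design a `study_design` matching the columns.
#' @return list with `per_feature` (data.frame feature x condition CVs) and
#'   `median_cv` (named per-condition medians).
#' @export
cv_summary <- function(linear_matrix, design) {
  conds <- unique(design$condition)
  out <- data.frame(feature = rownames(linear_matrix) %||%
                      as.character(seq_len(nrow(linear_matrix))),
                    stringsAsFactors = FALSE)
  meds <- stats::setNames(numeric(length(conds)), conds)
  for (cc in conds) {
    cols <- which(design$condition == cc)
    sub <- linear_matrix[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    cv <- ifelse(n_obs >= 2L, sdv / mu, NA_real_)
    out[[paste0("cv_", cc)]] <- cv
    meds[cc] <- stats::median(cv, na.rm = TRUE)
  }
  list(per_feature = out, median_cv = meds)
}

#' ON/OFF presence-absence analysis
#'
#' A protein is detected in a run when at least one of its precursors has a
#' non-missing quantity (apply q-value filters first). Per comparison, a
#' protein is called ON in one condition when its detection fraction reaches
#' `min_on_fraction` there and stays at or below `max_off_fraction` in the
#' other.
#'
#' @param table a (q-filtered) `precursor_table`.
#' @param design a `study_design`.
#' @param comparisons data.frame with `numerator`, `denominator`.
#' @param min_on_fraction,max_off_fraction detection-fraction thresholds
#'   (defaults 1.0 / 0.0: strict presence/absence);
#'   `min_on_fraction > max_off_fraction` required.
#' @return data.frame: `protein_group`, one `frac_<cond>` column per
#'   condition, and one `call_<num>_vs_<den>` column per comparison with
#'   values `ON_in_<num>`, `ON_in_<den>` or `none`.
#' @export
on_off_analysis <- function(table, design, comparisons,
                            min_on_fraction = 1.0, max_off_fraction = 0.0) {
  if (min_on_fraction <= max_off_fraction)
    abort("min_on_fraction must exceed max_off_fraction")
  obs <- table[!is.na(table$quantity), c("protein_group", "run_id")]
  obs <- unique(obs)
  prots <- sort(unique(table$protein_group))
  out <- data.frame(protein_group = prots, stringsAsFactors = FALSE)
  fracs <- list()
  for (cc in unique(design$condition)) {
    runs <- design$run_id[design$condition == cc]
    det <- obs[obs$run_id %in% runs, , drop = FALSE]
    counts <- table(factor(det$protein_group, levels = prots))
    fracs[[cc]] <- as.numeric(counts) / length(runs)
    out[[paste0("frac_", cc)]] <- fracs[[cc]]
  }
  for (k in seq_len(nrow(comparisons))) {
    a <- comparisons$numerator[k]; b <- comparisons$denominator[k]
    fa <- fracs[[a]]; fb <- fracs[[b]]
    call <- rep("none", length(prots))
    call[fa >= min_on_fraction & fb <= max_off_fraction] <- paste0("ON_in_", a)
    call[fb >= min_on_fraction & fa <= max_off_fraction] <- paste0("ON_in_", b)
    out[[sprintf("call_%s_vs_%s", a, b)]] <- call
  }
  out
}
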