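#' Censor quantities by identification q-values
#'
#' Rows whose precursor or protein-group q-value exceeds the threshold keep
#' their identity but lose their quantity (set to missing), so ID-rate
#' summaries can still be compared pre/post filter on one table.
#'
#' @param table a `precursor_table`.
#' @param max_precursor_q,max_pg_q thresholds in (0, 1].
#' @return The filtered `precursor_table`; the number of censored quantities
#'   is stored in `attr(, "n_censored")`.
#' @export
filter_qvalues <- function(table, max_precursor_q = 0.01, max_pg_q = 0.01) {
  stopifnot(max_precursor_q > 0, max_precursor_q <= 1,
            max_pg_q > 0, max_pg_q <= 1)
  fail <- (!is.na(table$precursor_qvalue) & table$precursor_qvalue > max_precursor_q) |
          (!is.na(table$pg_qvalue) & table$pg_qvalue > max_pg_q)
  n_censored <- sum(fail & !is.na(table$quantity))
  table$quantity[fail] <- NA_real_
  attr(table, "n_censored") <- n_censored
  table
}

#' Remove precursors carrying oxidized-methionine modifications
#'
#' Any precursor whose modified sequence contains one of the tag substrings
#' is dropped from all runs.
#'
#' @param table a `precursor_table`.
#' @param tags modification tag substrings matched literally; defaults cover
#'   the common report dialects.
#' @return The filtered `precursor_table`; distinct dropped precursors in
#'   `attr(, "n_dropped_precursors")`.
#' @export
remove_oxidized_met <- function(table,
                                tags = c("Oxidation (M)", "M[Oxidation]",
                                         "M(ox)")) {
  if (length(tags) == 0L) abort("tag list must be non-empty")
  hit <- rep(FALSE, nrow(table))
  for (tag in tags)
    hit <- hit | grepl(tag, table$modified_sequence, fixed = TRUE)
  out <- table[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_precursors") <- length(unique(table$precursor_id[hit]))
  out
}

#' Build a log2 peptide-intensity matrix from a precursor table
#'
#' Pivots the long table to a precursor x sample matrix of log2 intensities,
#' with columns ordered as in the study design.
#'
#' @param table a `precursor_table`.
#' @param design a `study_design`; every design run must occur in the table's
#'   runs and vice versa.
#' @return A `peptide_matrix`: list with `values` (log2 matrix, rows =
#'   precursor_id, cols = run_id), `row_meta` (precursor_id, protein_group,
#'   stripped_sequence), `design`, and `offsets` (NULL until normalization).
#' @export
build_peptide_matrix <- function(table, design) {
  runs_tab <- unique(table$run_id)
  if (!setequal(runs_tab, design$run_id))
    abort("run mismatch between report and design (report-only: %s; design-only: %s)",
          paste(setdiff(runs_tab, design$run_id), collapse = ","),
          paste(setdiff(design$run_id, runs_tab), collapse = ","))
  prec <- unique(table$precursor_id)
  values <- matrix(NA_real_, nrow = length(prec), ncol = nrow(design),
                   dimnames = list(prec, design$run_id))
  ok <- !is.na(table$quantity)
  values[cbind(match(table$precursor_id[ok], prec),
               match(table$run_id[ok], design$run_id))] <-
    log2(table$quantity[ok])
  first <- !duplicated(table$precursor_id)
  row_meta <- data.frame(
    precursor_id = table$precursor_id[first],
    protein_group = table$protein_group[first],
    stripped_sequence = table$stripped_sequence[first],
    stringsAsFactors = FALSE
  )
  row_meta <- row_meta[match(prec, row_meta$precursor_id), , drop = FALSE]
  rownames(row_meta) <- NULL
  if (all(is.na(values)))
    warnf("peptide matrix contains no finite values")
  structure(list(values = values, row_meta = row_meta, design = design,
                 offsets = NULL, flags = list()),
            class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf("peptide_matrix: %d precursors x %d samples (%d conditions)\n",
              nrow(x$values), ncol(x$values), length(unique(x$design$condition))))
  cat(sprintf("  missing: %.1f%%; normalized: %s\n",
              100 * mean(is.na(x$values)),
              if (is.null(x$offsets)) "no" else "yes"))
  invisible(x)
}

#' Condition-wise completeness filter
#'
#' Keeps a precursor row iff in at least one condition the fraction of
#' non-missing values reaches `min_fraction`.
#'
#' @param matrix a `peptide_matrix`.
#' @param min_fraction required fraction of observed replicates in (0, 1].
#' @return The filtered `peptide_matrix`; kept/dropped counts in
#'   `attr(, "n_kept")` / `attr(, "n_dropped")`.
#' @export
condition_wise_filter <- function(matrix, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  cond <- matrix$design$condition
  keep <- rep(FALSE, nrow(matrix$values))
  for (cc in unique(cond)) {
    cols <- which(cond == cc)
    frac <- rowMeans(!is.na(matrix$values[, cols, drop = FALSE]))
    keep <- keep | (frac >= min_fraction)
  }
  out <- matrix
  out$values <- matrix$values[keep, , drop = FALSE]
  out$row_meta <- matrix$row_meta[keep, , drop = FALSE]
  rownames(out$row_meta) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Median normalization of log2 intensities
#'
#' Each sample column is shifted so that all column medians equal the median
#' of the original column medians (median-of-medians centering).
#'
#' @param matrix a `peptide_matrix`.
#' @return The normalized `peptide_matrix` with per-column log2 `offsets`
#'   recorded (subtracted from each column).
#' @export
log2_median_normalize <- function(matrix) {
  meds <- apply(matrix$values, 2L, finite_median)
  if (anyNA(meds))
    abort("cannot normalize: run(s) with no finite values: %s",
          paste(colnames(matrix$values)[is.na(meds)], collapse = ", "))
  reference <- stats::median(meds)
  offsets <- meds - reference
  out <- matrix
  out$values <- sweep(matrix$values, 2L, offsets, `-`)
  out$offsets <- stats::setNames(offsets, colnames(matrix$values))
  out
}

# model matrix for condition + batch + covariates; condition first so
# nuisance columns are everything after the condition block
design_model_matrix <- function(design) {
  covars <- attr(design, "covariates") %||% character(0)
  has_batch <- "batch" %in% names(design) &&
    length(unique(design$batch)) > 1L  # single-level batch carries no effect
  covars <- covars[vapply(covars, function(v)
    length(unique(design[[v]])) > 1L, logical(1))]
  terms <- c("condition", if (has_batch) "batch", covars)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  df <- as.data.frame(design)
  df$condition <- factor(df$condition)
  if ("batch" %in% names(df)) df$batch <- factor(df$batch)
  X <- stats::model.matrix(fml, df)
  n_cond_cols <- 1L + (nlevels(df$condition) - 1L)
  attr(X, "nuisance_cols") <- setdiff(seq_len(ncol(X)), seq_len(n_cond_cols))
  X
}

#' Batch and covariate adjustment of peptide intensities
#'
#' Fits, per precursor row, an ordinary least-squares model of log2 intensity
#' on condition + batch + covariates (missing cells omitted) and subtracts
#' the fitted batch/covariate contributions, leaving condition effects and
#' residuals in place. Rows with too few observations to fit pass through
#' unadjusted and are flagged.
#'
#' @param matrix a `peptide_matrix`.
#' @param design a `study_design` with a `batch` and/or covariate column;
#'   defaults to the design stored in the matrix.
#' @return The adjusted `peptide_matrix`; row names of unadjusted rows in
#'   `attr(, "unadjusted_rows")`.
#' @export
adjust_batch_covariates <- function(matrix, design = matrix$design) {
  covars <- attr(design, "covariates") %||% character(0)
  if (!("batch" %in% names(design)) && length(covars) == 0L)
    return(matrix)  # nothing to adjust
  X <- design_model_matrix(design)
  if (length(attr(X, "nuisance_cols")) == 0L) return(matrix)
  if (qr(X)$rank < ncol(X)) {
    abort(paste("design is confounded: condition + batch/covariates do not",
                "have full rank; batch levels must span conditions"))
  }
  nuis <- attr(X, "nuisance_cols")
  if (length(nuis) == 0L) return(matrix)
  vals <- matrix$values
  p <- ncol(X)
  pattern <- apply(!is.na(vals), 1L, function(r)
    paste(as.integer(r), collapse = ""))
  adjusted <- vals
  skipped <- character(0)
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    obs <- which(strsplit(pat, "")[[1]] == "1")
    Xo <- X[obs, , drop = FALSE]
    if (length(obs) <= p || qr(Xo)$rank < p) {
      if (length(obs) > 0L) skipped <- c(skipped, rownames(vals)[rows])
      next
    }
    # one QR solve per missingness pattern covers all its rows at once
    Y <- t(vals[rows, obs, drop = FALSE])
    beta <- qr.coef(qr(Xo), Y)                       # p x length(rows)
    nuisance_fit <- X[, nuis, drop = FALSE] %*% beta[nuis, , drop = FALSE]
    adjusted[rows, ] <- vals[rows, , drop = FALSE] - t(nuisance_fit)
  }
  out <- matrix
  out$values <- adjusted
  out$flags$unadjusted_rows <- skipped
  attr(out, "unadjusted_rows") <- skipped
  out
}
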