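#' iBAQ value of one protein
#'
#' Intensity-based absolute quantification: summed linear-scale precursor
#' intensity per sample divided by the number of theoretically observable
#' tryptic peptides.
#'
#' @param linear_matrix peptide x sample matrix of linear-scale intensities
#'   (missing allowed); a vector is treated as a single-peptide matrix.
#' @param observable_count observable tryptic peptide count (>= 1).
#' @return Per-sample iBAQ values; samples with no observed precursor are NA.
#' @export
ibaq <- function(linear_matrix, observable_count) {
  if (is.vector(linear_matrix)) linear_matrix <- rbind(linear_matrix)
  if (is.na(observable_count) || observable_count < 1)
    abort("iBAQ undefined: no theoretical peptides")
  sums <- colSums(linear_matrix, na.rm = TRUE)
  none <- colSums(!is.na(linear_matrix)) == 0L
  out <- sums / observable_count
  out[none] <- NA_real_
  out
}

#' Hi3/Top3 value of one protein
#'
#' Mean of the three most intense precursors per sample; if fewer than three
#' are observed, the mean of those observed.
#'
#' @param linear_matrix peptide x sample matrix of linear-scale intensities.
#' @return Per-sample Hi3 values with the number of peptides used per sample
#'   in `attr(, "n_used")`.
#' @export
top3 <- function(linear_matrix) {
  if (is.vector(linear_matrix)) linear_matrix <- rbind(linear_matrix)
  vals <- apply(linear_matrix, 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(NA_real_, 0))
    x <- sort(x, decreasing = TRUE)
    k <- min(3L, length(x))
    c(mean(x[seq_len(k)]), k)
  })
  structure(vals[1L, ], n_used = as.integer(vals[2L, ]))
}

# connected components of samples linked by valid pairwise ratios
pair_components <- function(n, pairs) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' MaxLFQ profile of one protein
#'
#' For every sample pair with at least `min_peptides_pair` peptides observed
#' in both, the pairwise log2 ratio is the median of peptide differences; the
#' per-sample log2 profile minimizes the sum of squared deviations from these
#' ratios. The profile's free constant (per connected component) is fixed so
#' that its summed linear-scale intensity equals the protein's summed
#' observed intensity.
#'
#' @param log2_matrix peptide x sample matrix of log2 intensities.
#' @param min_peptides_pair minimum shared peptides for a valid pair
#'   (default 2).
#' @return Per-sample log2 profile; samples with no data are NA. If no valid
#'   pair exists among >1 samples with data, falls back to log2 of summed
#'   intensity with `attr(, "flag") == "maxlfq_fallback"`.
#' @export
maxlfq <- function(log2_matrix, min_peptides_pair = 2L) {
  if (is.vector(log2_matrix)) log2_matrix <- rbind(log2_matrix)
  n <- ncol(log2_matrix)
  obs <- !is.na(log2_matrix)
  has_data <- colSums(obs) > 0L
  profile <- rep(NA_real_, n)
  names(profile) <- colnames(log2_matrix)
  if (!any(has_data)) return(profile)
  pairs <- NULL
  ratios <- NULL
  idx <- which(has_data)
  if (length(idx) > 1L) {
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        shared <- obs[, i] & obs[, j]
        if (sum(shared) >= min_peptides_pair) {
          pairs <- rbind(pairs, c(i, j))
          ratios <- c(ratios,
                      stats::median(log2_matrix[shared, i] - log2_matrix[shared, j]))
        }
      }
    }
  }
  flag <- NULL
  if (is.null(pairs)) {
    if (length(idx) > 1L) flag <- "maxlfq_fallback"
    profile[idx] <- log2(colSums(2^log2_matrix[, idx, drop = FALSE], na.rm = TRUE))
    return(structure(profile, flag = flag))
  }
  comp <- pair_components(n, pairs)
  for (cc in unique(comp[idx])) {
    members <- which(comp == cc & has_data)
    prs <- pairs[comp[pairs[, 1L]] == cc, , drop = FALSE]
    rts <- ratios[comp[pairs[, 1L]] == cc]
    if (nrow(prs) == 0L) {
      # isolated sample (or unpairable): summed intensity on its own gauge
      profile[members] <- log2(colSums(2^log2_matrix[, members, drop = FALSE],
                                       na.rm = TRUE))
      next
    }
    D <- matrix(0, nrow(prs) + 1L, length(members))
    for (r in seq_len(nrow(prs))) {
      D[r, match(prs[r, 1L], members)] <- 1
      D[r, match(prs[r, 2L], members)] <- -1
    }
    D[nrow(prs) + 1L, ] <- 1  # gauge row: sum p = 0, removed by rescaling
    p <- qr.solve(D, c(rts, 0))
    total_obs <- sum(2^log2_matrix[, members, drop = FALSE], na.rm = TRUE)
    shift <- log2(total_obs / sum(2^p))
    profile[members] <- p + shift
  }
  structure(profile, flag = flag)
}

# resolve the sequence used for digestion of a (possibly multi-accession)
# protein group: longest member sequence found in the FASTA
group_sequence <- function(group, sequences) {
  accs <- strsplit(group, ";", fixed = TRUE)[[1]]
  hit <- accs[accs %in% names(sequences)]
  if (length(hit) == 0L) return(NULL)
  seqs <- sequences[hit]
  list(sequence = seqs[[which.max(nchar(seqs))]],
       multi = length(accs) > 1L)
}

#' Protein-level quantification
#'
#' Aggregates a normalized peptide matrix to protein-group level by iBAQ,
#' Hi3/Top3 or MaxLFQ.
#'
#' @param matrix a `peptide_matrix` (log2 values).
#' @param method one of `"ibaq"`, `"hi3"`, `"maxlfq"`.
#' @param sequences named sequence vector from [read_fasta()]; required for
#'   iBAQ.
#' @param min_peptides_pair MaxLFQ minimum peptide ratio count (default 2).
#' @param min_len,max_len,missed_cleavages iBAQ digestion parameters.
#' @return A `protein_quant`: list with `method`, `values` (protein x sample;
#'   linear scale for iBAQ/Hi3, log2 for MaxLFQ), `log2_values`,
#'   `n_peptides`, `flags` and the `design`.
#' @export
quantify_proteins <- function(matrix, method = c("maxlfq", "ibaq", "hi3"),
                              sequences = NULL, min_peptides_pair = 2L,
                              min_len = 7L, max_len = 30L,
                              missed_cleavages = 0L) {
  method <- match.arg(method)
  groups <- split(seq_len(nrow(matrix$values)), matrix$row_meta$protein_group)
  n_samp <- ncol(matrix$values)
  if (method == "ibaq" && is.null(sequences))
    abort("iBAQ requires protein sequences (FASTA)")
  values <- matrix(NA_real_, length(groups), n_samp,
                   dimnames = list(names(groups), colnames(matrix$values)))
  n_peptides <- integer(length(groups))
  flags <- stats::setNames(vector("list", length(groups)), names(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    sub_log2 <- matrix$values[rows, , drop = FALSE]
    n_peptides[g] <- length(rows)
    fl <- character(0)
    if (method == "ibaq") {
      gs <- group_sequence(names(groups)[g], sequences)
      if (is.null(gs)) {
        fl <- c(fl, "no_fasta_sequence")
      } else {
        cnt <- count_observable_peptides(gs$sequence, min_len, max_len,
                                         missed_cleavages)
        if (gs$multi) fl <- c(fl, "multi_accession_longest_member")
        if (cnt == 0L) {
          fl <- c(fl, "no_theoretical_peptides")
        } else {
          values[g, ] <- ibaq(2^sub_log2, cnt)
        }
      }
    } else if (method == "hi3") {
      v <- top3(2^sub_log2)
      values[g, ] <- v
      if (any(attr(v, "n_used") > 0L & attr(v, "n_used") < 3L))
        fl <- c(fl, "fewer_than_3_peptides")
    } else {
      v <- maxlfq(sub_log2, min_peptides_pair = min_peptides_pair)
      values[g, ] <- v
      if (!is.null(attr(v, "flag"))) fl <- c(fl, attr(v, "flag"))
    }
    if (length(fl) > 0L) flags[[g]] <- fl
  }
  log2_values <- if (method == "maxlfq") values else log2(values)
  linear_values <- if (method == "maxlfq") 2^values else values
  structure(list(method = method, values = values,
                 linear_values = linear_values, log2_values = log2_values,
                 n_peptides = stats::setNames(n_peptides, names(groups)),
                 flags = flags[!vapply(flags, is.null, logical(1))],
                 design = matrix$design),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant (%s): %d protein groups x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  if (length(x$flags) > 0L)
    cat(sprintf("  flagged proteins: %d\n", length(x$flags)))
  invisible(x)
}

#' Per-condition iBAQ decile annotation
#'
#' Ranks proteins within each condition by their condition-mean iBAQ and
#' assigns decile bins 1-10 (10 = most abundant) by empirical quantile;
#' ties get average ranks. Per comparison, the two deciles combine into a
#' `"decile_A|decile_B"` 2D code for the table color map.
#'
#' @param ibaq_quant a `protein_quant` with `method == "ibaq"`.
#' @param comparisons data.frame with columns `numerator`, `denominator`
#'   (condition names), or NULL for deciles only.
#' @return An `ibaq_deciles` data.frame: `protein_group`, one `decile_<cond>`
#'   column per condition, and one `code_<num>_vs_<den>` column per
#'   comparison.
#' @export
assign_ibaq_deciles <- function(ibaq_quant, comparisons = NULL) {
  stopifnot(inherits(ibaq_quant, "protein_quant"))
  if (ibaq_quant$method != "ibaq")
    abort("decile annotation requires iBAQ quantification")
  design <- ibaq_quant$design
  conds <- unique(design$condition)
  vals <- ibaq_quant$values
  out <- data.frame(protein_group = rownames(vals), stringsAsFactors = FALSE)
  few <- FALSE
  for (cc in conds) {
    cols <- which(design$condition == cc)
    cm <- rowMeans(vals[, cols, drop = FALSE], na.rm = TRUE)
    cm[!is.finite(cm)] <- NA_real_
    if (all(is.na(cm)))
      abort("condition '%s' has no iBAQ values", cc)
    dec <- rep(NA_integer_, length(cm))
    ok <- !is.na(cm)
    if (sum(ok) < 10L) few <- TRUE
    r <- rank(cm[ok], ties.method = "average")
    dec[ok] <- as.integer(ceiling(10 * r / sum(ok)))
    out[[paste0("decile_", cc)]] <- dec
  }
  if (few) attr(out, "flag") <- "fewer_than_10_proteins_bins_collapse"
  if (!is.null(comparisons)) {
    for (k in seq_len(nrow(comparisons))) {
      a <- comparisons$numerator[k]; b <- comparisons$denominator[k]
      out[[sprintf("code_%s_vs_%s", a, b)]] <-
        paste(out[[paste0("decile_", a)]], out[[paste0("decile_", b)]],
              sep = "|")
    }
  }
  class(out) <- c("ibaq_deciles", "data.frame")
  out
}
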