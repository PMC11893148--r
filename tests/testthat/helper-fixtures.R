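# fixture builders shared across test files

# minimal in-memory precursor table (internal column names)
toy_table <- function(run_id, condition, replicate, protein_group,
                      stripped, modified = paste0("_", stripped, "_"),
                      quantity, pq = 0.001, pgq = 0.001) {
  as_precursor_table(data.frame(
    run_id = run_id, condition = condition, replicate = replicate,
    protein_group = protein_group, stripped_sequence = stripped,
    modified_sequence = modified,
    precursor_id = paste0(modified, ".2"),
    quantity = quantity, precursor_qvalue = pq, pg_qvalue = pgq,
    stringsAsFactors = FALSE))
}

toy_design <- function(conditions = c("A", "A", "B", "B"),
                       batch = NULL, ...) {
  reps <- stats::ave(seq_along(conditions), conditions, FUN = seq_along)
  des <- data.frame(run_id = paste0("run", seq_along(conditions)),
                    condition = conditions, replicate = reps,
                    stringsAsFactors = FALSE)
  if (!is.null(batch)) des$batch <- batch
  extra <- list(...)
  for (nm in names(extra)) des[[nm]] <- extra[[nm]]
  as_study_design(des)
}

# wrap a numeric matrix as a peptide_matrix (log2 values)
toy_matrix <- function(values, protein_group = rep("P1", nrow(values)),
                       design = toy_design(rep(c("A", "B"),
                                               each = ncol(values) / 2))) {
  rn <- rownames(values) %||% paste0("pep", seq_len(nrow(values)))
  rownames(values) <- rn
  colnames(values) <- design$run_id
  structure(list(
    values = values,
    row_meta = data.frame(precursor_id = rn, protein_group = protein_group,
                          stripped_sequence = rn, stringsAsFactors = FALSE),
    design = design, offsets = NULL, flags = list()),
    class = "peptide_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a Spectronaut-style TSV for a toy table; returns the path
write_toy_report <- function(tab, path = tempfile(fileext = ".tsv")) {
  write_precursor_report(tab, path)
  path
}

# brute-force tryptic digestion oracle: enumerate all substrings and accept
# those whose boundaries are valid cleavage points with at most m internal
# missed cleavages (structurally independent of the fragment-based code)
oracle_digest_count <- function(seq, min_len, max_len, mc) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  is_cut <- function(pos) {  # cleavage between pos and pos+1
    pos >= 1 && pos < n && chars[pos] %in% c("K", "R") && chars[pos + 1] != "P"
  }
  peps <- character(0)
  for (s in 1:n) {
    if (!(s == 1 || is_cut(s - 1))) next
    for (e in s:n) {
      if (!(e == n || is_cut(e))) next
      internal <- if (e > s)
        sum(vapply(s:(e - 1), is_cut, logical(1))) else 0
      len <- e - s + 1
      if (internal <= mc && len >= min_len && len <= max_len)
        peps <- c(peps, paste(chars[s:e], collapse = ""))
    }
  }
  length(unique(peps))
}

# dense least-squares oracle for the MaxLFQ profile differences
oracle_maxlfq_diffs <- function(log2_matrix, min_peptides_pair = 2L) {
  n <- ncol(log2_matrix)
  obs <- !is.na(log2_matrix)
  rows <- list(); rhs <- numeric(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      shared <- obs[, i] & obs[, j]
      if (sum(shared) >= min_peptides_pair) {
        v <- numeric(n); v[i] <- 1; v[j] <- -1
        rows[[length(rows) + 1]] <- v
        rhs <- c(rhs, stats::median(log2_matrix[shared, i] -
                                      log2_matrix[shared, j]))
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  D <- do.call(rbind, rows)
  # pin p_1 = 0 and solve the normal equations densely
  A <- crossprod(D); b <- crossprod(D, rhs)
  A[1, ] <- 0; A[1, 1] <- 1; b[1] <- 0
  p <- solve(A, b)
  outer(drop(p), drop(p), `-`)  # matrix of p_i - p_j
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
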