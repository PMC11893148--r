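#' Default Spectronaut-style column mapping
#'
#' Maps the pipeline's internal field names to the column headers of a
#' Spectronaut-dialect precursor report. Override individual entries to
#' ingest reports whose headers drifted across software versions.
#'
#' @param ... named overrides, e.g. `quantity = "FG.MS2Quantity"`.
#' @return Named character vector: internal field -> report column header.
#' @export
#' @examples
#' spectronaut_columns()
#' spectronaut_columns(quantity = "FG.MS2Quantity")
spectronaut_columns <- function(...) {
  map <- c(
    run_id            = "R.FileName",
    condition         = "R.Condition",
    replicate         = "R.Replicate",
    protein_group     = "PG.ProteinGroups",
    stripped_sequence = "PEP.StrippedSequence",
    modified_sequence = "EG.ModifiedSequence",
    precursor_id      = "EG.PrecursorId",
    quantity          = "FG.Quantity",
    precursor_qvalue  = "EG.Qvalue",
    pg_qvalue         = "PG.Qvalue"
  )
  over <- c(...)
  if (length(over) > 0L) {
    bad <- setdiff(names(over), names(map))
    if (length(bad) > 0L)
      abort("unknown column-map field(s): %s", paste(bad, collapse = ", "))
    map[names(over)] <- over
  }
  map
}

# detect delimiter among tab / comma / semicolon from the header line
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ","  = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              ";"  = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))))
  if (all(counts == 0L)) abort("could not detect delimiter in '%s'", path)
  names(counts)[which.max(counts)]
}

#' Read a long-format precursor quantification report
#'
#' Parses a Spectronaut-style TSV/CSV report (one row per precursor x run)
#' into the pipeline's internal precursor table. Quantities that do not parse
#' as numbers, or that are not strictly positive, become missing. Duplicate
#' (precursor_id, run_id) rows are collapsed to the row with the lowest
#' precursor q-value, with a warning.
#'
#' @param path path to a delimited report; delimiter is auto-detected among
#'   tab, comma and semicolon.
#' @param column_map mapping from internal field names to report headers,
#'   see [spectronaut_columns()].
#' @return A `precursor_table`: a data.frame with columns `run_id`,
#'   `condition`, `replicate`, `protein_group`, `stripped_sequence`,
#'   `modified_sequence`, `precursor_id`, `quantity`, `precursor_qvalue`,
#'   `pg_qvalue`.
#' @export
read_precursor_report <- function(path, column_map = spectronaut_columns()) {
  if (!file.exists(path)) abort("report file '%s' does not exist", path)
  sep <- detect_delimiter(path)
  raw <- data.table::fread(path, sep = sep, header = TRUE,
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0L)
    abort("report is missing mapped column(s): %s",
          paste(missing_cols, collapse = ", "))
  tab <- data.frame(
    run_id            = raw[[column_map[["run_id"]]]],
    condition         = raw[[column_map[["condition"]]]],
    replicate         = suppressWarnings(as.integer(raw[[column_map[["replicate"]]]])),
    protein_group     = raw[[column_map[["protein_group"]]]],
    stripped_sequence = raw[[column_map[["stripped_sequence"]]]],
    modified_sequence = raw[[column_map[["modified_sequence"]]]],
    precursor_id      = raw[[column_map[["precursor_id"]]]],
    quantity          = suppressWarnings(as.numeric(raw[[column_map[["quantity"]]]])),
    precursor_qvalue  = suppressWarnings(as.numeric(raw[[column_map[["precursor_qvalue"]]]])),
    pg_qvalue         = suppressWarnings(as.numeric(raw[[column_map[["pg_qvalue"]]]])),
    stringsAsFactors  = FALSE
  )
  if (nrow(tab) == 0L) abort("report '%s' contains no data rows", path)
  as_precursor_table(tab)
}

#' Coerce a data.frame of precursor records to a precursor table
#'
#' Applies the ingestion contract to an in-memory data.frame with the
#' internal column names: non-positive quantities become missing and
#' duplicate (precursor_id, run_id) pairs collapse to the lowest
#' precursor q-value.
#'
#' @param tab data.frame with the internal precursor columns.
#' @return A `precursor_table`.
#' @export
as_precursor_table <- function(tab) {
  assert_columns(tab, c("run_id", "condition", "replicate", "protein_group",
                        "stripped_sequence", "modified_sequence",
                        "precursor_id", "quantity", "precursor_qvalue",
                        "pg_qvalue"), "precursor table")
  tab$quantity[is.nan(tab$quantity)] <- NA_real_
  nonpos <- !is.na(tab$quantity) & tab$quantity <= 0
  if (any(nonpos)) {
    message(sprintf("%d non-positive quantities treated as missing", sum(nonpos)))
    tab$quantity[nonpos] <- NA_real_
  }
  key <- paste(tab$precursor_id, tab$run_id, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warnf("%d duplicate (precursor_id, run_id) row(s) collapsed to lowest precursor q-value", n_dup)
    ord <- order(key, tab$precursor_qvalue, na.last = TRUE)
    tab <- tab[ord, , drop = FALSE]
    tab <- tab[!duplicated(key[ord]), , drop = FALSE]
  }
  rownames(tab) <- NULL
  class(tab) <- c("precursor_table", "data.frame")
  tab
}

#' Write a precursor table back to a Spectronaut-style TSV
#'
#' @param table a `precursor_table`.
#' @param path output file path.
#' @param column_map headers to emit, see [spectronaut_columns()].
#' @return `path`, invisibly.
#' @export
write_precursor_report <- function(table, path,
                                   column_map = spectronaut_columns()) {
  out <- data.frame(table, stringsAsFactors = FALSE)
  internal <- names(column_map)
  out <- out[internal]
  # %.17g guarantees exact double round-trips through text
  for (col in c("quantity", "precursor_qvalue", "pg_qvalue"))
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         sprintf("%.17g", out[[col]]))
  names(out) <- unname(column_map[internal])
  data.table::fwrite(out, path, sep = "\t", na = "NaN", quote = FALSE)
  invisible(path)
}

#' Read a protein FASTA into a named sequence vector
#'
#' The accession is the first whitespace-delimited token of the header;
#' UniProt `db|ACC|name` headers are reduced to `ACC`.
#'
#' @param path FASTA file path.
#' @return Named character vector: accession -> uppercase amino-acid sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) abort("FASTA '%s' contains no sequences", path)
  acc <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[[`, character(1), 1L)
  uni <- grepl("^[^|]+\\|[^|]+\\|", acc)
  acc[uni] <- vapply(strsplit(acc[uni], "|", fixed = TRUE), `[[`, character(1), 2L)
  out <- toupper(gsub("[[:space:]]", "", as.character(seqs)))
  if (anyDuplicated(acc))
    abort("duplicate FASTA accession(s): %s",
          paste(unique(acc[duplicated(acc)]), collapse = ", "))
  if (any(nchar(out) == 0L))
    abort("empty sequence for accession(s): %s",
          paste(acc[nchar(out) == 0L], collapse = ", "))
  names(out) <- acc
  out
}

#' Write a named sequence vector to FASTA
#'
#' @param sequences named character vector (accession -> sequence).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a study-design table
#'
#' @param path TSV with columns `run_id`, `condition`, `replicate` and
#'   optionally `batch` plus further covariate columns.
#' @return A data.frame of class `study_design`; covariate column names are
#'   stored in `attr(, "covariates")`.
#' @export
read_study_design <- function(path) {
  des <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  as_study_design(des)
}

#' Validate an in-memory study design
#'
#' @param des data.frame with `run_id`, `condition`, `replicate`, optional
#'   `batch` and covariate columns.
#' @return The validated `study_design`.
#' @export
as_study_design <- function(des) {
  assert_columns(des, c("run_id", "condition", "replicate"), "study design")
  if (anyDuplicated(des$run_id))
    abort("duplicate run_id in study design: %s",
          paste(unique(des$run_id[duplicated(des$run_id)]), collapse = ", "))
  des$condition <- as.character(des$condition)
  des$run_id <- as.character(des$run_id)
  des$replicate <- as.integer(des$replicate)
  if (any(is.na(des$replicate) | des$replicate < 1L))
    abort("study design replicates must be integers >= 1")
  attr(des, "covariates") <-
    setdiff(names(des), c("run_id", "condition", "replicate", "batch"))
  class(des) <- c("study_design", "data.frame")
  des
}

#' Identification-rate summary
#'
#' Counts distinct precursors, stripped peptides and protein groups per run,
#' over rows with non-missing quantity, plus a union row across all runs.
#'
#' @param table a `precursor_table`.
#' @return data.frame with columns `run_id`, `n_precursors`, `n_peptides`,
#'   `n_protein_groups`; the final row (`run_id == "total"`) holds union
#'   counts.
#' @export
id_rate_summary <- function(table) {
  if (nrow(table) == 0L) abort("empty precursor table")
  obs <- table[!is.na(table$quantity), , drop = FALSE]
  runs <- unique(table$run_id)
  per_run <- lapply(runs, function(r) {
    sub <- obs[obs$run_id == r, , drop = FALSE]
    data.frame(run_id = r,
               n_precursors = length(unique(sub$precursor_id)),
               n_peptides = length(unique(sub$stripped_sequence)),
               n_protein_groups = length(unique(sub$protein_group)),
               stringsAsFactors = FALSE)
  })
  total <- data.frame(run_id = "total",
                      n_precursors = length(unique(obs$precursor_id)),
                      n_peptides = length(unique(obs$stripped_sequence)),
                      n_protein_groups = length(unique(obs$protein_group)),
                      stringsAsFactors = FALSE)
  rbind(do.call(rbind, per_run), total)
}
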