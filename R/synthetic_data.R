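#' Configuration of a synthetic DIA study
#'
#' The generator emulates a two-or-more condition label-free DIA experiment:
#' protein base abundances are log-normal, peptides carry fixed ionization
#' offsets, replicates add Gaussian log2 noise, a fixed fraction of proteins
#' is regulated with a known log2 fold change, missingness is an
#' intensity-dependent logistic dropout, and a fraction of peptides gains an
#' oxidized-methionine precursor variant. A FASTA in which tryptic digestion
#' recovers exactly the generated peptides is emitted alongside.
#'
#' @param n_proteins number of proteins (default 200).
#' @param peptides_per_protein integer range, peptides drawn uniformly
#'   (default 3:8).
#' @param n_conditions number of conditions (default 2, named "A", "B", ...).
#' @param replicates_per_condition replicates per condition (default 3).
#' @param base_log2_mean,base_log2_sd protein base log2 intensity
#'   distribution (defaults 14, 2).
#' @param peptide_offset_sd per-peptide log2 ionization offset SD (default 1).
#' @param replicate_noise_sd per-measurement log2 noise SD (default 0.25).
#' @param fraction_regulated fraction of proteins regulated (default 0.2);
#'   the regulated count is `floor(n_proteins * fraction_regulated)`.
#' @param true_log2_fc log2 fold-change magnitude applied to every
#'   non-reference condition of a regulated protein (default 1).
#' @param fc_direction `"balanced"` (default): regulated proteins alternate
#'   deterministically between up- and down-regulation, so global median
#'   normalization stays unbiased (its core assumption: no net proteome
#'   shift); `"up"`: all regulated proteins shift upward.
#' @param batch_shifts named numeric vector of per-batch log2 shifts, or
#'   NULL for a single batch (default NULL). Batches are interleaved across
#'   conditions so they never confound the condition contrast.
#' @param dropout_midpoint,dropout_steepness logistic dropout in true log2
#'   intensity: `P(missing) = plogis(steepness * (midpoint - value))`
#'   (defaults 8, 1; set midpoint to `-Inf` to disable).
#' @param oxidation_fraction fraction of peptides that also emit an oxidized
#'   precursor variant (default 0.05).
#' @param qvalue_above_fraction fraction of rows assigned a precursor
#'   q-value above 0.01 (default 0.02).
#' @param seed RNG seed; generation is a pure function of the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 200L,
                              peptides_per_protein = 3:8,
                              n_conditions = 2L,
                              replicates_per_condition = 3L,
                              base_log2_mean = 14, base_log2_sd = 2,
                              peptide_offset_sd = 1,
                              replicate_noise_sd = 0.25,
                              fraction_regulated = 0.2,
                              true_log2_fc = 1,
                              fc_direction = c("balanced", "up"),
                              batch_shifts = NULL,
                              dropout_midpoint = 8, dropout_steepness = 1,
                              oxidation_fraction = 0.05,
                              qvalue_above_fraction = 0.02,
                              seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              n_conditions = as.integer(n_conditions),
              replicates_per_condition = as.integer(replicates_per_condition),
              base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
              peptide_offset_sd = peptide_offset_sd,
              replicate_noise_sd = replicate_noise_sd,
              fraction_regulated = fraction_regulated,
              true_log2_fc = true_log2_fc,
              fc_direction = match.arg(fc_direction),
              batch_shifts = batch_shifts,
              dropout_midpoint = dropout_midpoint,
              dropout_steepness = dropout_steepness,
              oxidation_fraction = oxidation_fraction,
              qvalue_above_fraction = qvalue_above_fraction,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1L || cfg$replicates_per_condition < 1L ||
      cfg$n_conditions < 1L)
    abort("infeasible config: need >= 1 protein, condition and replicate")
  stopifnot(cfg$base_log2_sd >= 0, cfg$peptide_offset_sd >= 0,
            cfg$replicate_noise_sd >= 0,
            cfg$fraction_regulated >= 0, cfg$fraction_regulated <= 1,
            cfg$oxidation_fraction >= 0, cfg$oxidation_fraction <= 1,
            cfg$qvalue_above_fraction >= 0, cfg$qvalue_above_fraction <= 1)
  class(cfg) <- "simulation_config"
  cfg
}

# random tryptic peptide: no internal K/R/P, ends in K or R
random_tryptic_peptide <- function(len) {
  body_alphabet <- c("A","C","D","E","F","G","H","I","L","M","N","Q","S",
                     "T","V","W","Y")
  paste0(paste(sample(body_alphabet, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Generate a synthetic DIA study with known ground truth
#'
#' @param config a [simulation_config()].
#' @return list with `table` (a `precursor_table`), `design`
#'   (`study_design`), `comparisons` (every non-reference condition vs the
#'   reference condition "A"), `truth` (data.frame: `protein_group`,
#'   `regulated`, `true_log2_fc`; per-run batch shifts and the config as
#'   attributes), and `fasta` (named sequence vector).
#' @export
generate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    np <- config$n_proteins
    conds <- LETTERS[seq_len(config$n_conditions)]
    nrep <- config$replicates_per_condition
    design <- data.frame(
      run_id = paste0("run_", rep(conds, each = nrep), "_",
                      rep(seq_len(nrep), length(conds)), ".raw"),
      condition = rep(conds, each = nrep),
      replicate = rep(seq_len(nrep), length(conds)),
      stringsAsFactors = FALSE
    )
    batch_shift_per_run <- rep(0, nrow(design))
    if (!is.null(config$batch_shifts)) {
      batches <- names(config$batch_shifts)
      # interleave batches over replicates so each batch spans all conditions
      design$batch <- batches[(design$replicate - 1L) %% length(batches) + 1L]
      batch_shift_per_run <- unname(config$batch_shifts[design$batch])
    }
    design <- as_study_design(design)

    prot_ids <- sprintf("P%04d", seq_len(np))
    n_reg <- floor(np * config$fraction_regulated)
    regulated <- rep(FALSE, np)
    if (n_reg > 0L) regulated[sample.int(np, n_reg)] <- TRUE
    fc_signed <- rep(0, np)
    if (n_reg > 0L) {
      signs <- if (config$fc_direction == "balanced")
        rep_len(c(1, -1), n_reg) else rep(1, n_reg)
      fc_signed[regulated] <- signs * config$true_log2_fc
    }
    base <- stats::rnorm(np, config$base_log2_mean, config$base_log2_sd)

    n_pep <- sample(config$peptides_per_protein, np, replace = TRUE)
    total_pep <- sum(n_pep)
    pep_lens <- sample(7:20, total_pep, replace = TRUE)
    pep_seqs <- vapply(pep_lens, random_tryptic_peptide, character(1))
    # oxidized variants need an M; force one in when absent
    n_ox <- round(config$oxidation_fraction * total_pep)
    ox_idx <- if (n_ox > 0L) sample.int(total_pep, n_ox) else integer(0)
    for (i in ox_idx) {
      if (!grepl("M", pep_seqs[i], fixed = TRUE))
        pep_seqs[i] <- paste0(substr(pep_seqs[i], 1L, 1L), "M",
                              substr(pep_seqs[i], 3L, nchar(pep_seqs[i])))
    }
    # regenerate any duplicate peptide until all are unique (keeps the
    # peptide -> protein map unambiguous)
    while (anyDuplicated(pep_seqs)) {
      dup <- which(duplicated(pep_seqs))
      pep_seqs[dup] <- vapply(sample(8:20, length(dup), replace = TRUE),
                              random_tryptic_peptide, character(1))
    }
    pep_protein <- rep(seq_len(np), n_pep)
    fasta <- vapply(split(pep_seqs, pep_protein), paste, character(1),
                    collapse = "")
    names(fasta) <- prot_ids
    pep_offset <- stats::rnorm(total_pep, 0, config$peptide_offset_sd)

    cond_effect <- outer(fc_signed,
                         as.numeric(conds != conds[1L]))  # protein x condition
    n_runs <- nrow(design)
    cond_idx <- match(design$condition, conds)

    make_rows <- function(pep_i, modified, shift) {
      prot <- pep_protein[pep_i]
      true_val <- base[prot] + pep_offset[pep_i] + shift +
        cond_effect[prot, cond_idx] + batch_shift_per_run +
        stats::rnorm(n_runs, 0, config$replicate_noise_sd)
      p_drop <- stats::plogis(config$dropout_steepness *
                                (config$dropout_midpoint - true_val))
      missing <- stats::runif(n_runs) < p_drop
      qv <- ifelse(stats::runif(n_runs) < config$qvalue_above_fraction,
                   stats::runif(n_runs, 0.02, 0.5),
                   stats::runif(n_runs, 1e-5, 0.009))
      data.frame(
        run_id = design$run_id,
        condition = design$condition,
        replicate = design$replicate,
        protein_group = prot_ids[prot],
        stripped_sequence = pep_seqs[pep_i],
        modified_sequence = modified,
        precursor_id = paste0(modified, ".2"),
        quantity = ifelse(missing, NA_real_, 2^true_val),
        precursor_qvalue = round(qv, 6),
        pg_qvalue = round(qv / 2, 6),
        stringsAsFactors = FALSE
      )
    }

    blocks <- vector("list", total_pep + length(ox_idx))
    for (i in seq_len(total_pep)) {
      blocks[[i]] <- make_rows(i, paste0("_", pep_seqs[i], "_"), 0)
    }
    for (k in seq_along(ox_idx)) {
      i <- ox_idx[k]
      mpos <- regexpr("M", pep_seqs[i], fixed = TRUE)
      modified <- paste0("_", substr(pep_seqs[i], 1L, mpos),
                         "[Oxidation (M)]",
                         substr(pep_seqs[i], mpos + 1L, nchar(pep_seqs[i])),
                         "_")
      blocks[[total_pep + k]] <- make_rows(i, modified, -2)  # oxidized: lower
    }
    table <- do.call(rbind, blocks)
    table <- as_precursor_table(table)

    truth <- data.frame(protein_group = prot_ids, regulated = regulated,
                        true_log2_fc = fc_signed,
                        stringsAsFactors = FALSE)
    attr(truth, "batch_shift_per_run") <-
      stats::setNames(batch_shift_per_run, design$run_id)
    attr(truth, "config") <- config
    comparisons <- if (length(conds) > 1L)
      data.frame(numerator = conds[-1L], denominator = conds[1L],
                 stringsAsFactors = FALSE)
    else NULL
    list(table = table, design = design, comparisons = comparisons,
         truth = truth, fasta = fasta)
  })
}

#' Write a synthetic study to disk
#'
#' Emits `report.tsv` (Spectronaut-style headers), `design.tsv`,
#' `proteome.fasta` and `truth.json` under `dir`.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_precursor_report(study$table, file.path(dir, "report.tsv"))
  data.table::fwrite(as.data.frame(study$design), file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE)
  write_fasta(study$fasta, file.path(dir, "proteome.fasta"))
  truth <- list(truth = study$truth,
                batch_shift_per_run = as.list(attr(study$truth, "batch_shift_per_run")),
                comparisons = study$comparisons)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Evaluate protein statistics against simulation ground truth
#'
#' @param protein_stats one comparison's data.frame from
#'   [differential_stats()].
#' @param truth truth data.frame from [generate_study()].
#' @param alpha significance threshold (default 0.05).
#' @return list with `type1_error` (fraction of non-regulated proteins at
#'   `protein_p < alpha`), `power` (fraction of regulated proteins at
#'   `adj_p < alpha`; NA if none regulated), `fc_bias` and `fc_rmse` of the
#'   median log2 ratio over regulated proteins, and the counts involved.
#' @export
truth_evaluation <- function(protein_stats, truth, alpha = 0.05) {
  m <- match(protein_stats$protein_group, truth$protein_group)
  if (anyNA(m))
    abort("protein(s) missing from truth: %s",
          paste(protein_stats$protein_group[is.na(m)][1:5], collapse = ", "))
  reg <- truth$regulated[m]
  fc <- truth$true_log2_fc[m]
  type1 <- if (any(!reg)) mean(protein_stats$protein_p[!reg] < alpha) else NA_real_
  power <- if (any(reg)) mean(protein_stats$adj_p[reg] < alpha) else NA_real_
  err <- protein_stats$median_log2_ratio[reg] - fc[reg]
  aligned <- protein_stats$median_log2_ratio[reg] * sign(fc[reg])
  list(type1_error = type1, power = power,
       fc_bias = if (any(reg)) mean(err) else NA_real_,
       fc_rmse = if (any(reg)) sqrt(mean(err^2)) else NA_real_,
       mean_aligned_ratio = if (any(reg)) mean(aligned) else NA_real_,
       n_regulated = sum(reg), n_null = sum(!reg), alpha = alpha)
}
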