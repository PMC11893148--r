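#' Default pipeline configuration
#'
#' @param ... overrides of the default parameters (unknown names error).
#' @return A named list: `max_precursor_q`, `max_pg_q` (0.01), `remove_oxidized`
#'   (TRUE), `oxidation_tags`, `min_fraction` (0.5), `normalize` (TRUE),
#'   `quant_methods` (ibaq, hi3, maxlfq), `min_peptides_pair` (2),
#'   `digest_min_len` (7), `digest_max_len` (30), `digest_missed_cleavages`
#'   (0), `peptide_statistic` ("moderated_t"), `alpha` (0.05),
#'   `min_on_fraction` (1.0), `max_off_fraction` (0.0),
#'   `log2_saturation` (2), `include_figures` (TRUE).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_precursor_q = 0.01, max_pg_q = 0.01,
    remove_oxidized = TRUE,
    oxidation_tags = c("Oxidation (M)", "M[Oxidation]", "M(ox)"),
    min_fraction = 0.5,
    normalize = TRUE,
    adjust_batch = TRUE,
    quant_methods = c("ibaq", "hi3", "maxlfq"),
    min_peptides_pair = 2L,
    digest_min_len = 7L, digest_max_len = 30L, digest_missed_cleavages = 0L,
    peptide_statistic = "moderated_t",
    alpha = 0.05,
    min_on_fraction = 1.0, max_off_fraction = 0.0,
    log2_saturation = 2,
    include_figures = TRUE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L)
    abort("unknown config parameter(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] parameters.
#' @return Resolved configuration list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Two-axis decile color map
#'
#' Bilinear RGB interpolation over the 10 x 10 grid of (decile_A, decile_B)
#' pairs: axis A runs corner `#2166AC` (low) to `#B2182B` (high), axis B
#' tilts the blend toward its own extremes, so each decile pair has a unique
#' fill color.
#'
#' @return data.frame with `decile_a`, `decile_b`, `hexcolor` (100 rows).
#' @export
decile_color_map <- function() {
  corner <- function(hex) grDevices::col2rgb(hex)[, 1L] / 255
  c00 <- corner("#F7F7F7"); c10 <- corner("#B2182B")
  c01 <- corner("#2166AC"); c11 <- corner("#762A83")
  grid <- expand.grid(decile_a = 1:10, decile_b = 1:10)
  hex <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    u <- (grid$decile_a[i] - 1) / 9
    v <- (grid$decile_b[i] - 1) / 9
    rgbv <- (1 - u) * (1 - v) * c00 + u * (1 - v) * c10 +
      (1 - u) * v * c01 + u * v * c11
    hex[i] <- grDevices::rgb(rgbv[1L], rgbv[2L], rgbv[3L])
  }
  grid$hexcolor <- hex
  grid
}

# signed three-point gradient for log2 ratios, saturating at +/- bound
log2_ratio_color <- function(x, bound = 2) {
  t <- pmax(-1, pmin(1, x / bound))
  out <- character(length(x))
  lo <- grDevices::col2rgb("#2166AC")[, 1L] / 255
  mid <- grDevices::col2rgb("#F7F7F7")[, 1L] / 255
  hi <- grDevices::col2rgb("#B2182B")[, 1L] / 255
  for (i in seq_along(x)) {
    if (is.na(t[i])) { out[i] <- NA_character_; next }
    w <- abs(t[i])
    tgt <- if (t[i] >= 0) hi else lo
    rgbv <- (1 - w) * mid + w * tgt
    out[i] <- grDevices::rgb(rgbv[1L], rgbv[2L], rgbv[3L])
  }
  out
}

#' Write annotated protein-statistics tables
#'
#' One spreadsheet-compatible CSV and one TSV twin per comparison, with the
#' iBAQ-decile 2D code and per-cell fill colors (log2-ratio gradient and the
#' 2D decile map) as explicit columns, plus the machine-readable 100-row
#' decile color legend.
#'
#' @param stats a `protein_stats` object.
#' @param out output directory (created if absent).
#' @param log2_saturation saturation bound of the ratio gradient (default 2).
#' @return Character vector of written file paths, invisibly.
#' @export
write_stat_tables <- function(stats, out, log2_saturation = 2) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  legend <- decile_color_map()
  paths <- character(0)
  legend_path <- file.path(out, "decile_color_legend.tsv")
  data.table::fwrite(legend, legend_path, sep = "\t", quote = FALSE)
  paths <- c(paths, legend_path)
  for (nm in names(stats)) {
    df <- stats[[nm]]
    cols <- intersect(c("protein_group", "n_peptides_tested",
                        "median_log2_ratio", "median_p", "protein_p",
                        "adj_p", "effect_size", "decile_num", "decile_den",
                        "code_2d"), names(df))
    df <- df[cols]
    df$log2_ratio_color <- log2_ratio_color(df$median_log2_ratio,
                                            log2_saturation)
    if (all(c("decile_num", "decile_den") %in% names(df))) {
      m <- match(paste(df$decile_num, df$decile_den),
                 paste(legend$decile_a, legend$decile_b))
      df$decile_2d_color <- legend$hexcolor[m]
    }
    tsv <- file.path(out, sprintf("protein_stats_%s.tsv", nm))
    csv <- file.path(out, sprintf("protein_stats_%s.csv", nm))
    data.table::fwrite(df, tsv, sep = "\t", quote = FALSE, na = "NA")
    data.table::fwrite(df, csv, sep = ",", quote = TRUE, na = "NA")
    paths <- c(paths, tsv, csv)
  }
  invisible(paths)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 50L) {
  if (is.null(df) || nrow(df) == 0L) return("<p><em>empty table</em></p>")
  shown <- utils::head(df, max_rows)
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", formatC(v, digits = 4, format = "g"))
    else html_escape(ifelse(is.na(v), "", as.character(v)))
  }
  cells <- vapply(shown, fmt, character(nrow(shown)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(shown))
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(shown)),
                                    "</th>", collapse = ""), "</tr>")
  body <- apply(cells, 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  note <- if (nrow(df) > max_rows)
    sprintf("<p><em>showing %d of %d rows</em></p>", max_rows, nrow(df)) else ""
  paste0("<table>", head_row, paste(body, collapse = "\n"), "</table>", note)
}

# base64-embedded PNG figure; returns "" if no usable graphics device
figure_png <- function(draw, width = 720, height = 480) {
  tmp <- tempfile(fileext = ".png")
  ok <- tryCatch({
    grDevices::png(tmp, width = width, height = height, type = "cairo")
    draw()
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    FALSE
  })
  if (!ok || !file.exists(tmp)) return("")
  raw <- readBin(tmp, "raw", file.info(tmp)$size)
  unlink(tmp)
  sprintf('<img src="data:image/png;base64,%s" alt="figure"/>',
          jsonlite::base64_enc(raw))
}

#' Render a self-contained HTML report
#'
#' Builds one static HTML file (all styling and figures inlined; no network
#' access needed to display) covering run parameters, ID rates, filtering,
#' normalization offsets, PCA, CV, ON/OFF calls and per-comparison protein
#' statistics. Missing sections are rendered with a "not computed" notice.
#'
#' @param bundle a `report_bundle` from [run_pipeline()] or a list with any
#'   of the elements `config`, `id_rates`, `filter_log`, `offsets`, `pca`,
#'   `cv`, `on_off`, `stats`, `versions`.
#' @param file output HTML path.
#' @return `file`, invisibly.
#' @export
render_html_report <- function(bundle, file) {
  cfg <- bundle$config %||% pipeline_config()
  include_figures <- isTRUE(cfg$include_figures)
  section <- function(title, body) {
    if (is.null(body) || identical(body, ""))
      body <- "<p><em>not computed</em></p>"
    sprintf("<section><h2>%s</h2>\n%s\n</section>", html_escape(title), body)
  }
  parts <- character(0)
  cfg_df <- data.frame(parameter = names(cfg),
                       value = vapply(cfg, function(v)
                         paste(format(v), collapse = ", "), character(1)))
  parts <- c(parts, section("Run parameters", html_table(cfg_df, 100L)))
  parts <- c(parts, section("Identification rates",
                            if (!is.null(bundle$id_rates)) html_table(bundle$id_rates, 100L)))
  parts <- c(parts, section("Filtering log",
                            if (!is.null(bundle$filter_log)) html_table(bundle$filter_log, 100L)))
  parts <- c(parts, section("Normalization offsets (log2)",
                            if (!is.null(bundle$offsets))
                              html_table(data.frame(run_id = names(bundle$offsets),
                                                    offset = as.numeric(bundle$offsets)), 100L)))
  pca_body <- NULL
  if (!is.null(bundle$pca)) {
    p <- bundle$pca
    ev <- data.frame(component = seq_along(p$explained_variance_fraction),
                     explained_fraction = p$explained_variance_fraction)
    fig <- ""
    if (include_figures && ncol(p$scores) >= 2L) {
      fig <- figure_png(function() {
        graphics::plot(p$scores[, 1L], p$scores[, 2L],
                       xlab = sprintf("PC1 (%.1f%%)", 100 * p$explained_variance_fraction[1L]),
                       ylab = sprintf("PC2 (%.1f%%)", 100 * p$explained_variance_fraction[2L]),
                       pch = 19, main = "PCA of protein profiles")
        graphics::text(p$scores[, 1L], p$scores[, 2L],
                       labels = rownames(p$scores), pos = 3, cex = 0.7)
      })
    }
    pca_body <- paste0(fig, html_table(ev, 20L))
  }
  parts <- c(parts, section("Multivariate analysis (PCA)", pca_body))
  cv_body <- NULL
  if (!is.null(bundle$cv)) {
    cv_body <- html_table(data.frame(condition = names(bundle$cv$median_cv),
                                     median_cv = as.numeric(bundle$cv$median_cv)))
  }
  parts <- c(parts, section("Coefficient of variation", cv_body))
  onoff_body <- NULL
  if (!is.null(bundle$on_off)) {
    call_cols <- grep("^call_", names(bundle$on_off), value = TRUE)
    hits <- bundle$on_off[rowSums(bundle$on_off[call_cols] != "none") > 0, ,
                          drop = FALSE]
    onoff_body <- paste0(
      sprintf("<p>%d of %d proteins with an ON/OFF call</p>", nrow(hits),
              nrow(bundle$on_off)),
      html_table(hits))
  }
  parts <- c(parts, section("ON/OFF analysis", onoff_body))
  stats_body <- NULL
  if (!is.null(bundle$stats)) {
    alpha <- attr(bundle$stats, "alpha") %||% 0.05
    pieces <- lapply(names(bundle$stats), function(nm) {
      df <- bundle$stats[[nm]]
      n_sig <- sum(df$adj_p < alpha, na.rm = TRUE)
      top <- df[order(df$adj_p), , drop = FALSE]
      paste0(sprintf("<h3>%s</h3><p>%d of %d proteins at adj_p &lt; %g</p>",
                     html_escape(nm), n_sig, nrow(df), alpha),
             html_table(top, 25L))
    })
    stats_body <- paste(unlist(pieces), collapse = "\n")
  }
  parts <- c(parts, section("Differential statistics", stats_body))
  versions <- bundle$versions %||%
    c(diaquant = as.character(utils::packageVersion("diaquant")),
      R = paste(R.version$major, R.version$minor, sep = "."))
  parts <- c(parts, section("Software versions",
                            html_table(data.frame(component = names(versions),
                                                  version = unname(versions)))))
  css <- paste(
    "body{font-family:sans-serif;margin:2em;max-width:70em}",
    "table{border-collapse:collapse;margin:0.5em 0}",
    "th,td{border:1px solid #999;padding:2px 8px;font-size:0.85em}",
    "th{background:#eee}section{margin-bottom:2em}")
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    "<title>DIA quantification report</title><style>", css, "</style></head>",
    "<body><h1>DIA quantification report</h1>\n",
    paste(parts, collapse = "\n"), "</body></html>")
  writeLines(html, file, useBytes = TRUE)
  invisible(file)
}

#' Run the full pipeline end to end
#'
#' Executes ingest, preprocessing, protein quantification, differential
#' statistics, QC and reporting sequentially, writing every intermediate
#' under a fixed folder layout (`01_ingest/` ... `06_report/`).
#'
#' @param report path to the precursor report.
#' @param design path to the design TSV, or a `study_design`.
#' @param fasta path to the protein FASTA (required when iBAQ is among the
#'   quantification methods), or a named sequence vector.
#' @param comparisons data.frame with `numerator`/`denominator`, or NULL to
#'   compare every condition against the first design condition.
#' @param config a [pipeline_config()] list or path to a YAML file.
#' @param out output directory root.
#' @param column_map report column mapping, see [spectronaut_columns()].
#' @return A `report_bundle`: list with all stage results (`table`,
#'   `design`, `id_rates`, `matrix`, `offsets`, `quant` (per method),
#'   `deciles`, `stats`, `pca`, `correlation`, `cv`, `on_off`, `config`,
#'   `paths`).
#' @export
run_pipeline <- function(report, design, fasta = NULL, comparisons = NULL,
                         config = pipeline_config(), out,
                         column_map = spectronaut_columns()) {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- read_pipeline_config(config)
  dirs <- file.path(out, c("01_ingest", "02_preprocess", "03_quant",
                           "04_stats", "05_qc", "06_report"))
  names(dirs) <- c("ingest", "preprocess", "quant", "stats", "qc", "report")
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s (partial outputs under %s)",
            name, conditionMessage(e), out)
    })
  }

  # 01 ingest
  bundle <- stage("01_ingest", {
    tab <- read_precursor_report(report, column_map)
    des <- if (inherits(design, "study_design")) design
           else read_study_design(design)
    idr <- id_rate_summary(tab)
    data.table::fwrite(idr, file.path(dirs["ingest"], "id_rate_summary.tsv"),
                       sep = "\t", quote = FALSE)
    list(table = tab, design = des, id_rates = idr)
  })
  if (is.null(comparisons)) {
    conds <- unique(bundle$design$condition)
    if (length(conds) < 2L) abort("need >= 2 conditions for comparisons")
    comparisons <- data.frame(numerator = conds[-1L], denominator = conds[1L],
                              stringsAsFactors = FALSE)
  }

  # 02 preprocess
  bundle <- stage("02_preprocess", {
    tab <- filter_qvalues(bundle$table, config$max_precursor_q, config$max_pg_q)
    filter_log <- data.frame(step = "qvalue_censoring",
                             n = attr(tab, "n_censored"))
    if (isTRUE(config$remove_oxidized)) {
      tab <- remove_oxidized_met(tab, config$oxidation_tags)
      filter_log <- rbind(filter_log,
                          data.frame(step = "oxidized_met_precursors_dropped",
                                     n = attr(tab, "n_dropped_precursors")))
    }
    mat <- build_peptide_matrix(tab, bundle$design)
    mat <- condition_wise_filter(mat, config$min_fraction)
    filter_log <- rbind(filter_log,
                        data.frame(step = "condition_wise_filter_dropped",
                                   n = attr(mat, "n_dropped")))
    offsets <- NULL
    if (isTRUE(config$normalize)) {
      mat <- log2_median_normalize(mat)
      offsets <- mat$offsets
      data.table::fwrite(data.frame(run_id = names(offsets),
                                    offset_log2 = as.numeric(offsets)),
                         file.path(dirs["preprocess"], "normalization_offsets.tsv"),
                         sep = "\t", quote = FALSE)
    }
    if (isTRUE(config$adjust_batch) &&
        ("batch" %in% names(bundle$design) ||
         length(attr(bundle$design, "covariates") %||% character(0)) > 0L)) {
      mat <- adjust_batch_covariates(mat)
      filter_log <- rbind(filter_log,
                          data.frame(step = "batch_adjust_skipped_rows",
                                     n = length(attr(mat, "unadjusted_rows"))))
    }
    data.table::fwrite(filter_log,
                       file.path(dirs["preprocess"], "filter_log.tsv"),
                       sep = "\t", quote = FALSE)
    vals <- data.frame(precursor_id = rownames(mat$values), mat$values,
                       check.names = FALSE)
    data.table::fwrite(vals, file.path(dirs["preprocess"], "peptide_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    c(bundle, list(filtered_table = tab, matrix = mat, offsets = offsets,
                   filter_log = filter_log))
  })

  # 03 quantification
  bundle <- stage("03_quant", {
    seqs <- NULL
    if ("ibaq" %in% config$quant_methods) {
      if (is.null(fasta)) abort("iBAQ requested but no FASTA given")
      seqs <- if (is.character(fasta) && length(fasta) == 1L) read_fasta(fasta)
              else fasta
    }
    quant <- list()
    for (mth in config$quant_methods) {
      quant[[mth]] <- quantify_proteins(
        bundle$matrix, method = mth, sequences = seqs,
        min_peptides_pair = config$min_peptides_pair,
        min_len = config$digest_min_len, max_len = config$digest_max_len,
        missed_cleavages = config$digest_missed_cleavages)
      qv <- data.frame(protein_group = rownames(quant[[mth]]$values),
                       quant[[mth]]$values,
                       n_peptides = quant[[mth]]$n_peptides,
                       check.names = FALSE)
      data.table::fwrite(qv, file.path(dirs["quant"],
                                       sprintf("protein_quant_%s.tsv", mth)),
                         sep = "\t", quote = FALSE)
    }
    deciles <- NULL
    if (!is.null(quant$ibaq)) {
      deciles <- assign_ibaq_deciles(quant$ibaq, comparisons)
      data.table::fwrite(as.data.frame(deciles),
                         file.path(dirs["quant"], "ibaq_deciles.tsv"),
                         sep = "\t", quote = FALSE)
    }
    c(bundle, list(quant = quant, deciles = deciles))
  })

  # 04 statistics
  bundle <- stage("04_stats", {
    effect_quant <- bundle$quant$maxlfq %||% bundle$quant[[1L]]
    stats_res <- differential_stats(
      bundle$matrix, comparisons,
      peptide_statistic = config$peptide_statistic,
      protein_quant = effect_quant, deciles = bundle$deciles,
      alpha = config$alpha)
    write_stat_tables(stats_res, dirs[["stats"]],
                      log2_saturation = config$log2_saturation)
    c(bundle, list(stats = stats_res))
  })

  # 05 qc
  bundle <- stage("05_qc", {
    qc_mat <- (bundle$quant$maxlfq %||% bundle$quant[[1L]])$log2_values
    pca_res <- tryCatch(pca(qc_mat), error = function(e) NULL)
    if (!is.null(pca_res)) {
      data.table::fwrite(data.frame(run_id = rownames(pca_res$scores),
                                    pca_res$scores, check.names = FALSE),
                         file.path(dirs["qc"], "pca_scores.tsv"),
                         sep = "\t", quote = FALSE)
      data.table::fwrite(data.frame(component = seq_along(pca_res$explained_variance_fraction),
                                    explained_fraction = pca_res$explained_variance_fraction),
                         file.path(dirs["qc"], "explained_variance.tsv"),
                         sep = "\t", quote = FALSE)
    }
    corr <- sample_correlation(bundle$matrix$values)
    data.table::fwrite(data.frame(run_id = rownames(corr$correlation),
                                  corr$correlation, check.names = FALSE),
                       file.path(dirs["qc"], "sample_correlation.tsv"),
                       sep = "\t", quote = FALSE)
    cv <- cv_summary(2^bundle$matrix$values, bundle$design)
    data.table::fwrite(cv$per_feature, file.path(dirs["qc"], "cv_summary.tsv"),
                       sep = "\t", quote = FALSE)
    onoff <- on_off_analysis(bundle$filtered_table, bundle$design, comparisons,
                             config$min_on_fraction, config$max_off_fraction)
    data.table::fwrite(onoff, file.path(dirs["qc"], "on_off_calls.tsv"),
                       sep = "\t", quote = FALSE)
    c(bundle, list(pca = pca_res, correlation = corr, cv = cv, on_off = onoff))
  })

  # 06 report
  bundle <- stage("06_report", {
    bundle$config <- config
    yaml::write_yaml(config[!vapply(config, is.function, logical(1))],
                     file.path(dirs["report"], "run_parameters.yaml"))
    render_html_report(bundle, file.path(dirs["report"], "report.html"))
    bundle
  })
  bundle$paths <- dirs
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  cat(sprintf("  %d precursor rows, %d samples\n", nrow(x$table),
              nrow(x$design)))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}
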