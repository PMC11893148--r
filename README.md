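# diaquant

Downstream analysis of label-free DIA mass-spectrometry experiments, starting
from the long-format precursor report that search engines such as
Spectronaut® export (one row per precursor × run). The package is aimed at
proteomics core facilities and analysts who need a reproducible, scriptable
route from that report to protein-level quantification, differential
statistics and QC, without assembling the steps by hand for every study.

The pipeline covers:

* **Ingestion & validation** — configurable column map for the report
  dialect, q-value censoring, identification-rate summaries, ON/OFF
  presence–absence calls.
* **Preprocessing** — removal of oxidized-Met precursors, condition-wise
  completeness filtering, log2 median normalization, per-peptide OLS
  batch/covariate adjustment that protects condition effects. Missing values
  are never imputed.
* **Protein quantification** — iBAQ (summed intensity over the count of
  observable tryptic peptides, 7–30 residues, cleavage after K/R except
  before P), Hi3/Top3 (mean of the three most intense precursors), and
  MaxLFQ: for each sample pair *(i, j)* with enough shared peptides the
  ratio is `r_ij = median_p (x_pi − x_pj)` on the log2 scale, and the
  per-sample profile solves `min_p Σ (p_i − p_j − r_ij)²` with the absolute
  level anchored to the protein's total observed signal.
* **Differential statistics** — per-peptide pooled t-tests, moderated by an
  empirical-Bayes variance prior (`s̃² = (d0·s0² + df·s²)/(d0 + df)` with
  `(d0, s0²)` fitted by method of moments on log-variances), aggregated per
  protein by the PECA rule: the protein ratio is the median peptide log2
  ratio, and the protein p-value is `P(median of n iid U(0,1) ≤ median p)`
  from the beta order-statistic distribution (exact for odd and even *n*).
  Benjamini–Hochberg adjustment across proteins, Cohen's *d* effect sizes,
  and per-condition iBAQ decile annotation with a 2D color code.
* **QC & reporting** — complete-case PCA with a deterministic sign
  convention, pairwise-complete sample correlations, per-condition CVs, and
  a self-contained static HTML report plus TSV/CSV result tables under a
  fixed folder layout.

A fully deterministic synthetic-study generator (`generate_study()`) emits
report, design, FASTA and ground truth, so every stage — and the pipeline's
error rates — can be validated without any external data.

## Worked example

```r
library(diaquant)

study <- generate_study(simulation_config(n_proteins = 200, seed = 1))
write_study(study, "demo")          # report.tsv, design.tsv, proteome.fasta, truth.json

bundle <- run_pipeline("demo/report.tsv", "demo/design.tsv",
                       fasta = "demo/proteome.fasta",
                       comparisons = study$comparisons, out = "demo_out")
print(bundle)
#> report_bundle
#>   7080 precursor rows, 6 samples
#> protein_stats (moderated_t peptide statistic):
#>   B_vs_A: 200 proteins, 45 with adj_p < 0.05

truth_evaluation(bundle$stats[["B_vs_A"]], study$truth)
#> type-I error 0.087 | power 1.00 | FC bias +0.047 | FC RMSE 0.132
```

The default study simulates 200 proteins (20% regulated at |log2 FC| = 1,
half up, half down), 2 conditions × 3 replicates, intensity-dependent
dropout and a small oxidized-precursor fraction. Of the 40 regulated
proteins all 40 are recovered at adj_p < 0.05 (the 5 extra calls above are
false positives among the 160 null proteins, consistent with the nominal
5% level on a draw this size); the estimated fold changes track the truth
with RMSE ≈ 0.13 log2 units. The top of the result table:

```
protein_group n_peptides_tested median_log2_ratio    protein_p        adj_p effect_size code_2d
        P0020                 7          1.137707 6.338685e-28 4.318693e-26    9.163059     3|1
        P0051                 7          1.143294 2.978327e-28 4.318693e-26   18.012007     8|7
        P0074                 6          1.134996 6.478039e-28 4.318693e-26   11.364481    10|8
```

`code_2d` is the pair of per-condition iBAQ deciles (10 = most abundant);
the written tables carry matching hex fill colors so low-abundance proteins
— whose ratios are least reliable — are visually flagged. All intermediates
live under `demo_out/01_ingest/ … 06_report/`, including the standalone
`report.html`.

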