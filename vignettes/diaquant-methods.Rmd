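---
title: "Models and methods behind the diaquant pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the diaquant pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaquant)
```

This vignette documents the statistical models, the tunable parameters and
the numerical choices implemented in diaquant, in the spirit of the methods
sections that accompany mature omics-analysis packages. Nothing here is a
benchmark claim; every number quoted is computed by the package's own test
suite or acceptance script.

## The data model

The pipeline's input currency is the long-format precursor report: one row
per precursor (modified peptide sequence + charge) per run, with a
quantity, a precursor-level q-value and a protein-group q-value. The
precursor — not the stripped peptide — is the unit of all downstream
arithmetic; stripped-peptide aggregation occurs only in identification
counting. Quantities that are non-positive or unparseable are treated as
missing at ingestion (search engines occasionally emit sentinel values);
duplicated (precursor, run) rows collapse to the row with the lowest
precursor q-value, with a warning.

q-value filtering (defaults: 0.01 at both levels) *censors* the quantity
rather than deleting the row. This keeps one table from which
identification-rate summaries can be computed both before and after
filtering, and means presence/absence analysis and quantification see the
same censoring decisions.

## Preprocessing

**Condition-wise completeness filter.** A precursor is kept iff, in at
least one condition, the fraction of non-missing replicates reaches
`min_fraction` (default 0.5). The fraction form (rather than an absolute
count) behaves consistently across designs with unequal replicate numbers.
The filter is monotone: raising the threshold can only shrink the kept set.

**Normalization.** Sample `j` is shifted by
`offset_j = median_j − median(all column medians)` on the log2 scale.
Median centering is the deterministic field standard for label-free data;
it assumes the bulk of the proteome is unchanged and that regulation has no
strong net direction. Post-normalization column medians agree to numerical
precision (< 1e-9), and the operation is idempotent. Reports already
normalized upstream can switch it off (`normalize = FALSE`).

**Batch/covariate adjustment.** Per precursor row, an OLS fit of log2
intensity on `condition + batch + covariates` (missing cells omitted); the
fitted batch/covariate contributions are subtracted, leaving condition
effects and residuals untouched — the removeBatchEffect-style contract that
cannot erase treatment signal by construction. Rows with no more
observations than model parameters (or a rank-deficient row submatrix) pass
through unadjusted and are flagged rather than dropped. A design in which
batch is confounded with condition is a hard error, because no linear
adjustment can separate the two. Rows sharing a missingness pattern are
solved in one QR decomposition, which keeps the per-row model affordable at
report scale. Single-level batch columns carry no information and are
ignored. Missing values are never imputed anywhere in the pipeline;
downstream statistics use complete cases per comparison. Imputation schemes
embed distributional assumptions about dropout that DIA data routinely
violate, and the moderated statistics handle unequal per-peptide sample
sizes directly.

## Protein quantification

**iBAQ.** Summed linear-scale precursor intensity of the protein divided by
its count of observable tryptic peptides. Digestion cleaves C-terminal of K
or R except before P; with `m` missed cleavages every concatenation of up
to `m + 1` consecutive fragments is a candidate, and distinct candidate
sequences with length in [`min_len`, `max_len`] are counted. Defaults (7–30
residues, 0 missed cleavages, distinct-sequence counting) follow the
original iBAQ formulation and are configurable. Multi-accession protein
groups are digested on the longest member sequence found in the FASTA and
flagged; groups without any FASTA match are flagged and left unquantified
by iBAQ.

**Hi3/Top3.** Mean of the three most intense precursors, selected per
sample independently; with fewer than three observed the mean of those
observed is used and flagged. Computed on the linear scale from the
normalized log2 matrix (2^x), so normalization carries over.

**MaxLFQ.** For each sample pair with at least `min_peptides_pair` shared
peptides (default 2, the classic minimum ratio count), the pairwise log2
ratio is the median of peptide differences. The per-sample profile is the
least-squares solution of the pairwise system, solved per connected
component of the pair graph via QR with a sum-to-zero gauge row. Pairwise
ratios leave one free constant per component; it is fixed by shifting the
profile so its summed linear-scale intensity equals the protein's summed
observed intensity — preserving both the ratio structure and a meaningful
abundance scale. Samples in disconnected components get independent
anchors; a protein with data in several samples but no valid pair falls
back to per-sample summed intensity with a `maxlfq_fallback` flag. The
implementation is verified against a dense normal-equations solve on random
instances (agreement < 1e-8).

**iBAQ deciles.** Per condition, each protein's condition-mean iBAQ
(condition-mean rather than median or per-sample values: stable for 2–4
replicates and monotone in abundance) is ranked with average ties and
binned into deciles 1–10 by empirical quantile, `d = ceil(10·rank/n)`.
Decile assignment is invariant under monotone transforms of the iBAQ scale.
Per comparison the two deciles combine into a `"d_num|d_den"` code, mapped
to a bilinear two-axis color gradient (100-row legend emitted as TSV) so
that low-abundance proteins — whose fold changes are least reliable because
of detector dynamic range — are visually marked in the result tables.

## Differential statistics

**Peptide tests.** Per comparison, every precursor with ≥ 2 finite values
in both conditions gets a two-sided pooled-variance t-test (pooled rather
than Welch by default, because the variance-moderation model assumes a
shared variance structure; Welch remains available).

**Variance moderation.** Residual variances across all tested peptides of
a comparison are modeled with a scaled inverse-chi-square prior. On the log
scale, `E[log s²] = log σ² + ψ(df/2) − log(df/2)` and
`Var[log s²] = ψ′(df/2)`, so matching the mean and the excess spread of
log-variances (digamma/trigamma identities, with a Newton inversion of the
trigamma function) yields `(d0, s0²)`. If the observed spread does not
exceed the sampling-only spread, `d0 = ∞` and all variances shrink to the
common `s0²`. The moderated statistic uses
`s̃² = (d0·s0² + df·s²)/(d0 + df)` with `d0 + df` degrees of freedom;
`d0 = 0` reproduces the ordinary test exactly and `d0 = ∞` uses the normal
reference. Parameter recovery is validated by simulation (20 000 peptides
from a known prior: d0 within ±15%, s0² within ±10%), and null p-values
pass a Kolmogorov–Smirnov uniformity check.

**Protein aggregation.** The protein log2 ratio is the median of its
peptide log2 ratios (robust to single aberrant peptides; an
intensity-weighted slope model was the alternative, rejected for its
sensitivity to the highest-intensity peptide). The protein p-value is the
probability that the median of `n` iid Uniform(0,1) p-values is at most the
observed median peptide p. For odd `n` this is the Beta(k, n−k+1) CDF with
`k = (n+1)/2`. For even `n` the median is the average of the two central
order statistics; their joint density `K·u^(k−1)(1−v)^(n−k−1)` on `u < v`
reduces the CDF to a one-dimensional integral, evaluated with
`stats::integrate` at rel.tol 1e-10 — exact, deterministic, and verified
against Monte-Carlo order statistics. The aggregation layer accepts any
peptide-level p-value, so the plain t-test variant (`peptide_statistic =
"t"`) shares the identical protein-level machinery. The peptide-level
statistic behind the default is the moderated t rather than a
bootstrap-optimized family: the aggregation rule is what drives the
protein-level error control, and a closed-form peptide statistic keeps the
pipeline deterministic at any scale.

Benjamini–Hochberg adjustment is applied across proteins within each
comparison separately (`stats::p.adjust`; a brute-force step-up oracle
checks equality in the tests). Effect sizes are Cohen's *d* on per-sample
protein profiles, MaxLFQ by default; zero pooled SD is flagged rather than
reported as an infinite d. Multi-condition designs are handled as pairwise
comparisons; omnibus testing is out of scope.

## QC

PCA operates on protein-level MaxLFQ profiles by default, complete-case
(features with any missing value dropped — consistent with the no-imputation
rule), centered, via SVD. A deterministic sign convention (each loading's
largest-magnitude entry is positive) makes outputs bit-stable across
platforms. Sample correlations use pairwise-complete observations with a
minimum overlap of 3. CVs are computed per condition on the linear scale
(SD/mean over observed replicates, ≥ 2 observations required) and are
scale-invariant. ON/OFF calls derive from detection fractions (a protein is
detected in a run when ≥ 1 precursor passed the q-filters with a quantity);
defaults are strict presence/absence (on-fraction 1.0, off-fraction 0.0),
both configurable.

## The synthetic-study generator

`generate_study()` draws a hierarchical model: protein base level ~
Normal(14, 2) on the log2 scale (a realistic DIA dynamic range of roughly
4 orders of magnitude), per-peptide ionization offset ~ Normal(0, 1),
per-measurement replicate noise ~ Normal(0, 0.25), two conditions × 3
replicates, 20% of proteins regulated at |log2 FC| = 1. Regulated proteins
alternate deterministically between up- and down-regulation: global median
normalization assumes no net proteome shift, and a simulation whose entire
regulated set moves one way would violate the assumption of the very
normalization the pipeline applies (with `fc_direction = "up"` available
for studying exactly that failure mode). The regulated count is
`floor(n · fraction)` rather than a Bernoulli draw so truth counts are
assertable. Missingness is an intensity-dependent logistic dropout
(`P(missing) = plogis(steepness·(midpoint − log2 intensity))`, defaults
midpoint 8, steepness 1 — a few percent missing, concentrated at low
abundance, the dominant DIA mechanism). A 5% fraction of peptides also
emits an oxidized-Met precursor variant (tagged in the modified sequence,
two log2 units lower) to exercise the modification filter. The FASTA is
built by concatenating each protein's generated tryptic peptides (peptides
end in K/R and contain no internal K, R or P), so digestion recovers
exactly the generated peptide set and the iBAQ divisor is self-consistent.
Generation is a pure function of (config, seed): identical seeds give
byte-identical files.

What the generator does *not* emulate: correlated peptide errors within a
protein (real digests share missed-cleavage and matrix effects), retention-
time-dependent intensity drift, interference/chimeric signals,
heavy-tailed noise, and shared peptides between protein groups. Passing
tests therefore demonstrate correctness of the implemented contracts and
calibration under the stated model — not performance guarantees on any
real instrument's data.

## Validation scale and determinism

The shipped test suite validates the numerical contracts at desk scale:
oracle equivalence on 100 random MaxLFQ instances (≤ 6 samples, ≤ 10
peptides), 1000-sequence digestion and 1000-vector BH oracle sweeps,
10^6-draw Monte-Carlo checks of the order-statistic CDF at n ∈ {3, 5, 7},
type-I error on a 2000-protein null study (observed fraction of
protein_p < 0.05 within [0.03, 0.07]), and fold-change recovery on a
200-protein regulated study (sign-aligned mean estimated log2 FC within
1.0 ± 0.1). The full suite runs in about 2½ minutes; `scripts/acceptance.R`
recomputes the headline quantities in ~10 s.

Determinism is treated as a feature throughout: no stage uses randomness,
generator output is seed-pure, the even-n order-statistic CDF is computed
by quadrature rather than sampling, PCA signs are pinned, and two pipeline
runs from the same inputs produce byte-identical statistics tables and
HTML (figures can be disabled via `include_figures = FALSE` where
byte-identity of the report file matters).

## Known limitations

* Protein groups are taken as given; shared peptides are not reallocated,
  and multi-accession iBAQ uses one member sequence.
* No retention-time (local regression) normalization; median centering only.
* ROPECA-style inference assumes peptide p-values of a null protein are
  independent; correlated peptide errors make the protein p anticonservative
  in proportion to the correlation.
* No longitudinal/mixed models; comparisons are pairwise two-condition.
* The HTML report is static (sortable tables only), and spreadsheet outputs
  are CSV/TSV with explicit color columns rather than styled workbooks.
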