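---
title: "Methods: multi-omic profiling of a small gene network across tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic profiling of a small gene network across tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

panmethnet analyzes how DNA methylation shapes the expression of a small
gene network across many tumor cohorts, and how that network couples to
protein levels and patient survival. This vignette documents the models
and procedures, the parameters that matter, the synthetic data the test
suite relies on, and the numerical decisions behind each stage.

## The analysis model

The pipeline operates on four linked data types per cohort: log2(fpkm +
0.001) expression for genes and their spliced isoforms, Illumina
450K-style beta values for CG probesets annotated to gene regions
(promoter, 1st exon, gene body, 3'UTR), RPPA-style protein levels
available only in subsets of cohorts, and right-censored survival
endpoints (overall survival, OS; progression-free interval, PFI).

**Differential expression.** For two groups of log2 expression values, the
signed fold change is

$$FC = \pm\, 2^{\,|\overline{x}_2 - \overline{x}_1|},$$

positive when group 2 (conventionally the tumor group) has the higher
mean, negative otherwise. Equal means map to +1: a tie can never be
called in either direction, so its sign is immaterial and the +1
convention keeps the magnitude invariant $|FC| \ge 1$ intact.
Significance uses the two-tailed unpaired t-test; the unequal-variance
(Welch) form is the default because it is the default of R's `t.test`,
with the pooled-variance form available via `var_equal = TRUE`. A feature
is called up when $FC \ge 1.4$ and $p \le 0.05$, down when
$FC \le -1.4$ and $p \le 0.05$ — thresholds are configuration, never
hard-coded. No multiple-testing correction is applied to the calls (the
analysis convention this pipeline reproduces uses per-test p-values); a
Benjamini–Hochberg column is emitted alongside for readers who want it.
Pooled analyses pool raw samples, unweighted by cohort size — cohorts
with more samples therefore contribute more, which is stated here
because the alternative (equal cohort weights) is equally defensible.

**Profiling.** Per cohort, the tumor median of each feature is compared
with the interquartile range of the matched normal tissue: above the 3rd
quartile, below the 1st, or neither. Quantiles are linear-interpolation
type 7, R's default, and configurable. "Outlier" cohorts are flagged
with the standard Tukey boxplot rule — beyond $Q_1 - 1.5\,\mathrm{IQR}$
or $Q_3 + 1.5\,\mathrm{IQR}$ of the per-cohort medians — chosen because
it is the rule the field's boxplot-centric displays imply; no other
operationalization is standard. Methylation states use the conventional
beta-value bands: methylated when the median beta $\ge 0.6$,
unmethylated when $\le 0.2$, partial in between. Both boundaries are
closed on the extreme side; the 0.2 boundary is sometimes quoted
exclusively elsewhere, so it is a documented, configurable choice here.

**Correlation.** Pearson's r with a two-sided p from the t transform
$t = r\sqrt{(n-2)/(1-r^2)}$, $df = n - 2$. Missing values are removed
pairwise, not listwise, because RPPA panels differ by cohort and
listwise deletion would discard whole cohorts. Pairs with fewer than 3
complete observations — the mathematical floor for a p-value — are
dropped and counted. Significance is $|r| \ge 0.3$ at $p \le 0.05$ for
expression and protein analyses and $p \le 0.01$ for the per-cohort
methylation–expression analyses, matching the conventions of the
analyses this pipeline reproduces; both are configuration keys.
Correlation profiles are grouped by agglomerative clustering with
average linkage on Euclidean distances, cut to exactly `n_clusters`
(default 7). Rows are sorted lexicographically before clustering so that
distance ties resolve deterministically, and labels are renumbered by
first appearance.

**Concordance networks.** Per-cohort significant correlations aggregate
into undirected edges: a pair significant in at least `min_cohorts`
cohorts (default 5 for gene–protein, 20 for protein–protein) becomes an
edge whose concordance is *total* when every significant cohort agrees
in sign and *partial* otherwise. Non-significant cohorts are ignored
entirely — they carry no sign information under the thresholding rule —
and `mean_r` averages significant cohorts only. Self-pairs are excluded
and edges are unordered, since correlation networks are undirected.

**Four-group stratification.** Tumor samples are stratified by one
promoter probeset and one body probeset, each split at its central value
over all included samples: Group 1 = promoter low / body high, Group 2 =
promoter low / body low, Group 3 = promoter high / body high, Group 4 =
promoter high / body low. When promoter methylation represses and body
methylation accompanies transcription, expression is expected to order
Group 1 highest and Group 4 lowest, with the promoter effect separating
Groups 2 and 3. The split statistic defaults to the median, with
`center = "mean"` available: the two conventions coexist in this
analysis family, so both are supported and neither is silently
preferred. Samples exactly at a split value go to the low side —
deterministic, documented, configurable in effect by nudging the probe
choice. Expression differences between all six group pairs use the same
FC and Welch machinery as the differential stage. The probe pair is an
input, never auto-selected: choosing the "most correlated" pair inside
the function would bias the downstream test.

**Survival.** Features are dichotomized at the median of the included
samples (ties to the low group — the grouping rule is an explicit
assumption, recorded in the output, since upstream sources rarely state
theirs), and the two groups are compared with the standard two-group
log-rank test (hypergeometric variance at each distinct event time, 1
df). Significant features are *favorable* when the high-feature group
has the better survival curve and *unfavorable* otherwise; "better" is
operationalized as the higher restricted-mean survival over the common
observed horizon, the standard scalar summary of curve ordering. No Cox
modeling, hazard ratios, or covariate adjustment: the annotation is a
log-rank screen, not a prognostic model.

## The synthetic cohort generator

Every downstream stage is validated against data with known ground
truth. `simulation_config()` defaults describe the emulated study
conditions: 33 tumor cohorts named with TCGA codes, 200 tumor and 50
matched normal samples per cohort, three network genes with eight
isoforms and twenty CG probesets each (6 promoter, 4 1st-exon, 8 body,
2 3'UTR), and a twelve-protein RPPA panel.

Generation proceeds per cohort and gene:

- **Expression** is Gaussian in log2 space around a cohort baseline
  (`base_mean` plus a cohort effect with sd `cohort_sd` = 0.5), shifted
  by `tumor_shift` log2-units in tumor samples, with residual sd
  `noise_sd` = 1 — values typical of bulk RNA-seq log2 expression.
  Values are floored at log2(0.001), the minimum of the
  log2(fpkm + 0.001) scale. Isoforms are their gene's value plus a
  biotype offset (coding −0.5, non-coding −3, retained-intron −4
  log2-units, mirroring the weak expression of non-coding and
  retained-intron isoforms) plus noise (sd 0.3).
- **Methylation** uses a Gaussian-copula construction: a latent normal
  $z = \rho_{lat}\, x_{std} + \sqrt{1-\rho_{lat}^2}\,\varepsilon$ is
  coupled to standardized tumor expression and mapped through the
  logistic function to (0, 1) with a region-specific location (promoter
  −2, 1st exon −0.5, body +2, 3'UTR +0.5 on the logit scale — promoters
  hypomethylated, bodies hypermethylated). Because the logistic
  transform attenuates Pearson correlation, the latent coupling is
  inflated by the analytically computed attenuation factor
  $a = \mathrm{cor}(\mathrm{plogis}(loc + z), z)$ (Gaussian quadrature),
  so the *configured* coupling is the *realized* beta–expression
  correlation, not an upper bound on it. Promoter and 1st-exon probes
  share `promoter_coupling`; body and 3'UTR probes share
  `body_coupling`. Only correlation signs and magnitudes are specified
  by the analyses this emulates, so the copula form is a design choice;
  it makes planted couplings exact and recoverable.
- **Proteins** are standard-normal variables coupled to their gene's
  standardized expression at a signed target correlation. Six core
  proteins are measured in all nine tumor groups at $|\rho| = 0.7$ —
  pairs of core proteins attached to the same gene then inherit a
  pairwise correlation of about $0.49$, which is what lets
  protein–protein edges clear an $|r| \ge 0.3$ threshold across ≥ 20
  cohorts, as a broadly-measured core panel does in real RPPA data. The
  other six are measured only in a 5-of-9 window of tumor groups at
  $|\rho| = 0.5$, reproducing panel heterogeneity. Cohorts cycle
  through tumor groups 1–9.
- **Survival** times are exponential with log-hazard linear in
  standardized expression (summed over genes, each weighted by its
  `survival_effect`), with administrative censoring at the baseline
  70th percentile — about 30% censored under the null, typical of
  registry follow-up and enough to keep the log-rank test powered at
  n = 200. OS and PFI share effects but differ in baseline rate
  (1/1000 vs 1/600 per day), so PFI events come earlier.

The seed fully determines the bundle; equal seeds give byte-identical
output. A truth table records every planted parameter per gene and
cohort.

What the generator does **not** emulate: empirical marginal
distributions of real expression or methylation data, batch effects,
copy-number structure, inter-gene co-expression (genes are generated
independently, so proteins never correlate with two genes at once and
the shared-anchor summary is exercised on constructed fixtures instead),
probe-level spatial autocorrelation, or informative censoring. Passing
tests therefore demonstrate that the *statistical machinery* recovers
planted structure at realistic sizes and calibrates correctly under the
null — not that any biological conclusion transfers to real cohorts.

## Numerical and interface decisions

- **File dialect.** Tab-separated, feature-id-first-column matrices
  (the UCSC Xena genomicMatrix shape); `""` and `"NA"` (any case) read
  as missing, `"NA"` written. Read/write round-trips are byte-identical
  on canonical fixtures; sample and feature order is always preserved,
  never sorted. Beta matrices are range-checked on read with the
  offending cell named. Genomic intervals, when present, are 0-based
  half-open and carried as metadata only.
- **Degenerate inputs** are skipped with a reason, not thrown, wherever
  a pipeline must survive them: sparse features in t-tests (< 2 values
  per group, or zero variance — both yield a missing p), constant
  vectors in correlations, all-missing probesets, degenerate median
  splits in survival. Structural violations (duplicate identifiers,
  out-of-range beta values, empty sample intersections, missing probes)
  are hard errors naming the offender.
- **Determinism.** The pipeline writes a manifest of MD5 hashes per
  artifact; identical configuration and seed reproduce identical
  hashes. Number formatting is fixed at 15 significant digits,
  non-scientific.
- **Command-line interface.** The package's functions are the primary
  interface; a thin `inst/cli/panmethnet.R` script exposes `simulate`
  and `run-all` — the two entry points with end-to-end contracts —
  while per-stage analyses are exported functions rather than
  subcommands, which keeps the CLI surface minimal without hiding any
  stage.

## Problem sizes used in validation

The test suite validates arithmetic against hand-computed values and
independent reference implementations (1,000 randomized quantile
instances; 500 each for Welch, Pearson and log-rank agreement at 1e-8),
recovers planted effects on single cohorts of 200 tumor samples over
100 seeds (fold change within [1.7, 2.3] for a planted 1-log2 shift;
significant negative correlation for a planted −0.5 promoter coupling;
correct direction for a planted hazard effect — each in ≥ 95% of
seeds), checks null calibration (≤ 10% of runs significant at
p ≤ 0.05 with all effects zero), and runs the full 33-cohort default
bundle end-to-end twice to confirm byte-determinism. These sizes were
chosen to give the binomial pass criteria comfortable margins while
keeping the default suite quick to run.

## Known limitations

- Direction calls in survival annotation depend on the median-split
  assumption; tertile or continuous analyses may disagree near the
  threshold.
- The partial/total concordance classification ignores non-significant
  cohorts entirely; a pair barely missing significance in a dissenting
  cohort still counts as total concordance.
- Pooled correlations mix within- and between-cohort variation; planted
  within-cohort couplings therefore appear attenuated in pooled
  estimates (e.g. a −0.5 within-cohort promoter coupling pools to about
  −0.45 with the default cohort spread). Per-cohort tables are the
  faithful view.
- The fold-change magnitude floor of 1 means FC is non-informative for
  near-tied means; calls rely on the p-value in that regime.
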