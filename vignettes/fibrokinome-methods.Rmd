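---
title: "Kinome panel expression analysis of fibrotic lung tissue: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinome panel expression analysis of fibrotic lung tissue: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrokinome)
```

## The problem

Idiopathic pulmonary fibrosis (IPF) progresses unevenly across the lung:
different segments of the same organ can range from nearly normal to
end-stage honeycombing, and the Ashcroft score (0–8) grades this severity
histologically, with ≥ 6 conventionally read as severe fibrosis.
`fibrokinome` analyses targeted RNA-seq of a 612-gene kinome panel across
multiple tissue samples per patient, asking three questions: does the
expression signature track fibrosis severity rather than diagnosis alone;
is IPF tissue more internally heterogeneous than control tissue; and
which kinases — in particular those with clinically available inhibitors
— are upregulated, overall and per patient.

Because the pipeline's inputs (a raw count matrix with transcript lengths
and mapped-library totals, a sample sheet, a panel annotation) are rarely
publicly available for studies of this kind, the package ships a
first-class synthetic-data generator that reproduces the study design and
plants known effects, so every stage is testable against ground truth.

## Normalization

Counts are converted to RPKM:
$$\mathrm{RPKM}_{gs} = \frac{10^9 \, c_{gs}}{L_g \, N_s},$$
with $L_g$ the transcript length in bp and $N_s$ the sample's *total*
mapped-read count. $N_s$ is carried explicitly per sample and never
inferred from panel column sums: a targeted panel captures only a few
percent of the library, so the per-million denominator must be the
library-wide total. Whether the upstream pipeline counted mapped reads
genome-wide or panel-wide is a property of the input file, not of this
package; the totals field supports either convention.

The targetable subpanel filter keeps the 46 inhibitor-flagged kinases and
then removes any whose summary RPKM falls below the overall median RPKM
of the full gene × sample matrix. Neither the pooling nor the per-gene
summary convention is canonical, so the per-gene summary is configurable
(`median` default, `mean` selectable). The filter records the threshold
on its output, so re-filtering an already filtered subpanel is a no-op
(the threshold is defined against the full panel, not recursively).

## Clustering adjustment

Before clustering, each sample column is centred by its own median, then
each gene row is divided by its standard deviation across all samples of
the centred matrix. Conventions, each configurable:

* **SD convention**: population (divide by $n$) by default — the
  convention of the classic clustering tools this adjustment imitates —
  with sample ($n-1$) selectable.
* **SD scope**: per-gene across samples by default; a single pooled SD of
  the whole matrix is selectable, since "standard deviation of all
  samples" admits both readings.
* Zero-variance genes after centring are dropped with a warning rather
  than producing infinities.

Clustering itself is agglomerative over sample columns with uncentered
Pearson correlation distance and average linkage by default (centred
correlation and Euclidean distance; single and complete linkage are
selectable). Merging is deterministic: among pairs tied in distance
(within 1e−12), the pair whose sorted leaf-label vector is
lexicographically smallest merges first. The implementation is checked in
the test suite against both an exhaustive agglomeration oracle and
`stats::hclust`. Dendrograms export as Newick (via `ape`) and as a merge
table; flat labels come from cutting the tree at a requested count.

By default the full-study pipeline clusters $\log_2(\mathrm{RPKM}+1)$
values: log transformation before hierarchical clustering is the standard
practice of the expression-clustering tools this stage follows, and on
the raw scale the median-centring step is dominated by the most abundant
genes. Raw-scale clustering remains available (`cluster_log2 = FALSE`).

## Expression diversity

For each patient with at least two samples and each gene,
$$D_{pg} = \frac{\max_s \mathrm{RPKM}_{gs} - \min_s \mathrm{RPKM}_{gs}}
               {\mathrm{SD}_g},$$
the range taken over that patient's samples and $\mathrm{SD}_g$ the
gene's SD over *all* samples (per-gene scope and population SD by
default, consistent with the clustering module). Single-sample patients
are excluded — a range needs two values. Patient-level summaries (median
over genes by default, mean selectable) are compared between IPF and
control by a Wilcoxon rank-sum test.

Two properties of this index matter for interpretation:

* **The range grows with the number of samples per patient.** A patient
  contributing six samples has a systematically larger expected range
  than one contributing two, even under identical biology. Group
  comparisons on an unbalanced roster therefore mix heterogeneity with
  sampling depth; the package reports per-patient sample counts alongside
  the summaries so this is visible, and the test's null calibration in
  the acceptance suite uses a balanced roster where the groups are
  genuinely exchangeable.
* **Attainable significance at small n.** With 3 eligible IPF patients
  and 4 controls the exact two-sided Wilcoxon cannot go below
  p = 2/35 ≈ 0.057. The default therefore uses the normal approximation
  without continuity correction, for which the most extreme rank
  arrangements reach p ≈ 0.034 and the realized type-I error
  (≈ 2/35) stays near the nominal 0.05; the exact test is selectable
  (`exact = TRUE`).

## Differential ranking

For a case selection (a group, a patient, or explicit samples) against a
reference group, each gene gets
$$\log_2\!\frac{\bar{x}_{\mathrm{case}} + \varepsilon}
               {\bar{x}_{\mathrm{ref}} + \varepsilon},$$
with $\varepsilon$ = 0.1 RPKM by default keeping ratios finite at zero
means ($\varepsilon = 0$ is allowed; zero-mean genes are then reported
unranked rather than infinite). Ratios are of group means of raw RPKM —
not means of logs — matching how fold changes are conventionally reported
for this design. "More than twofold" is the strict inequality
log₂ ratio > 1. DEG counts per Ashcroft stratum compare the stratum's IPF
samples against all controls at |log₂ ratio| > 1.

Per-gene significance uses Welch's t test by default: with 13-vs-8
unpaired groups there is no natural pairing, so the paired mode — kept
because such designs sometimes prescribe it — requires an explicit
pairing map and refuses to truncate silently. No multiple-testing
correction is applied by default (fold-change ranking, not hypothesis
screening, is the primary output); Benjamini–Hochberg adjusted p values
are available behind `stats::p.adjust` on the returned column.

## Weighted-voting severity classifier

Training uses one patient's samples split at Ashcroft ≥ 6. For each gene,
the class-mean difference $\mu_{\ge6} - \mu_{<6}$ is computed on
$\log_2(\mathrm{RPKM}+1)$ by default; genes beyond $+1$ are "induced",
beyond $-1$ "suppressed". The log₂ scale is the default because the ±1
threshold then means "twofold" for every gene regardless of abundance;
on raw RPKM a threshold of "1 RPKM unit" selects by baseline expression
and admits abundant noise genes. Raw scale is selectable and recorded in
the model metadata.

Each selected gene receives the signal-to-noise weight and midpoint
boundary
$$S_x = \frac{\mu_{\ge6} - \mu_{<6}}{\sigma_{\ge6} + \sigma_{<6}},
\qquad b_x = \frac{\mu_{\ge6} + \mu_{<6}}{2},$$
and a test sample casts votes $V_x = S_x (g_x - b_x)$; the sign of
$\sum_x V_x$ predicts the stratum (severe when positive). A total of
exactly zero is called non-severe and flagged as a tie — a conservative
default. No prediction-strength cutoff is applied: every sample receives
a call. The model serializes to a plain TSV (gene, class, $S_x$, $b_x$)
for auditability.

## The synthetic generator

Counts are drawn negative-binomially with mean
$$\mu_{gs} \cdot \frac{L_g N_s}{10^9}, \qquad
\mu_{gs} = B_g \cdot 2^{\,e_g \sigma_s + \epsilon_{gp} + \epsilon_{gs}},$$
so RPKM normalization recovers $\mu_{gs}$ in expectation. Defaults, each
chosen once as a realistic rendering of the study design:

* **Roster**: 13 IPF samples over 5 patients (6, 3, 2, 1, 1) and 8
  control samples over 4 patients (2 each); Ashcroft scores give the
  six-sample patient three severe and three moderate samples, the
  three-sample patient 2 + 1, the two-sample patient 1 + 1.
* **Panel**: 612 genes — 517 kinase, 46 cancer-related, the remaining 49
  uncategorized ("other") — with 46 inhibitor-flagged kinases; transcript
  lengths log-uniform in [500, 10000] bp; mapped totals uniform in
  [2, 4] million.
* **Baseline** $B_g$: lognormal, median 10 RPKM, sdlog 1.2.
* **Severity effect** $e_g$: 30 induced genes at log₂ effect +2 and 10
  suppressed at −2, active in the severe stratum ($\sigma_s \in \{0,1\}$
  binary by default; a linear-in-Ashcroft mode is available).
* **Noise**: per-(gene, patient) log₂ SD 0.25; per-(gene, sample) segment
  log₂ SD 0.25, multiplied by 3 for IPF samples (the within-patient
  heterogeneity the diversity index is designed to detect); NB dispersion
  0.05.

Two named scenarios are used by the recovery-style tests and documented
here as part of the study conditions:

* **Low noise** (gene-selection recovery): segment SD 0.2, heterogeneity
  1, dispersion 0.01, totals 10⁷. The deep totals matter: at 2–4 million
  reads, Poisson noise on ~1-RPKM genes alone can exceed the ±1 selection
  threshold, so a recovery test at shallow depth measures sequencing
  depth rather than the selection rule.
* **Strong severity signature** (clustering separation): 60 induced + 30
  suppressed genes (~15 % of the panel) at log₂ effect 3, patient SD
  0.05, segment SD 0.2, dispersion 0.01. The smaller patient SD is what
  makes severity, rather than patient identity, the dominant correlation
  structure: at the default patient SD the per-patient signature spans
  all 612 genes and average linkage clusters samples by patient — which
  is realistic, and mirrors the fact that at the whole-cohort level IPF
  and control samples need not separate.

What the generator does **not** emulate: gene–gene correlation beyond the
shared patient/segment factors, GC or length bias, alignment artifacts,
zero inflation, and any real kinome biology — planted effect genes are
exchangeable with the rest of the panel. Passing recovery tests therefore
demonstrates that the algorithms detect the structure they target at
realistic noise levels, not that real IPF lungs carry that structure.

## Numerical choices and degenerate inputs

* Population SD throughout by default; every module shares the same
  switch.
* Zero-variance genes: dropped with a warning in adjustment and
  diversity; an error in the signal-to-noise weight (a degenerate gene in
  a fitted model is a modelling error, not a data nuisance).
* Tie-breaks: lexicographic smallest leaf pair in clustering; non-severe
  on a zero voting total.
* Validation is strict and early: duplicate ids, negative counts (with
  cell coordinates), missing mapped totals, IPF samples without Ashcroft
  scores, and patients in both groups are all hard errors; the full run
  configuration is validated before any computation starts.
* Problem sizes in the test suite: oracle checks run on 40-gene
  instances; recovery and calibration checks use the full 612-gene study
  at 100–500 replicates, sizes at which the whole suite completes in
  about a minute.

## Known limitations

* The diversity index confounds within-patient heterogeneity with
  per-patient sample count (see above); comparisons across unbalanced
  rosters should be read accordingly.
* The weighted-voting classifier is fitted on a single patient by design;
  its transfer to other patients depends on the severity effect being
  shared, which the generator guarantees but real cohorts need not.
* With three eligible IPF patients the diversity comparison has minimal
  resolution; the test is reported with its direction and estimate so the
  effect size, not the p value, carries the interpretation.
* The subpanel filter's "overall median" threshold makes survival of a
  gene depend on the abundance distribution of the whole panel, so
  survivor counts are not comparable across panels.
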