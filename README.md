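# fibrokinome

Targeted kinome-panel RNA-seq analysis of multi-region lung tissue in
idiopathic pulmonary fibrosis (IPF).

IPF lungs are spatially heterogeneous: fibrosis severity, graded
histologically by the Ashcroft score (0–8, dichotomized at ≥ 6 = severe),
varies between segments of the same lung. `fibrokinome` implements, as a
tested and reusable pipeline, the analysis stages used to profile kinase
gene expression across such multi-region samples on a 612-gene targeted
panel (517 protein-kinase-coding and 46 cancer-related genes, with a
46-gene subpanel of kinases that have clinically available inhibitors):

1. **RPKM normalization** — RPKM_gs = counts_gs × 10⁹ / (L_g × N_s), with
   L_g the transcript length (bp) and N_s the sample's total mapped reads.
2. **Sample clustering** — median-centring of each sample, per-gene SD
   scaling, then agglomerative clustering (uncentered correlation
   distance, average linkage by default) with Newick export.
3. **Expression diversity** — per patient and gene, (max − min RPKM
   across the patient's samples) / the gene's SD over all samples; an
   index of within-patient heterogeneity, compared between IPF and
   control patients by a rank-based test.
4. **Fold-change ranking** — log₂ ratio of group-mean RPKM (IPF vs
   control, integrated and per patient), > twofold flagging, stratified
   DEG counts, and per-gene Welch/Student/paired t tests.
5. **Targetable subpanel filter** — restricts to inhibitor-flagged
   kinases and drops genes below the overall median RPKM of the full
   matrix.
6. **Weighted-voting severity classifier** — per-gene signal-to-noise
   weight S_x = (μ_≥6 − μ_<6)/(σ_≥6 + σ_<6), boundary
   b_x = (μ_≥6 + μ_<6)/2, vote V_x = S_x(g_x − b_x); genes with class-mean
   difference beyond ±1 (log₂ scale) enter as "induced"/"suppressed", and
   the sign of ΣV_x predicts the severity stratum of a held-out sample.
7. **Synthetic-data generator** — negative-binomial counts with
   severity-linked effects and an IPF within-patient heterogeneity
   multiplier, reproducing the study design (21 samples from 9 patients:
   13 IPF over 5 patients with 6,3,2,1,1 samples, 8 control over 4
   patients with 2 each) so every stage is testable without raw data.

## Worked example

```r
library(fibrokinome)

d    <- simulate_dataset(default_study_config(), seed = 1)
expr <- compute_rpkm(d$counts, d$panel)

count_degs(expr, d$sheet, "severe")       # 58
count_degs(expr, d$sheet, "moderate")     # 15

div <- compute_diversity(expr, d$sheet)
test_group_diversity(div, d$sheet)$p_value  # 0.034

model <- fit_model(expr, d$sheet, "IPF1")   # 43 induced + 31 suppressed
held  <- d$sheet$sample_id[d$sheet$patient_id %in% c("IPF2", "IPF3")]
scores <- score_samples(model, expr, held)
evaluate_model(scores, d$sheet)$accuracy    # 1
```

With the default generator settings (30 induced + 10 suppressed genes at
log₂ effect 2 in the severe stratum; 3× segment-noise inflation for IPF),
the severe stratum shows far more > twofold DEGs than the moderate one
(58 vs 15; the planted signal sits entirely in the severe stratum), the
within-patient diversity contrast favours IPF (p = 0.034, the smallest
value the 3-vs-4-patient comparison can produce), and the voting model
fitted on the six-sample patient classifies every held-out sample of the
other two multi-sample IPF patients correctly.

`run_full_study(run_config(out_dir = "out", simulate =
default_study_config()))` executes all stages and writes every result
table (adjusted matrix, dendrogram in Newick, DEG counts, diversity
tables, integrated and per-case rankings, subpanel profiles, voting model
and scores) plus a YAML manifest echoing the configuration.

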