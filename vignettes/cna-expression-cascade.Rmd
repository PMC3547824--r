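---
title: "Methods: the integrative CNA/expression cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the integrative CNA/expression cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaxpress)
```

## The scientific problem

In oral squamous cell carcinoma and many other solid tumors, part of the
transcriptional difference between metastatic and non-metastatic tumor cells
is driven by segmental DNA copy-number abnormalities (CNAs): a gained or
deleted chromosomal segment changes the dosage of the genes it contains.
Transcripts whose differential expression is *explained by* a local
copy-number change are attractive driver candidates, because the genomic
lesion provides a causal anchor that expression differences alone lack.

`cnaxpress` implements a three-gate cascade that operationalizes this idea,
together with the downstream uses of the resulting transcript signature
(patient stratification and survival analysis) and the analysis of siRNA
viability screens used to functionally triage the candidates. Because
desk-scale validation needs known truth, the package also ships a synthetic
cohort generator that emulates the statistical structure of the inputs with
planted driver transcripts.

## The cascade

Given an expression matrix (transcripts x samples, normalized log2 scale), a
SNP panel with a probes x samples matrix of log2 tumor:reference intensity
ratios, and a two-group design (non-metastatic primary vs nodal metastasis):

1. **Differential expression** (`de_screen()`). Probes with no variation
   across samples, or expressed at very low magnitude, are removed first
   (`filter_probes()`; defaults: SD strictly positive, maximum at or above
   the matrix's 25th percentile — both configurable, as there is no
   principled universal constant). Each remaining transcript is tested with
   a two-group linear model whose standard error is the HC0 sandwich
   estimate, i.e. \(\mathrm{SE}^2 = \hat\sigma^2_1/n_1 + \hat\sigma^2_2/n_2\)
   with maximum-likelihood group variances and a normal reference. This is a
   deliberately transparent stand-in for generic regression-based estimating
   equations: it is robust to unequal group variances and exactly
   reproducible. Selection uses Benjamini–Hochberg at FDR < 5%.
2. **Copy-number correlation** (`robust_corr_test()`). Each DE transcript is
   assigned the SNPs within a closed ±250 kb window around its gene body
   (`map_snps()`); its per-sample copy number is the arithmetic mean of the
   smoothed log2 estimates of those SNPs (`transcript_cn()`; the mean is the
   least-assumption summary, the median is available via
   `pipeline_config(cn_summary=)`). Expression is regressed on copy number
   across *all* samples with a Huber M-estimator (`MASS::rlm`, MAD scale)
   so single outlying samples cannot manufacture or destroy a correlation;
   the zero-slope test uses the M-estimator's asymptotic SE. BH is
   recomputed *within the DE set* and gated at FDR < 1%.
3. **Group copy-number difference** (`group_cn_difference()`). Within the
   correlated set, the transcript-level copy number is compared between
   groups by the Wilcoxon rank-sum test (midranks for ties; exact null
   distribution when the smaller group has ≤ 8 samples and there are no
   ties, otherwise the normal approximation with tie and continuity
   corrections). BH again within the candidate set, gated at FDR < 1%.

Survivors of all three gates form the signature. Each is labelled
`up_amplified` (expression and copy number both higher in metastases),
`down_deleted` (both lower), or `discordant` — discordant transcripts are
retained but flagged, since the gates themselves impose no concordance
requirement. Recomputing BH within each successive candidate set (rather
than once globally) matches the stage-wise FDR semantics of the gate
thresholds: each stage controls the false-discovery proportion among the
candidates it actually passes on.

## Copy-number estimation

Log2 ratios are smoothed per chromosome with the sparse fused-lasso signal
approximator,

$$\min_\beta \tfrac12\sum_i (y_i-\beta_i)^2 + \lambda_1\sum_i|\beta_i|
  + \lambda_2\sum_{i>1}|\beta_i-\beta_{i-1}|,$$

solved **exactly**: the fusion-only solution is computed by Condat's direct
total-variation algorithm and then soft-thresholded by $\lambda_1$, which is
the exact minimizer of the full objective for the 1-D problem. Smoothing is
applied independently within each chromosome (no fusion across chromosome
boundaries — a genome-wide run would fuse unrelated chromosome ends).
Sparsity shrinks toward log2 ratio 0, the neutral two-copy state, which is
why smoothing operates on the log scale; gain/loss calls then convert to the
ratio scale, with a probe called gained when $2^{\hat\beta} > 1.07$ and lost
when $2^{\hat\beta} < 0.93$, strict inequalities (a ratio exactly at a
threshold is neutral).

**Choosing the penalties.** The TV solution displaces each block from its
data mean by up to $\lambda_2/\ell$ where $\ell$ is the block length; blocks
flanking a true jump are therefore pulled *toward* the jump, and in samples
carrying a segmental gain this imparts a small positive offset to the
entire flanking region. If $\lambda_1$ is below that pull plus the block
noise floor ($\approx \sigma/\sqrt{\ell}$), neutral regions near real
segment boundaries retain a systematic group-specific offset large enough
for a rank test at realistic sample sizes — a false-positive mechanism that
motivates the defaults $\lambda_1 = 0.1$ (about $2\sigma/3$ for arrays with
noise SD $\sigma = 0.15$) and $\lambda_2 = 1$ (large enough to fuse
single-probe noise excursions, small enough to keep 30-probe segments).
Both are explicit arguments everywhere, and the breakpoint-recovery and
oracle tests pin down the solver's exactness independently of any choice.

## Patient stratification and survival

To evaluate a signature on an independent cohort, the signature transcripts'
expression is centered (unscaled — the inputs are already on a common log2
scale) and patients are projected onto the first 3 principal components
(`pca_scores()`), then clustered by Ward-linkage agglomerative clustering on
Euclidean distances of the scores, cut at k = 2 (`cluster_patients()`).
Linkage and distance are substitutions, not reconstructions — variance-
minimizing Ward on PC scores is the standard default, and complete linkage
is available. Cluster labels from a dendrogram are arbitrary, so clusters
are renamed deterministically: cluster 2 is the one whose mean signature
expression deviation correlates best with the metastatic direction vector
(the signature's DE effects), ties broken toward the larger cluster. This
makes downstream hazard ratios reproducible and interpretable.

Survival evaluation uses the standard engines: Kaplan–Meier with Greenwood
variance and log-rank for overall mortality; for disease-specific mortality
the Aalen–Johansen cumulative incidence and Gray's K-sample test, *not*
1 − KM of cause-specific deaths, because censoring by death from other
causes is informative; and multivariable Cox regression (Efron ties,
Newton–Raphson, Wald CIs) adjusting for age (continuous), sex, HPV status
and AJCC stage (binary codings). Efron's tie correction is the lower-bias
standard; Breslow is available and is also the setting under which the
partial likelihood's duplication-scale property holds exactly, which the
test suite exploits as an oracle.

## siRNA screen analysis

Raw luminescence readings are divided by the mean of the same cell line's
control wells (transfection reagent only), giving relative viability with
1 = control. A gene is a growth-suppression hit when its replicate-mean
viability is ≤ 0.70 in **at least one** cell line (≥ 30% suppression,
inclusive; the per-line replicate mean is used rather than requiring all
replicates below threshold). Enrichment of hits among the signature-derived
targets relative to a background set (e.g. a kinome panel) uses the
two-sided Fisher exact test in the minimum-likelihood convention: summing
hypergeometric probabilities of all tables, at fixed margins, no more
likely than the observed one. On the worked example of 18/26 signature
genes versus 149/708 background genes this gives p = 3.42e-07.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; every generator draws from its
own substream of the master seed, so a config is bit-reproducible end to
end. The reference conditions are:

* **Cohort**: 20 non-metastatic primary + 20 metastatic samples — the scale
  of a microdissected two-group array study.
* **Genome**: 4 chromosomes × 100 SNPs at 100 kb spacing. Metastasis-
  specific segments of 30 SNPs at log2 shift ±0.5 (two gains, two losses —
  a clear single-copy-scale change), one primary-specific loss and one
  shared gain for realism; additive Gaussian noise of SD 0.15, typical of
  SNP-array log ratios.
* **Transcriptome**: 1000 transcripts with baselines ~ N(7, 1); 40 drivers
  whose expression adds `driver_beta` = 1.5 × (mean true log2 copy number
  over their ±250 kb window); 40 DE-only transcripts with a pure group
  shift of 1.0; the rest null; Gaussian noise SD 0.35. Drivers are anchored
  inside group-differential segments — the only placement under which the
  full cascade can succeed by construction — while DE-only and null
  transcripts are anchored so their windows avoid differential segments,
  keeping planted truth unambiguous.
* **Survival**: cluster-specific cause hazards (defaults 0.04/0.19 per year
  for disease death in clusters 1/2, 0.03 for other death, censoring 0.05),
  latent times independent exponentials; covariates are drawn independently
  of cluster so the cluster hazard ratio is directly interpretable in
  recovery experiments (confounding can be introduced by configuring
  hazards per stratum externally).
* **Screen**: 26 signature and 708 background genes on 5 cell lines with 9
  replicates; 18 and 149 genes respectively carry a planted one-line
  suppression to viability 0.55 against 0.92 elsewhere; replicate noise is
  multiplicative lognormal at CV 0.10 (mean-one), matching luminescence
  readouts.

What the generator does **not** emulate: tumor purity and stromal
admixture, allele-specific copy number, batch and plate-position effects,
probe-level GC biases, and HPV-specific biology. Passing recovery tests
therefore shows the cascade's statistical machinery works under its own
assumptions — linear cis dosage effects, independent Gaussian noise — not
that it would recover drivers at the same rates from real arrays.

## Numerical choices and degenerate inputs

* The fused-lasso solver is exact (verified against an independent ADMM
  convex solver to 1e-6 on random instances); ties at the CNA-call
  thresholds go to neutral by the strict inequalities.
* BH selection uses strict `q < threshold`, consistent with gate semantics
  ("FDR < 5%"); for continuous p-values the boundary case has measure zero.
* Transcripts whose window contains no SNP are flagged unmapped and leave
  the cascade; constant copy-number vectors make the correlation test
  undefined and are dropped with reason `constant_cn`.
* `rlm` non-convergence is caught and reported as a drop reason rather than
  propagating an error mid-cascade.
* Cox fits flag non-convergence and monotone-likelihood separation instead
  of returning silently; `km_fit` with zero events warns and returns the
  unit curve.
* Exact Wilcoxon p-values switch to the tie/continuity-corrected normal
  approximation when ties occur or the smaller group exceeds 8.

## Problem sizes used in the validation suite

The test suite and the acceptance script rerun every experiment at sizes
chosen to make Monte-Carlo bounds tight while keeping a laptop-scale run:
10 reference cohorts and 20 null cohorts for cascade recovery, 50 null
cohorts for BH calibration, 200 random instances for the solver oracle, 200
replicates for Cox CI coverage, 50 replicates at n = 500 for hazard-ratio
recovery (true HR 4.75, the magnitude of a strong two-cluster mortality
contrast). Under the reference conditions the cascade attains precision and
recall above 0.9, null cohorts yield empty signatures, and the BH null
selection fraction stays far below its nominal 5%.

## Known limitations

* The DE screen is a robust-variance two-group model: no covariate
  adjustment, paired designs, or empirical-Bayes variance moderation.
* The cascade tests cis windows only; distal (trans) dosage effects are out
  of scope.
* Gray's test is provided for the two-group cumulative-incidence contrast;
  Fine–Gray subdistribution *regression* is not implemented.
* λ selection is fixed-default; the BIC-style grid search is deliberately
  simple and users with very different noise scales should revisit
  $\lambda_1,\lambda_2$ on their own data.
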