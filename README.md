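# cnaxpress

Integrative copy-number/expression analysis for metastatic tumor
signatures.

## What it does, and for whom

In oral squamous cell carcinoma (and solid tumors generally), some of the
expression differences between metastatic and non-metastatic tumor cells are
caused by segmental DNA copy-number abnormalities (CNAs): a gained or
deleted chromosomal segment changes the dosage of its resident genes.
`cnaxpress` is for computational biologists who want to isolate exactly
those transcripts — differentially expressed **and** dosage-coupled **and**
sitting on a region whose copy number differs between groups — and then
evaluate the resulting signature in patient cohorts and functional screens.

The core is a three-gate cascade over paired SNP-array and expression data:

1. **Differential expression** between non-metastatic primary and
   metastatic samples: per-transcript two-group linear model with
   heteroskedasticity-robust (HC0 sandwich) variance,
   $z = (\bar x_{met} - \bar x_{pri}) / \sqrt{\hat\sigma^2_1/n_1 + \hat\sigma^2_2/n_2}$,
   Benjamini–Hochberg FDR < 5%.
2. **Copy-number correlation**: SNPs within a closed ±250 kb window of each
   DE transcript are averaged from fused-lasso-smoothed log2 ratios; the
   Huber M-estimated regression of expression on copy number is gated at
   BH FDR < 1% (recomputed within the DE set).
3. **Group copy-number difference**: Wilcoxon rank-sum test of the
   transcript-level copy number between groups, BH FDR < 1% within the
   correlated set.

Copy-number profiles come from an **exact** sparse fused-lasso signal
approximator, solved per chromosome:

$$\min_\beta \tfrac12\sum_i (y_i-\beta_i)^2 + \lambda_1\sum_i|\beta_i|
  + \lambda_2\sum_{i>1}|\beta_i-\beta_{i-1}|$$

(Condat's direct total-variation algorithm + soft-thresholding), with
gain/loss calls at cancer:normal ratios > 1.07 / < 0.93. Downstream, the
package stratifies an independent cohort by PCA + Ward clustering of the
signature transcripts, evaluates the clusters against overall and
disease-specific mortality (Kaplan–Meier, log-rank, Aalen–Johansen
cumulative incidence, Gray's test, multivariable Cox with Efron ties), and
analyses siRNA viability screens (control normalization, ≥30%
any-cell-line suppression rule, two-sided Fisher enrichment). A synthetic
cohort generator with planted ground truth makes every stage testable at
desk scale. See `vignettes/cna-expression-cascade.Rmd` for the methods.

## Worked example

```r
library(cnaxpress)
report <- run_pipeline(sim_config(seed = 11), pipeline_config())
print(report)
#> Pipeline run report (seed 11)
#>   cascade:  transcripts=1000, de_tested=933, de_selected=82, mapped=82, correlated=36, signature=35
#>   signature precision 1.000, recall 0.875
#>   clusters 20/20 (agreement with truth 1.000)
#>   log-rank p 0.0172, Gray p 0.000879, cluster HR 3.01
#>   screen: 18/26 vs 149/708 hits, Fisher p 3.42e-07
```

Reading this: of 1000 simulated transcripts, 933 pass the variation/
magnitude filter, 82 are differentially expressed at FDR < 5%, 36 of those
are dosage-correlated at FDR < 1%, and 35 also show a group copy-number
difference at FDR < 1% — the signature. All 35 are planted drivers
(precision 1.000) covering 35 of the 40 planted (recall 0.875). On an
independent simulated cohort, clustering the signature expression recovers
the two latent patient groups exactly; the signature-concordant cluster has
about 3-fold higher all-cause mortality hazard, and both the log-rank and
Gray tests reject equality of the survival/cumulative-incidence curves.
The simulated screen reproduces its planted 18/26 vs 149/708 hit structure,
strongly enriched by Fisher's exact test.

Individual stages are plain functions on plain data:

```r
fused_lasso_smooth(c(0, 0.1, -0.05, 0.62, 0.55, 0.6, 0.02),
                   lam1 = 0.05, lam2 = 0.3)
#> [1] 0.0667 0.0667 0.0667 0.3400 0.3400 0.3400 0.2700

fisher_enrichment(18, 26, 149, 708)$p
#> [1] 3.420863e-07

head(report$signature[, c("transcript_id", "chrom", "de_effect",
                          "corr_slope", "wilcoxon_z", "direction")], 3)
#>   transcript_id chrom de_effect corr_slope wilcoxon_z    direction
#> 1         t0001  chr1     0.862       2.58       5.77 up_amplified
#> 2         t0003  chr1     0.689       2.10       5.77 up_amplified
#> 3         t0005  chr1     0.747       2.51       5.77 up_amplified
```

`run_pipeline(..., dir = "out")` additionally writes every stage's
tab-delimited outputs (`segmented.tsv`, `cna_calls.tsv`, `de_results.tsv`,
`integration.tsv`, `signature.tsv`, `hits.tsv`) and a `run_report.json`.

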