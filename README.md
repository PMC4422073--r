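# stromasig

Tumour stroma reacts to growth-factor signalling, and the transcriptional
response of stromal fibroblasts — for instance to bone morphogenetic
proteins (BMPs) — can carry prognostic information for the patients whose
tumours harbour that stroma. `stromasig` implements, as a tested and
reusable R pipeline, the complete analysis path that turns spot-level
two-color microarray data from stimulation experiments into a
cell-type-specific gene signature and evaluates that signature against
tumour cohorts with survival data. It is aimed at computational biologists
who want each stage of that classic analysis — quality filtering,
imputation, permutation-based differential expression, Eisen-convention
clustering, signature mapping, centroid scoring, survival stratification —
as an explicit, testable function rather than a chain of desktop tools.

Every stage can be exercised against synthetic data with planted ground
truth (`simulate_expression_study()`, `simulate_survival_cohort()`,
`simulate_spot_table()`), so the pipeline's operating characteristics
(false-call calibration, signature recall, hazard-ratio recovery) are
measurable rather than assumed.

## What is implemented

**Preprocessing** (`spot_quality_filter()`, `compute_log_ratios()`,
`presence_filter()`, `variability_filter()`, `zero_transform()`,
`time_course_normalize()`): spots are kept when the foreground mean over
background median exceeds 1.5 in at least one channel (strict) and the
within-spot pixel regression correlation exceeds 0.6 (strict); expression
is the log2 ratio of background-subtracted sample (Cy5) over reference
(Cy3) intensity; genes need measurements in at least 80% of samples
(inclusive) and a standard deviation of at least 0.7 (inclusive); responses
are zero-transformed against the mean of the mock (non-stimulated)
duplicates.

**Imputation** (`knn_impute()`): 10-nearest-neighbour estimation of missing
log ratios with inverse-distance weighting over co-observed samples.

**Significance analysis** (`run_sam()` and friends): the permutation-based
microarray significance method, written from scratch. For gene *i* the
two-class statistic is

    d_i = (mean2_i - mean1_i) / (s_i + s0)

with `s_i` the pooled standard error and `s0` the fudge factor chosen to
minimise the coefficient of variation of `d` across `s_i` windows.
Observed ordered statistics are compared with expected order statistics
averaged over label permutations (exhaustively enumerated when few, seeded
sampling otherwise; within-block permutation supported for multi-cell-line
designs), and a `delta` threshold is calibrated so the estimated false
discovery rate (permutation false positives scaled by the estimated
true-null proportion) meets the target (1%, or 0.8% for the blocked
design). Multiclass and two-class modes mirror the reference
implementation's formulas.

**Clustering** (`uncentered_pearson_distance()`, `average_linkage()`,
`cut_two_groups()`, `write_cdt()`): uncentered Pearson ("non-centered
metric") distances, deterministic UPGMA, root-cut two-group stratification,
and CDT/GTR/ATR export for tree viewers.

**Signature derivation and scoring** (`fold_change_select()`,
`cell_type_specific_set()`, `response_correlation()`, `map_signature()`,
`centroid_score()`, `median_split()`): genes induced at least 4-fold
(inclusive) in the target cell type and below 1.5-fold in every other type
form the specific signature; signatures are mapped across platforms by
averaging probes within a Unigene cluster and requiring more than 80% data
values; the centroid score is each sample's mean expression over the
signature, split at the cohort median.

**Survival** (`make_endpoint()`, `kaplan_meier()`, `cox_univariate()`,
`stratified_analysis()`): hand-written product-limit estimator and
univariate Cox proportional-hazards fit (Newton–Raphson on the partial
likelihood, Efron tie handling, Wald/score/likelihood-ratio p-values, both
reference codings reported), for overall and disease-specific endpoints.

Results are tibbles throughout; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Derive a fibroblast-specific signature from a synthetic three-cell-type
stimulation study, then stratify a simulated tumour cohort:

```r
library(stromasig)

cfg   <- sim_config(seed = 7)                    # 2000 genes, 3 cell types,
study <- simulate_expression_study(cfg)          # duplicate mock/BMP2 samples
res   <- run_derive_signature(study$expr, study$samples, seed = 7)

glance(res$sam)
#> # A tibble: 1 x 11
#>   mode              n_genes    s0 delta   pi0   fdr target_fdr n_significant_up
#>   <chr>               <int> <dbl> <dbl> <dbl> <dbl>      <dbl>            <int>
#> 1 two_class_blocked     136 0.700     0     0     0      0.008               69

nrow(res$signature)                              # 85 genes in the derived set
mean(study$truth$specific_gene_ids %in% res$signature$gene_id)
#> [1] 0.85                                       # recall of the planted truth

cohort <- simulate_survival_cohort(
  sim_config(n_genes = 60, cohort_n = 400, beta = log(2),
             missing_rate = 0, seed = 7),
  signature_genes = sprintf("G%05d", 1:40))
stratified_analysis(
  cohort$expr[cohort$expr$gene_id %in% sprintf("G%05d", 1:40), ],
  cohort$clinical, method = "median_score")
#> Stratified survival analysis (median_score)
#> # A tibble: 6 x 3
#>   group horizon survival
#>   <chr>   <dbl>    <dbl>
#> 1 low        12   0.762
#> 2 low        24   0.636
#> 3 low        60   0.335
#> 4 high       12   0.565
#> 5 high       24   0.411
#> 6 high       60   0.0700
#> Univariate Cox fit (efron ties)
#>   group: high vs low (reference)
#>   HR 2.074 (log HR 0.730, SE 0.121), Wald p = 1.623e-09, n = 400, events = 294
#>   swapped reference: HR 0.482
```

The high-centroid group carries roughly twice the hazard of the low group
(the cohort was simulated with a true hazard ratio of 2), and its survival
curve sits below the low group's at every horizon. The blocked
significance analysis recovers the planted common-response genes, and the
4-fold specificity rule assembles the target-cell-type signature without
admitting any planted shared-response gene.

A thin command-line wrapper over the same functions ships at
`inst/scripts/stromasig-pipeline.R` with `simulate`, `derive-signature`
and `validate-signature` subcommands.

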