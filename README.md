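# retinaprog

Transcriptome analysis of staged retinal disease, built around a
stage-position-learning sparse regression model of disease progression.

Diabetic retinopathy (DR) progresses through clinically graded stages —
diabetic without retinopathy, non-proliferative DR (NPDR), NPDR with
macular edema (DME), proliferative DR — yet bulk differential expression
against healthy controls typically finds significant changes only in the
late stages. `retinaprog` is for computational biologists analysing such
staged cohorts (bulk mRNA + miRNA from multiple retinal sample sites,
optionally with a single-cell reference). It provides, as a tested R
package:

* preprocessing: log2 CPM normalization, two-stage expressed-transcript
  filters, technical-replicate detection (Pearson r > 0.98),
  surrogate-variable estimation and residuals-plus-intercept confounder
  correction;
* moderated group-vs-healthy differential expression with BH control and
  fold-change flagging;
* **disease-progression modelling** (the core): transcripts predictive of
  disease stage, found by sparse partial least squares on a numeric stage
  target whose intermediate positions are free parameters;
* gene-set statistics: hypergeometric over-representation with
  min-overlap and category-exclusion rules, and a calibrated
  bidirectional fold-change-distribution test;
* miRNA integration: target over-representation, a Kolmogorov–Smirnov
  test for negative correlation skew between miRNA and their targets, and
  a triple-evidence filter;
* single-cell integration: unique marker detection, marker
  over-representation, and weighted iterative NNLS cell-type
  deconvolution;
* a synthetic cohort generator (`simulate_study()`) that plants every
  structure the pipeline is designed to detect, so the whole analysis is
  validated end-to-end without patient data.

## The model

Disease groups are mapped to stage positions: Healthy → 0, NPDR+DME → 3,
and the intermediates to free parameters
d_Diabetic, d_NPDR ∈ [0.1, 2.9] (no ordering imposed; the few PDR
samples are excluded). For a candidate encoding, features are ranked by
|Spearman ρ| with the stage target and the top *n* enter a sparse PLS
fit: per component the cross-covariance z = Xᵀy is soft-thresholded at
η·max|z|, the active set accumulates the nonzero supports, ordinary PLS
is refit on the active set, and the response is deflated. The five
hyperparameters (d_Diabetic, d_NPDR, n ≥ 50, η ∈ [0.1, 0.9],
K ∈ {1,…,12}; κ fixed at 0.5) are chosen by scatter search minimizing
the RMSE of repeated stratified cross-validation (desk scale 5×5 folds /
300 evaluations; full scale 5×20 / 1,000). The selected features of the
refit at the optimum are the disease-progression (DP) transcripts, and
the fitted intermediate positions are a data-driven readout of relative
disease severity.

See `vignettes/retinaprog-methods.Rmd` for the statistical details and
design rationale of every stage.

## Worked example

Simulate the desk-scale progression cohort (1,000 transcripts, 80
samples, stage positions 0 / 0.8 / 1.8 / 3, 5% planted progression
transcripts), preprocess it, and fit the progression model:

```r
library(retinaprog)

study <- simulate_study(progression_demo_config(seed = 42))
study
#> <retina_study>
#>   mRNA:  1000 transcripts x 80 samples
#>   miRNA: 0 transcripts
#>   single-cell reference: 1000 genes x 1600 cells (10 types)
#>   planted progression transcripts: 50

prep <- preprocess_study(study)
dp <- find_dp_transcripts(prep$norm_mrna, prep$metadata, site = "macula",
                          cvspec = cv_spec(5, 5, seed = 42),
                          optconfig = scatter_search_config(300, seed = 42))
dp
#> <dp_result> site macula: 39 DP transcripts (CV RMSE 0.2685;
#>             d_Diabetic 0.80, d_NPDR 1.72, n 765, eta 0.86, K 1)
```

The fitted intermediate positions land at 0.80 and 1.72 against true
values 0.8 and 1.8 — the model recovers both the clinical ordering
(diabetic milder than NPDR) and the approximate spacing from expression
data alone. Of the 39 selected transcripts, all 39 are planted
progression transcripts (recall 39/50 on the macula samples alone):

```r
truth <- intersect(study$truth$dp_transcripts, rownames(prep$norm_mrna))
length(intersect(dp$dp_transcripts, truth))
#> [1] 39
head(tidy(dp), 3)
#> # A tibble: 3 × 2
#>   term      estimate
#> 1 gene00687  -0.0437
#> 2 gene00637   0.0434
#> 3 gene00549   0.0430
```

`autoplot(dp)` draws the optimization trace (RMSE, stage positions and
model size per improvement). On the full default cohort
(`simulation_config()`: ~4,000 mRNA, 250 miRNA, two sites, replicate
pairs, confounder, miRNA–target coupling, declining ganglion-cell
fraction), the downstream stages pick up their planted structures, e.g.
deconvolution of the bulk samples against the simulated single-cell
reference recovers the retinal ganglion cell (RGC) decline:

```r
study <- simulate_study(simulation_config(seed = 42))
prep  <- preprocess_study(study)
dec   <- deconvolve(prep$norm_mrna, study$sc_ref)
grp   <- prep$metadata$group[match(rownames(dec$proportions), prep$metadata$sample_id)]
round(tapply(dec$proportions[, "RGC"], grp, mean)[c("Healthy","Diabetic","NPDR","NPDR_DME")], 3)
#>  Healthy Diabetic     NPDR NPDR_DME
#>    0.086    0.069    0.045    0.018
```

`run_pipeline(config)` chains every stage (preprocess → DE → progression
→ enrichment → miRNA evidence → cell types) into one seeded, reproducible
report.

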