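# glycoscore

Tumours that lean on aerobic glycolysis (the Warburg effect) build an
acidic, immunosuppressed microenvironment and respond poorly to immune
checkpoint inhibitors (ICIs). `glycoscore` is an R package for analysts
who want to quantify that link and exploit it: it derives a glycolytic
gene signature from single-cell data, scores it per sample, relates it to
immune features, predicts ICI response from bulk cohorts, and ranks
immune-resistance genes from CRISPR screens — each stage testable on
synthetic data with recorded ground truth.

## What it computes

**Signature derivation.** Within each single-cell dataset, cells are
scored for glycolysis intensity with a rank-based single-sample
enrichment statistic (ssGSEA, weight α = 0.25). Two gene sets are formed:

- *Gx* — genes positively correlated with the glycolysis score across
  malignant cells (Spearman *R* > 0, BH FDR < 1e−5, strict);
- *Gy* — genes overexpressed in malignant cells (two-sided Wilcoxon FDR
  < 0.05, log-scale fold change > 0.25);

and intersected into *Gn*. Across datasets, each gene's per-dataset
*R* values (taken where the gene entered Gn) are combined by geometric
mean, and the signature keeps genes with

&nbsp;&nbsp;&nbsp;&nbsp;(∏ᵢ Rᵢ)^(1/k) > 0.3  (strict), with a configurable dataset-support floor.

**Response modelling.** Bulk ICI cohorts are merged and batch-adjusted
with a parametric empirical-Bayes location/scale model (ComBat family),
split 80/20 stratified by response (round-half-up: 772 samples → 618
train / 154 validation), and seven classifier families — kernel naive
Bayes, k-NN, random forest, SVM, boosted logit and boosted trees
stand-ins, and a parameter-free correlation nearest-centroid — are tuned
by repeated stratified 5-fold CV and selected by validation-set AUC
(tie-corrected Mann–Whitney statistic, DeLong CI). Predicted
non-responders are contrasted with responders by Efron-ties Cox
regression and Kaplan–Meier medians.

**CRISPR ranking.** Guide-level log-fold changes are averaged per gene,
z-scored within each screen, averaged across screens (missing pairs
skipped), and ranked ascending — the most negative mean Z is the
strongest immune-resistance candidate. Top-k cuts use floor(frac·N)
(22,505 genes → 1,125 / 2,250 / 4,501 at 5/10/20%), and signature
enrichment among top-ranked genes is a one-sided Fisher exact test.

## Worked example

Derive a signature from one simulated single-cell dataset, then train and
evaluate a response model on simulated cohorts:

```r
library(glycoscore)

planted <- sprintf("G%04d", 31:80)
sim <- simulate_sc_dataset(
  n_genes = 1000, n_cells = 800,
  truth = sc_sim_truth(gene_set("PLANTED", planted), malignant_logfc = 1,
                       corr_strength = 1, seed = 1)
)
ds <- derive_dataset_sets("D1", log_normalize(sim$expr),
                          sim$annotations, sim$glyc_set)
ds
#> <dataset_gene_sets> D1: |Gx| = 80, |Gy| = 47, |Gn| = 47
agg <- aggregate_signature(list(ds))
glance(agg)
#> # A tibble: 1 × 3
#>   n_candidates n_signature max_geo_mean_r
#>          <int>       <int>          <dbl>
#> 1           47          47          0.555
mean(planted %in% agg$signature$genes)
#> [1] 0.94
```

47 of the 50 planted program genes survive both filters and the 0.3
geometric-mean cut in a single dataset (recall 0.94, no false
positives); with five datasets recall reaches 1.0.

```r
sig <- gene_set("SIG", sprintf("G%04d", 1:50))
cohorts <- simulate_ici_cohorts(
  n_cohorts = 3, n_per_cohort = 80, signature = sig,
  truth = cohort_sim_truth(signature_effect = 1.5, seed = 2), n_genes = 300
)
mg <- merge_cohorts(cohorts$expr)
adj <- combat_adjust(mg$expr, mg$batch)$adjusted
model <- train_select(adj, cohorts$clinical, sig,
                      algorithms = c("nb", "rf", "cancerclass"),
                      cv_repeats = 2, seed = 3, test_cohorts = "C03")
tidy(model)
#> # A tibble: 3 × 3
#>   algorithm   cv_auc validation_auc
#>   <chr>        <dbl>          <dbl>
#> 1 nb               1          1
#> 2 rf               1          1
#> 3 cancerclass     NA          0.570

pred <- predict_response(model, expr_matrix(unclass(adj)[, model$split$test_ids],
                                            layer = "adjusted"))
test_clin <- dplyr::filter(cohorts$clinical, cohort == "C03")
roc_auc(pred$score[match(test_clin$sample_id, pred$sample_id)],
        test_clin$response)
#> <glyc_roc> AUC 1.000 (95% CI 1.000-1.000), 40 NR / 40 R
survival_compare(test_clin, pred)
#> <glyc_survcmp> HR(NR vs R) 2.26 (95% CI 1.32-3.87), p = 0.00302
```

The planted effect (signature genes shifted by 1.5 in non-responders) is
large relative to noise, so the held-out cohort separates perfectly
(AUC 1.0), and predicted non-responders show roughly the simulated
two-fold hazard (HR 2.26). Result objects have `tidy()`/`glance()`
methods and `autoplot()` views (ROC curve, Kaplan–Meier curves,
signature aggregation scatter); `plot_crispr_ranking()` draws the screen
ranking waterfall.

The methods vignette
(`vignettes/glycolysis-signature-methods.Rmd`) documents the models,
conventions, synthetic-data design, and limitations.

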