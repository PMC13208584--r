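# msieval

Ion filtering and dual-metric evaluation of spatial clustering for mass
spectrometry imaging (MSI).

## What problem this solves, and for whom

MSI produces, for every pixel of a tissue section, the intensities of
hundreds to thousands of ions — one spatial "ion image" per m/z feature.
Clustering those pixels into metabolically distinct regions is a core step of
spatial metabolomics, but it is haunted by two opposite failure modes:
spatially random noise ions fragment cluster maps into salt-and-pepper
patterns, while aggressive spatial smoothing yields contiguous regions with
little metabolic distinction. `msieval` is for analysts and method developers
who need to (a) quality-filter an ion panel before clustering and (b) judge
and rank clustering results on both axes at once.

## The statistics at its core

* **SNS (Spatial Noise Score)**, per ion: binarize the ion image at its
  median (strictly-greater rule), then score the fraction of pixels whose
  binary value disagrees with a strict majority of their existing
  8-neighbors. Coherent ions score ≈ 0; i.i.d. noise ions score near the
  random-image expectation (≈ 0.37 on a large full grid). Gradient filtering
  keeps the top `p` fraction of ions by ascending SNS
  (5–100% sweep: `sns_fractions`).
* **PAS (Percentage of Abnormal Spots)**, per clustering: the same
  strict-majority disagreement rule applied to cluster labels —
  the fraction of pixels inconsistent with more than half of their existing
  8-neighbors. Low PAS = spatially continuous clustering.
* **median-η²**, per clustering: for each ion the one-way ANOVA variance
  decomposition η² = SS_between / SS_total under the cluster labels; the
  median over evaluable ions summarizes inter-cluster metabolic
  heterogeneity (zero-variance ions are excluded and counted).
* **Dual-metric rule**: a method passes iff `PAS < 0.2` and
  `median-η² > 0.5` (strict); the composite rank is the mean of the PAS rank
  (ascending) and median-η² rank (descending).
* Supporting metrics: **NMI** (arithmetic-mean normalization) for
  method–method consistency and validation against external annotations,
  and median one-vs-rest **Moran's I** (binary 8-neighbor weights) as a
  spatial-autocorrelation cross-check on PAS.

A synthetic phantom generator (`generate_phantom()`) plants contiguous
regions, region-structured informative ions and spatially random noise ions
under multiplicative lognormal noise, providing ground truth for every part
of the workflow.

## Worked example

```r
library(msieval)

# A 40x40 phantom: 4 banded regions, 30 informative + 10 noise ions
ph <- generate_phantom(phantom_spec(seed = 1))
ph$dataset
#> <msi_dataset> 1600 pixels x 40 ions; grid 40 x 40 (100% occupied)
#> ions: sig_001, sig_002, sig_003, sig_004, sig_005, sig_006, ...

run <- run_pipeline(
  ph$dataset,
  methods = c("pca_kmeans", "pca_gmm", "pca_hclust"), k = 4,
  filter_fraction = 0.8, reference = ph$truth, morans_i = TRUE, seed = 1
)
run
#> <msi_run> 3 method(s) on 1600 pixels; 32/40 ions retained (fraction 0.80)
#> # A tibble: 3 x 6
#>   method       pas median_eta2 pass_pas pass_eta2 pass_both
#>   <chr>      <dbl>       <dbl> <lgl>    <lgl>     <lgl>
#> 1 pca_kmeans     0       0.777 TRUE     TRUE      TRUE
#> 2 pca_gmm        0       0.777 TRUE     TRUE      TRUE
#> 3 pca_hclust     0       0.777 TRUE     TRUE      TRUE
```

All three baselines recover the planted regions exactly: PAS 0 (no pixel
disagrees with a majority of its neighbors), median-η² 0.777 (for the typical
ion, 78% of spatial variance is between clusters — well above the 0.5
threshold), NMI vs the planted truth 1, and median Moran's I 0.923 (compact,
spatially autocorrelated clusters). All pass the dual-metric rule.

Filtering matters on noisier data. On a phantom with 80% noise ions and weak
signal, PCA + k-means fragments without filtering and recovers with it:

```r
noisy <- generate_phantom(phantom_spec(
  n_rows = 32, n_cols = 32, k_regions = 4,
  n_informative_ions = 10, n_noise_ions = 40,
  effect_size = 1, noise_sd = 0.5, seed = 1
))
sweep_report(noisy$dataset, methods = "pca_kmeans", k = 4,
             fractions = c(0.2, 1.0), seed = 1)
#> # A tibble: 2 x 6
#>   method     fraction n_ions    pas median_eta2 runtime_s
#>   <chr>         <dbl>  <int>  <dbl>       <dbl>     <dbl>
#> 1 pca_kmeans      0.2     10 0.0547     0.357      0.0120
#> 2 pca_kmeans      1       50 0.0645     0.00449    0.0270
```

Retaining the top 20% of ions by SNS lowers PAS and raises median-η² by two
orders of magnitude (the unfiltered median is dominated by the 40 noise
ions, whose η² is near zero).

Other entry points: `sns_score()`, `filter_top_fraction()`,
`evaluate_clustering()` (with broom-style `glance()`/`tidy()`),
`evaluate_dual()`, `composite_ranking()`, `pass_rate_summary()`,
`threshold_sensitivity()`, `external_validation()`, `pairwise_nmi()`,
`register_adapter()` for external methods, and `plot_ion_image()` /
`plot_cluster_map()` / `plot_sweep()` / `autoplot()` for figures. A thin
command-line front end with `simulate`, `sns`, `filter`, `cluster`,
`evaluate`, `rank`, `sweep` and `pipeline` subcommands ships at
`system.file("cli", "msieval.R", package = "msieval")`.

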