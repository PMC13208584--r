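---
title: "Evaluating MSI clustering with msieval: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating MSI clustering with msieval: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msieval)
```

## The problem

Mass spectrometry imaging (MSI) measures, at every pixel of a tissue section,
the intensities of hundreds to thousands of ions, yielding one spatial "ion
image" per m/z feature. Pixel clustering is the standard route to delineating
metabolically distinct tissue regions, but two failure modes are endemic:

* **Salt-and-pepper fragmentation.** Many ions carry no anatomical signal —
  matrix interference and stochastic detection noise produce spatially random
  images. These noisy ions dominate distance computations and fragment the
  cluster map into isolated mislabeled pixels.
* **Over-smoothing.** Conversely, methods that enforce spatial continuity too
  aggressively can produce beautiful, contiguous regions that barely differ
  in their metabolite content.

`msieval` implements an evaluation workflow addressing both: a per-ion
**Spatial Noise Score (SNS)** for quality filtering before clustering, and a
**dual-metric framework** — spatial continuity via the Percentage of Abnormal
Spots (PAS) and inter-cluster metabolic heterogeneity via the median of
per-ion eta-squared values — for judging clustering results afterwards,
complemented by normalized mutual information (NMI) for consistency and
external validation and by one-vs-rest Moran's I as a cross-check on spatial
continuity.

## Data model

Input is a pixel-by-ion intensity matrix: first two columns are the X and Y
pixel coordinates (instrument units; typical MSI pitches are 20–100 µm), the
remaining columns one ion each, headers kept verbatim as ion identifiers.
All spatial logic runs on an inferred integer grid: the pitch per axis is the
minimum positive difference among sorted unique coordinates, each coordinate
snaps to `round((coord - min)/pitch)`, and any coordinate farther than 10% of
the pitch from its grid position is an error rather than a silent distortion.
The 10% snap tolerance is this package's choice; it accepts the jitter seen
in exported coordinate tables while refusing genuinely irregular sampling.

Tissue masks are implicit. MSI matrices are typically background-removed, so
absent pixels simply do not appear; every neighborhood computation uses the
neighbors that actually exist. A pixel has 0–8 neighbors — the existing
pixels whose grid position differs by at most one in each axis.

## Spatial Noise Score

For one ion, the image is binarized at its median intensity — a pixel is 1
only if **strictly** greater than the median, so values equal to the median
(including the zeros of zero-inflated ions, and the whole of a constant
image) map to 0. This tie rule is deterministic and keeps heavily
zero-inflated ions well-defined. The SNS is then the fraction of *abnormal*
pixels: those whose binary value differs from the values of strictly more
than half of their existing neighbors. Pixels without neighbors are never
abnormal.

The abnormality rule is deliberately identical to the one inside PAS (below):
both quantify the same notion of local spatial inconsistency, once on a
binarized ion image and once on a cluster labeling. Two reference points
anchor the scale: any spatially coherent binarization (constant image,
half-plane) has SNS exactly 0, while an i.i.d. continuous image has expected
SNS equal to the neighbor-class mixture of strict-majority binomial tails,
`P(Binomial(m, 1/2) > m/2)` for `m` existing neighbors — about 0.374 on a
full 50×50 grid. Real structured ions sit near 0; shuffling a structured
ion's pixels pushes its SNS to the random-image level, which is the basis of
several tests.

Gradient filtering ranks ions by ascending SNS (ties keep column order) and
retains the top fraction `p`, with `max(1, ceiling(p * n_ions))` ions kept so
the result is never empty. The canonical sweep is 5%, 10%, 20%, 40%, 60%,
80%, 100%. Because the appropriate retention level is dataset-specific —
too-stringent filtering removes informative ions — `select_filter_fraction()`
implements the pragmatic heuristic of picking the sweep fraction minimizing
the mean PAS of a designated baseline; it is a suggestion, not an automatic
step.

## The evaluation metrics

**PAS.** The fraction of pixels whose cluster label disagrees with strictly
more than half of their existing 8-neighbors. Border and masked-edge pixels
are judged against the neighbors they have, not a fixed denominator of 8,
which would count every tissue-boundary pixel as half-abnormal by
construction. PAS is invariant to relabeling, 0 for constant labelings,
half-planes and straight band boundaries, and 1 for single-row stripes. A
checkerboard of 2×2 blocks scores 0: every pixel disagrees with at most half
of its neighbors, and exactly-half disagreement is not abnormal under the
strict-majority rule.

**Per-ion eta-squared and median-eta².** For each ion, the one-way ANOVA
variance decomposition `eta² = SS_between / SS_total` under the cluster
labels: the fraction of the ion's spatial intensity variance explained by the
clustering. Ions with zero total variance have undefined eta² and are
*excluded and counted* (`n_excluded_ions`) rather than scored 0, which would
bias the median on sparse panels. The summary score is the standard median
over evaluable ions; a median-eta² above 0.5 means that for a typical ion,
more than half of the spatial variance is between clusters. eta² is invariant
under per-ion affine transforms, so it does not depend on intensity units.
It is computed on whatever matrix is passed in — if you evaluate on a
filtered matrix, the report reflects the filtered ion panel, and the pipeline
records which panel was used.

**NMI.** `I(A;B) / ((H(A)+H(B))/2)` from the joint contingency table with
natural logarithms — the arithmetic-mean normalization, the most common
symmetric, bounded variant. Degenerate conventions: two single-cluster
partitions are identical (NMI 1); if exactly one partition is single-cluster
the NMI is 0.

**Moran's I.** For each cluster, the spatial autocorrelation of its binary
one-vs-rest membership map with non-row-standardized binary 8-neighbor
weights; clusters whose indicator is constant are skipped; the summary is
the median over clusters. Under random labeling the expectation is
`-1/(n-1)`; compact clusters approach 1. It serves as an independent
cross-check on PAS — across graded corruptions of a good labeling the two
move in opposite directions.

## The dual-metric framework

A method passes when `PAS < 0.2` **and** `median-eta² > 0.5`, both strict, as
the thresholds are phrased as strict inequalities. These are empirical
defaults for converting the two continuous metrics into pass/fail outcomes;
changing them never changes the metric values or the ordering of methods,
only the binary summary, and `threshold_sensitivity()` reports pass counts
under nested strict/default/relaxed settings (defaults 0.15/0.55, 0.20/0.50,
0.25/0.45 — the exact strict/relaxed values are this package's choice, with
nesting enforced so pass sets can only grow).

The composite score ranks methods jointly: the mean of the PAS rank
(ascending) and the median-eta² rank (descending), average ranks on ties,
exact ties broken alphabetically. A rank-based score is invariant to
monotone transforms of either metric and does not require the two metrics to
share a scale; since no closed-form composite is canonical, a normalized-score
mean is available via `composite_ranking(score = "norm_mean")`. External
validation correlates this composite ranking with the NMI-vs-reference
ranking by Spearman's rho (average ranks on ties).

Methods that crash on a dataset are recorded as non-passing with the error
message retained; the batch continues.

## Clustering baselines

Built-in adapters cover the classic non-spatial two-stage pipeline:
`log1p` transform, per-ion z-score (zero-variance ions dropped), PCA to
`n_components` dimensions (default 20, capped at the data's rank), then
k-means (10 restarts), a Gaussian mixture (mclust, `G = k`), or Ward
agglomeration. The preprocessing is fixed and recorded in the result object
so runs are comparable; all adapters are deterministic given the seed and
never modify their input. t-SNE/UMAP front ends are deliberately omitted —
they add heavy dependencies without exercising any new evaluation logic.
External methods plug in through `register_adapter()` (a function returning
one label per pixel) or by writing labels CSVs validated against the
dataset's pixel set.

## The phantom generator

`generate_phantom()` emulates the post-peak-picking structure of
background-removed MSI data, not the spectral domain (no peak shapes, m/z
axis, or isotopes):

* a rectangular pixel grid partitioned into `k_regions` contiguous regions —
  `"blocks"` (equal horizontal bands) or `"voronoi"` (nearest-center cells).
  Bands have straight boundaries along which no pixel disagrees with a
  majority of its neighbors, so the ground truth has PAS exactly 0; a 2-D
  tiling would place a handful of abnormal pixels at tile junctions, which
  is why bands were chosen for the "clean geometry" layout. Voronoi cells
  supply irregular boundaries to stress edge handling.
* **informative ions**: ion `j` draws per-region log-means standardized to
  spread `effect_size * noise_sd`; each pixel's intensity is
  `exp(meanlog[region] + N(0, noise_sd))` — the region mean times
  multiplicative lognormal noise. The effect size is defined on the log
  scale, the natural scale for a lognormal model of nonnegative,
  right-skewed MSI intensities.
* **noise ions**: i.i.d. lognormal with `sdlog = noise_sd * sqrt(1 +
  effect_size²)`, matching the informative ions' marginal log-variance so
  the two groups differ only in spatial organization; at `effect_size = 0`
  they are distributionally identical.
* an optional tissue mask removing the `mask_fraction` of pixels farthest
  from the grid centre (an elliptical, tissue-like outline). A deterministic
  mask keeps planted regions 4-connected in practice; connectivity is
  verified after masking and generation is retried (voronoi re-draws
  centres) up to 10 times before erroring.

Defaults — 40×40 grid, 4 regions, 30 informative + 10 noise ions,
`effect_size = 3`, `noise_sd = 0.3` — represent a moderately quality-filtered
panel with clear regional chemistry: the ground-truth labeling passes the
dual-metric defaults. Experiments on noise-limited data use an explicitly
noisy construction: 80% noise ions with `effect_size = 1`, `noise_sd = 0.5`,
the regime in which PCA + k-means becomes fragmented without filtering and
recovers after top-20% SNS retention. Degradation tools complete the test
substrate: `add_label_noise()` flips an exact count of pixels to uniformly
random different labels, and `shuffle_ion()` permutes one ion's pixels while
preserving its histogram.

What the phantom does **not** emulate: correlated noise between ions, spatial
intensity gradients within a region, pixel-level dropout, platform-specific
matrix effects, or the sheer dimensionality of real panels (thousands of
ions). Passing tests on phantoms therefore demonstrates the correctness and
qualitative behavior of the metrics and workflow, not performance claims
about any particular real dataset.

## Numerical and degenerate-input choices

* Binarization ties go to 0; a constant ion image has SNS 0.
* Pixels with no neighbors are never abnormal in SNS or PAS.
* eta² is clamped to [0, 1] against floating-point overshoot; zero-variance
  ions are excluded, and an all-zero-variance matrix is an error.
* NMI is clamped to [0, 1]; degenerate entropies follow the conventions
  above.
* Moran's I skips size-0/size-n clusters and errors only if every cluster is
  degenerate; singleton clusters are legal everywhere.
* Retention counts use `ceiling` with a floor of one ion.
* Wall-clock runtime is recorded around each adapter call; peak-RSS sampling
  is platform-dependent and intentionally not implemented.

## Problem sizes used by the test suite

Tests generate all data programmatically: oracle comparisons run on 8×8–12×12
grids (1,000 random labelings for PAS, 100 dataset/labeling pairs for eta²,
200 partition pairs for NMI), distributional checks on 20×20–50×50 grids
(200 i.i.d. images for SNS, 100 random labelings for the Moran null), and the
filtering phenomenon on 32×32 phantoms with 50 ions over 20 seeds. These
sizes give stable Monte-Carlo estimates at the stated tolerances while
keeping the whole suite under a minute of compute.

## Limitations

* The composite score's exact form (mean of ranks) is a design choice; any
  monotone-consistent alternative yields the same top/bottom structure on
  clearly separated methods but can reorder near-ties.
* SNS assumes the median split is meaningful; ions detected in fewer than
  half the pixels binarize to their detection mask, which is usually — but
  not always — the spatially relevant pattern.
* PAS and SNS are defined on grids; profile-mode or heavily irregular
  acquisitions must be regularized upstream.
* The built-in baselines are references for the evaluation machinery, not a
  benchmark of state-of-the-art clustering.
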