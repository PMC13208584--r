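#' Median binarization of one ion image
#'
#' A pixel becomes 1 when its intensity is strictly greater than the median
#' intensity of that ion over all pixels, else 0. Values equal to the median
#' binarize to 0, so a constant image is all zeros — a deterministic rule that
#' behaves well on heavily zero-inflated ion images.
#'
#' @param intensities Numeric vector of one ion's per-pixel intensities.
#' @return Integer vector of 0/1, same length.
#' @export
binarize_ion <- function(intensities) {
  as.integer(intensities > median(intensities))
}

#' Spatial Noise Score of one ion image
#'
#' The SNS of an ion quantifies how spatially dispersed its image is. The
#' image is first binarized at its median ([binarize_ion()]); the SNS is then
#' the proportion of abnormal boundary pixels — pixels whose binary label
#' differs from the labels of strictly more than half of their existing
#' 8-neighbors. Pixels with no neighbors are never abnormal. A low SNS means
#' a spatially coherent ion likely to reflect genuine anatomical structure;
#' i.i.d. noise ions score near the random-image expectation (about 0.37 on a
#' large full grid).
#'
#' @param dataset An `msi_dataset`.
#' @param ion Ion column index or ion id string.
#' @return SNS value in \[0, 1\].
#' @export
compute_sns <- function(dataset, ion) {
  stopifnot(inherits(dataset, "msi_dataset"))
  j <- resolve_ion(dataset, ion)
  b <- binarize_ion(dataset$intensities[, j])
  d <- disagreement_counts(dataset, b)
  mean(d$n_diff * 2L > d$n_nb & d$n_nb > 0L)
}

#' Score every ion's Spatial Noise Score
#'
#' Computes the SNS of each ion independently and ranks ions from low (most
#' spatially coherent) to high SNS; ties keep the original column order.
#'
#' @param dataset An `msi_dataset`.
#' @return A tibble with one row per ion, in original column order:
#'   `ion_id`, `ion_index`, `sns`, and `rank` (1 = lowest SNS).
#' @examples
#' ph <- generate_phantom(phantom_spec(n_rows = 12, n_cols = 12, seed = 1))
#' sns_score(ph$dataset)
#' @export
sns_score <- function(dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  pr <- neighbor_pairs(dataset)
  n <- n_pixels(dataset)
  n_nb <- tabulate(pr[, 1L], nbins = n)
  sns <- vapply(seq_len(n_ions(dataset)), function(j) {
    b <- binarize_ion(dataset$intensities[, j])
    n_diff <- tabulate(pr[, 1L][b[pr[, 1L]] != b[pr[, 2L]]], nbins = n)
    mean(n_diff * 2L > n_nb & n_nb > 0L)
  }, numeric(1))
  ord <- order(sns, seq_along(sns))
  rank <- integer(length(sns))
  rank[ord] <- seq_along(sns)
  tibble(
    ion_id = dataset$ion_ids,
    ion_index = seq_along(sns),
    sns = sns,
    rank = rank
  )
}

#' Retain the top fraction of ions by ascending SNS
#'
#' Keeps the `max(1, ceiling(p * n_ions))` lowest-SNS ions (the spatially most
#' coherent ones) and drops the rest. The pixel set is unchanged and the
#' retained ions keep their original column order. The canonical gradient
#' sweep retains 5%, 10%, 20%, 40%, 60%, 80% and 100% of ions
#' (see [sns_fractions]).
#'
#' @param dataset An `msi_dataset`.
#' @param quality Per-ion quality table from [sns_score()]; computed on the
#'   fly when `NULL`.
#' @param p Fraction of ions to retain, in (0, 1\].
#' @return A filtered `msi_dataset`.
#' @export
filter_top_fraction <- function(dataset, quality = NULL, p) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p > 1) {
    abort("`p` must be a single fraction in (0, 1]")
  }
  if (is.null(quality)) quality <- sns_score(dataset)
  stopifnot(nrow(quality) == n_ions(dataset))
  n_keep <- max(1L, as.integer(ceiling(p * n_ions(dataset))))
  keep_idx <- sort(quality$ion_index[quality$rank <= n_keep])
  subset_ions(dataset, keep_idx)
}

subset_ions <- function(dataset, idx) {
  structure(
    list(
      coords = dataset$coords,
      intensities = dataset$intensities[, idx, drop = FALSE],
      ion_ids = dataset$ion_ids[idx]
    ),
    class = "msi_dataset"
  )
}

#' The canonical SNS retention sweep fractions
#'
#' Retention fractions used by the gradient filtering strategy:
#' top 5%, 10%, 20%, 40%, 60%, 80%, and 100% of ions by ascending SNS.
#' @export
sns_fractions <- c(0.05, 0.10, 0.20, 0.40, 0.60, 0.80, 1.00)

#' Pick a filtering fraction by minimizing baseline PAS
#'
#' Helper that sweeps the retention fractions, runs a designated baseline
#' clustering at each, and returns the fraction whose mean PAS (over seeds)
#' is smallest. Datasets differ in noise structure, so the appropriate
#' retention level is dataset-specific; this encodes the common heuristic of
#' choosing the level where the baseline's spatial fragmentation bottoms out.
#' It is a suggestion tool, not an automatic step.
#'
#' @param dataset An `msi_dataset`.
#' @param method Baseline method name (see [cluster_methods()]).
#' @param k Cluster count for the baseline.
#' @param fractions Candidate fractions (default [sns_fractions]).
#' @param seeds Seeds to average PAS over.
#' @return A list with `fraction` (the pick) and `sweep` (tibble of
#'   `fraction`, `mean_pas`).
#' @export
select_filter_fraction <- function(dataset, method = "pca_kmeans", k = 4,
                                   fractions = sns_fractions, seeds = 1:3) {
  quality <- sns_score(dataset)
  sweep <- purrr::map_dfr(fractions, function(p) {
    filtered <- filter_top_fraction(dataset, quality, p)
    pas <- vapply(seeds, function(s) {
      cl <- run_baseline(filtered, method = method, k = k, seed = s)
      compute_pas(cl$labels, filtered)
    }, numeric(1))
    tibble(fraction = p, mean_pas = mean(pas))
  })
  list(fraction = sweep$fraction[which.min(sweep$mean_pas)], sweep = sweep)
}

resolve_ion <- function(dataset, ion) {
  if (is.character(ion)) {
    j <- match(ion, dataset$ion_ids)
    if (is.na(j)) abort(sprintf("unknown ion id '%s'", ion))
    return(j)
  }
  if (!is.numeric(ion) || length(ion) != 1 || ion < 1 || ion > n_ions(dataset)) {
    abort("invalid ion index")
  }
  as.integer(ion)
}
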