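#' Percentage of Abnormal Spots (PAS)
#'
#' PAS measures the spatial continuity of a pixel clustering: the proportion
#' of pixels whose cluster label is inconsistent with strictly more than half
#' of their existing 8-neighbors. Border and masked-tissue pixels are judged
#' against the neighbors they actually have (a fixed denominator of 8 would
#' inflate PAS along tissue edges); pixels with no neighbors are never
#' abnormal. Low PAS indicates smooth, spatially coherent cluster regions;
#' salt-and-pepper fragmentation drives PAS up. Invariant under any bijective
#' relabeling of clusters.
#'
#' @param labels Per-pixel cluster labels (integer or factor-like), aligned to
#'   the dataset's pixels.
#' @param dataset An `msi_dataset`.
#' @return PAS in \[0, 1\].
#' @examples
#' ph <- generate_phantom(phantom_spec(n_rows = 10, n_cols = 10, seed = 1))
#' compute_pas(ph$truth, ph$dataset)
#' @export
compute_pas <- function(labels, dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  labels <- check_labels(labels, n_pixels(dataset))
  d <- disagreement_counts(dataset, labels)
  mean(d$n_diff * 2L > d$n_nb & d$n_nb > 0L)
}

check_labels <- function(labels, n) {
  if (length(labels) != n) {
    abort(sprintf("labels have length %d but dataset has %d pixels", length(labels), n))
  }
  if (anyNA(labels)) abort("labels must not contain NA")
  as.integer(factor(labels))
}

#' Per-ion eta-squared under a clustering
#'
#' For every ion, the fraction of its total spatial intensity variance
#' explained by the cluster labels: the one-way ANOVA variance decomposition
#' eta^2 = SS_between / SS_total, where
#' SS_total = sum_i (x_ij - mean_j)^2 and
#' SS_between = sum_c n_c (mean_cj - mean_j)^2. Ions whose intensities are
#' constant (SS_total = 0) have undefined eta^2 and are returned as `NA`
#' rather than silently scored, so sparse panels do not bias the median.
#' eta^2 is invariant under per-ion affine transforms x -> a x + b (a != 0).
#'
#' @inheritParams compute_pas
#' @return A tibble with columns `ion_id`, `eta2` (NA for zero-variance ions).
#' @seealso [median_eta2()]
#' @export
compute_eta2 <- function(dataset, labels) {
  stopifnot(inherits(dataset, "msi_dataset"))
  labels <- check_labels(labels, n_pixels(dataset))
  x <- dataset$intensities
  n <- nrow(x)
  grand <- colMeans(x)
  cnt <- tabulate(labels)
  gm <- rowsum(x, labels, reorder = TRUE) / cnt  # cluster means, k x n_ions
  centered <- sweep(x, 2L, grand)
  ss_total <- colSums(centered^2)
  gdev <- sweep(gm, 2L, grand)
  ss_between <- colSums(gdev^2 * cnt)
  eta2 <- unname(ifelse(ss_total == 0, NA_real_, pmin(1, pmax(0, ss_between / ss_total))))
  if (all(is.na(eta2))) abort("all ions have zero variance; eta-squared undefined")
  tibble(ion_id = dataset$ion_ids, eta2 = eta2)
}

#' Median eta-squared over evaluable ions
#'
#' The composite inter-cluster heterogeneity score: the standard median (mean
#' of the two central order statistics for even length) of the per-ion eta^2
#' values, after dropping undefined (zero-variance) ions.
#'
#' @param eta2 Numeric vector of per-ion eta^2 values, or the tibble returned
#'   by [compute_eta2()]. `NA` entries (excluded ions) are dropped.
#' @return Median eta^2 in \[0, 1\].
#' @export
median_eta2 <- function(eta2) {
  if (is.data.frame(eta2)) eta2 <- eta2$eta2
  eta2 <- eta2[!is.na(eta2)]
  if (length(eta2) == 0) abort("no evaluable ions: eta-squared vector is empty")
  median(eta2)
}

#' Normalized Mutual Information between two partitions
#'
#' NMI(A, B) = I(A; B) / ((H(A) + H(B)) / 2), computed from the joint
#' contingency table with natural logarithms. Ranges over \[0, 1\]; 1 for
#' identical partitions up to relabeling. Degenerate conventions: if both
#' partitions are single-cluster (both entropies zero) the partitions are
#' identical and NMI is 1; if exactly one entropy is zero NMI is 0.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return NMI in \[0, 1\].
#' @export
compute_nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("label vectors must have equal length")
  }
  if (length(labels_a) == 0) abort("label vectors must be non-empty")
  if (anyNA(labels_a) || anyNA(labels_b)) abort("labels must not contain NA")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pij <- tab / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pa[row(pij)[nz]] * pb[col(pij)[nz]])))
  min(1, max(0, mi / ((ha + hb) / 2)))
}

#' Pairwise NMI matrix over a set of clusterings
#'
#' @param labelings A named list of equal-length label vectors (one per
#'   method).
#' @return A symmetric numeric matrix with unit diagonal, entries in \[0, 1\],
#'   dimnames taken from the list names.
#' @export
pairwise_nmi <- function(labelings) {
  if (!is.list(labelings) || length(labelings) < 2) {
    abort("need a list of at least 2 labelings")
  }
  len <- lengths(labelings)
  if (length(unique(len)) != 1) abort("all labelings must have equal length")
  m <- length(labelings)
  nm <- names(labelings) %||% paste0("method_", seq_len(m))
  out <- diag(1, m)
  dimnames(out) <- list(nm, nm)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      v <- compute_nmi(labelings[[i]], labelings[[j]])
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Median one-vs-rest Moran's I of a clustering
#'
#' For each cluster, the spatial autocorrelation (Moran's I) of its binary
#' one-vs-rest membership map is computed with binary 8-neighbor weights
#' (non-row-standardized):
#' I_c = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2, with z the centered
#' indicator and W the total weight. Clusters whose indicator is constant
#' (empty or covering every pixel) are skipped. The summary is the median of
#' the per-cluster values. Values near 1 indicate compact, spatially
#' autocorrelated clusters; the expectation for a random labeling is
#' -1/(n - 1).
#'
#' @inheritParams compute_pas
#' @return Median Moran's I in \[-1, 1\] (approximately; the statistic is not
#'   strictly bounded by ±1 but stays within it on these weights).
#' @export
compute_morans_i <- function(labels, dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  labels <- check_labels(labels, n_pixels(dataset))
  n <- n_pixels(dataset)
  pr <- neighbor_pairs(dataset)
  W <- nrow(pr)
  if (W == 0) abort("dataset has no adjacent pixel pairs")
  ks <- sort(unique(labels))
  vals <- purrr::map_dbl(ks, function(c) {
    ind <- as.numeric(labels == c)
    if (all(ind == ind[1])) return(NA_real_)
    z <- ind - mean(ind)
    lag <- rowsum(z[pr[, 2L]], pr[, 1L], reorder = FALSE)
    # rowsum drops pixels with no neighbors; align back
    num <- sum(z[as.integer(rownames(lag))] * lag)
    (n / W) * num / sum(z^2)
  })
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    abort("all clusters have constant one-vs-rest indicators; Moran's I undefined")
  }
  median(vals)
}

#' Evaluate one clustering against a dataset
#'
#' Computes the full metric report for one clustering result: PAS (spatial
#' continuity), per-ion eta^2 and median-eta^2 (inter-cluster metabolic
#' heterogeneity), and optionally NMI against an external reference
#' annotation and the median one-vs-rest Moran's I.
#'
#' @inheritParams compute_pas
#' @param reference Optional per-pixel reference labels (e.g., cell-type
#'   annotations) for external validation via NMI.
#' @param morans_i If `TRUE`, also compute the median one-vs-rest Moran's I.
#' @param method Method name recorded in the report.
#' @param runtime_s Optional wall-clock seconds to record (e.g., from
#'   [run_baseline()]).
#' @return An object of class `msi_report`. Use [glance()] for a one-row
#'   tibble of the scalar metrics and [tidy()] for the per-ion eta^2 table.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_rows = 12, n_cols = 12, seed = 1))
#' rep <- evaluate_clustering(ph$dataset, ph$truth, method = "truth")
#' glance(rep)
#' @export
evaluate_clustering <- function(dataset, labels, reference = NULL,
                                morans_i = FALSE, method = "method",
                                runtime_s = NA_real_) {
  if (inherits(labels, "msi_clustering")) {
    if (is.na(runtime_s)) runtime_s <- labels$runtime_s
    if (identical(method, "method")) method <- labels$method
    labels <- labels$labels
  }
  labels <- check_labels(labels, n_pixels(dataset))
  eta2 <- compute_eta2(dataset, labels)
  nmi_ref <- if (!is.null(reference)) {
    if (length(reference) != n_pixels(dataset)) {
      abort("reference annotation is not aligned to the dataset's pixels")
    }
    compute_nmi(labels, reference)
  } else {
    NA_real_
  }
  structure(
    list(
      method = method,
      pas = compute_pas(labels, dataset),
      eta2_per_ion = eta2,
      median_eta2 = median_eta2(eta2),
      n_excluded_ions = sum(is.na(eta2$eta2)),
      nmi_vs_reference = nmi_ref,
      morans_i_median = if (isTRUE(morans_i)) compute_morans_i(labels, dataset) else NA_real_,
      runtime_s = runtime_s,
      k = length(unique(labels))
    ),
    class = "msi_report"
  )
}

#' @export
print.msi_report <- function(x, ...) {
  cat(sprintf(
    "<msi_report> %s (k = %d): PAS = %.4f, median-eta2 = %.4f (%d ion(s) excluded)\n",
    x$method, x$k, x$pas, x$median_eta2, x$n_excluded_ions
  ))
  if (!is.na(x$nmi_vs_reference)) cat(sprintf("  NMI vs reference: %.4f\n", x$nmi_vs_reference))
  if (!is.na(x$morans_i_median)) cat(sprintf("  median Moran's I: %.4f\n", x$morans_i_median))
  if (!is.na(x$runtime_s)) cat(sprintf("  runtime: %.3fs\n", x$runtime_s))
  invisible(x)
}

#' @method glance msi_report
#' @export
glance.msi_report <- function(x, ...) {
  tibble(
    method = x$method,
    k = x$k,
    pas = x$pas,
    median_eta2 = x$median_eta2,
    n_excluded_ions = x$n_excluded_ions,
    nmi_vs_reference = x$nmi_vs_reference,
    morans_i_median = x$morans_i_median,
    runtime_s = x$runtime_s
  )
}

#' @method tidy msi_report
#' @export
tidy.msi_report <- function(x, ...) x$eta2_per_ion
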