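#' Plot one ion image
#'
#' @param dataset An `msi_dataset`.
#' @param ion Ion column index or id.
#' @param trans Intensity transform for the fill scale (`"log1p"` or
#'   `"identity"`).
#' @return A ggplot object.
#' @export
plot_ion_image <- function(dataset, ion, trans = c("log1p", "identity")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  trans <- arg_match(trans)
  j <- resolve_ion(dataset, ion)
  v <- dataset$intensities[, j]
  if (trans == "log1p") v <- log1p(v)
  df <- tibble(x = dataset$coords$x, y = dataset$coords$y, intensity = v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (trans == "log1p") "log1p" else "intensity") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("ion", dataset$ion_ids[j])) +
    ggplot2::theme_minimal()
}

#' Plot a cluster label map
#'
#' @param dataset An `msi_dataset`.
#' @param labels Per-pixel labels (or an `msi_clustering`).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_cluster_map <- function(dataset, labels, title = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (inherits(labels, "msi_clustering")) {
    if (is.null(title)) title <- labels$method
    labels <- labels$labels
  }
  labels <- check_labels(labels, n_pixels(dataset))
  df <- tibble(
    x = dataset$coords$x, y = dataset$coords$y,
    cluster = factor(labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$cluster)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot PAS retention curves from a sweep
#'
#' Draws PAS (and optionally median-eta^2) as a function of the SNS retention
#' fraction, one line per method — the retention-curve view of how ion
#' filtering affects spatial continuity.
#'
#' @param sweep A tibble from [sweep_report()].
#' @param metric `"pas"` or `"median_eta2"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metric = c("pas", "median_eta2")) {
  metric <- arg_match(metric)
  stopifnot(all(c("method", "fraction", metric) %in% names(sweep)))
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = .data$fraction, y = .data[[metric]],
    colour = .data$method, group = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(
      x = "top fraction of ions retained (by ascending SNS)",
      y = if (metric == "pas") "PAS" else "median eta-squared"
    ) +
    ggplot2::theme_minimal()
}

#' Dual-metric scatter of a pipeline run
#'
#' Scatter of median-eta^2 against PAS per method with the dual-metric
#' threshold lines; the passing region is the upper-left quadrant
#' (PAS below, median-eta^2 above threshold).
#'
#' @param object An `msi_run` from [run_pipeline()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot msi_run
#' @export
autoplot.msi_run <- function(object, ...) {
  m <- filter(object$metrics, !is.na(.data$pas))
  ggplot2::ggplot(m, ggplot2::aes(
    x = .data$pas, y = .data$median_eta2,
    colour = .data$pass_both, label = .data$method
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, show.legend = FALSE, size = 3) +
    ggplot2::geom_vline(xintercept = m$pas_threshold[1], linetype = "dashed") +
    ggplot2::geom_hline(yintercept = m$eta2_threshold[1], linetype = "dashed") +
    ggplot2::labs(
      x = "PAS (lower = more spatially continuous)",
      y = "median eta-squared (higher = more heterogeneous)",
      colour = "passes both"
    ) +
    ggplot2::theme_minimal()
}
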