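#' Run the filter–cluster–evaluate–rank pipeline
#'
#' End-to-end orchestration on one dataset: score ions by SNS, retain the top
#' `filter_fraction`, run every requested clustering method, evaluate each
#' labeling (PAS, per-ion eta^2, median-eta^2, optional reference NMI and
#' Moran's I), apply the dual-metric thresholds, build the composite ranking
#' and the pairwise NMI consistency matrix. A method that errors is recorded
#' as failed (non-passing) without aborting the rest of the batch. When
#' `out_dir` is given, all results plus the fully serialized configuration
#' are written there so the run can be replayed.
#'
#' @param dataset An `msi_dataset`, or a path to a CSV in the
#'   [read_msi_csv()] convention.
#' @param methods A data frame of method specs with columns `method`, `k`,
#'   and optionally `n_components` (default 20) and `seed` (default the
#'   pipeline seed); or a character vector of method names combined with the
#'   `k` argument.
#' @param k Default cluster count used when `methods` is a character vector.
#' @param filter_fraction SNS retention fraction in (0, 1\]; 1 disables
#'   filtering.
#' @param pas_threshold,eta2_threshold Dual-metric thresholds.
#' @param reference Optional per-pixel reference annotation for external NMI.
#' @param morans_i If `TRUE`, add the median one-vs-rest Moran's I per method.
#' @param seed Pipeline seed (default for method seeds).
#' @param out_dir Optional output directory; see [write_outputs()].
#' @return An object of class `msi_run`: a list with `metrics` (one row per
#'   method, including dual-metric decisions), `ranking`, `nmi_matrix`,
#'   `labelings` (named list), `quality` (SNS table), `config`, `stage_log`
#'   (per-stage wall-clock), and `errors`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_rows = 16, n_cols = 16, seed = 3))
#' run <- run_pipeline(ph$dataset, methods = c("pca_kmeans", "pca_hclust"),
#'                     k = 4, filter_fraction = 0.5, seed = 3)
#' run$metrics
#' @export
run_pipeline <- function(dataset, methods, k = NULL, filter_fraction = 1,
                         pas_threshold = 0.2, eta2_threshold = 0.5,
                         reference = NULL, morans_i = FALSE, seed = 1L,
                         out_dir = NULL) {
  if (is.character(dataset) && length(dataset) == 1) {
    dataset <- read_msi_csv(dataset, quiet = TRUE)
  }
  stopifnot(inherits(dataset, "msi_dataset"))
  methods <- normalize_method_specs(methods, k, seed)
  stage_log <- list()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  quality <- sns_score(dataset)
  filtered <- filter_top_fraction(dataset, quality, filter_fraction)
  stage_log$filter_s <- tic() - t0

  t0 <- tic()
  runs <- vector("list", nrow(methods))
  errors <- character(0)
  for (i in seq_len(nrow(methods))) {
    runs[i] <- list(tryCatch(
      run_baseline(
        filtered,
        method = methods$method[i], k = methods$k[i],
        n_components = methods$n_components[i], seed = methods$seed[i]
      ),
      error = function(e) {
        errors <<- c(errors, stats::setNames(conditionMessage(e), methods$method[i]))
        NULL
      }
    ))
  }
  stage_log$cluster_s <- tic() - t0

  t0 <- tic()
  ok <- !vapply(runs, is.null, logical(1))
  reports <- purrr::map(runs[ok], function(cl) {
    evaluate_clustering(filtered, cl, reference = reference, morans_i = morans_i)
  })
  metrics <- purrr::map_dfr(reports, glance)
  failed <- methods[!ok, , drop = FALSE]
  if (nrow(failed) > 0) {
    metrics <- bind_rows(metrics, tibble(
      method = failed$method, k = NA_integer_, pas = NA_real_,
      median_eta2 = NA_real_, n_excluded_ions = NA_integer_,
      nmi_vs_reference = NA_real_, morans_i_median = NA_real_,
      runtime_s = NA_real_
    ))
  }
  decisions <- evaluate_dual(metrics, pas_threshold, eta2_threshold)
  evaluable <- decisions %>% filter(!is.na(.data$pas))
  ranking <- if (nrow(evaluable) >= 2) composite_ranking(evaluable) else evaluable
  labelings <- stats::setNames(
    purrr::map(runs[ok], "labels"),
    methods$method[ok]
  )
  nmi_matrix <- if (length(labelings) >= 2) pairwise_nmi(labelings) else NULL
  stage_log$evaluate_s <- tic() - t0

  out <- structure(
    list(
      metrics = decisions,
      ranking = ranking,
      nmi_matrix = nmi_matrix,
      labelings = labelings,
      reports = reports,
      quality = quality,
      dataset = filtered,
      config = list(
        methods = methods, filter_fraction = filter_fraction,
        pas_threshold = pas_threshold, eta2_threshold = eta2_threshold,
        morans_i = morans_i, seed = as.integer(seed),
        n_pixels = n_pixels(dataset), n_ions_input = n_ions(dataset),
        n_ions_retained = n_ions(filtered)
      ),
      stage_log = stage_log,
      errors = errors
    ),
    class = "msi_run"
  )
  if (!is.null(out_dir)) write_outputs(out, out_dir)
  out
}

normalize_method_specs <- function(methods, k, seed) {
  if (is.character(methods)) {
    if (is.null(k)) abort("`k` is required when `methods` is a character vector")
    methods <- tibble(method = methods, k = as.integer(k))
  }
  methods <- as_tibble(methods)
  stopifnot(all(c("method", "k") %in% names(methods)))
  if (nrow(methods) == 0) abort("no methods requested")
  if (!"n_components" %in% names(methods)) methods$n_components <- 20L
  if (!"seed" %in% names(methods)) methods$seed <- as.integer(seed)
  methods
}

#' @export
print.msi_run <- function(x, ...) {
  cat(sprintf(
    "<msi_run> %d method(s) on %d pixels; %d/%d ions retained (fraction %.2f)\n",
    nrow(x$metrics), x$config$n_pixels,
    x$config$n_ions_retained, x$config$n_ions_input, x$config$filter_fraction
  ))
  print(select(
    x$metrics, "method", "pas", "median_eta2",
    "pass_pas", "pass_eta2", "pass_both"
  ))
  if (length(x$errors) > 0) {
    cat("failed methods:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' PAS and median-eta^2 across an SNS retention sweep
#'
#' Runs each method at every retention fraction and tabulates the metrics,
#' producing the data behind retention-curve figures (PAS as a function of
#' the fraction of ions kept). Failures are recorded and skipped.
#'
#' @inheritParams run_pipeline
#' @param fractions Retention fractions to sweep (default [sns_fractions]).
#' @return A tibble with columns `method`, `fraction`, `n_ions`, `pas`,
#'   `median_eta2`, `runtime_s`.
#' @seealso [plot_sweep()]
#' @export
sweep_report <- function(dataset, methods, k = NULL,
                         fractions = sns_fractions, seed = 1L) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (length(fractions) < 1) abort("need at least one fraction")
  methods <- normalize_method_specs(methods, k, seed)
  quality <- sns_score(dataset)
  purrr::map_dfr(sort(fractions), function(p) {
    filtered <- filter_top_fraction(dataset, quality, p)
    purrr::map_dfr(seq_len(nrow(methods)), function(i) {
      tryCatch({
        cl <- run_baseline(
          filtered,
          method = methods$method[i], k = methods$k[i],
          n_components = methods$n_components[i], seed = methods$seed[i]
        )
        eta2 <- compute_eta2(filtered, cl$labels)
        tibble(
          method = methods$method[i], fraction = p, n_ions = n_ions(filtered),
          pas = compute_pas(cl$labels, filtered),
          median_eta2 = median_eta2(eta2), runtime_s = cl$runtime_s
        )
      }, error = function(e) tibble())
    })
  })
}

#' Write a pipeline run to disk
#'
#' Writes, into `dir`: one labels CSV per method (`labels_<method>.csv` with
#' columns x, y, label), a metrics CSV with one row per method (including the
#' dual-metric pass columns), the SNS quality table, the pairwise NMI matrix,
#' and a machine-readable JSON run summary holding the full configuration,
#' per-method runtimes and per-stage wall-clock times.
#'
#' @param run An `msi_run` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(run, dir) {
  stopifnot(inherits(run, "msi_run"))
  if (nrow(run$metrics) == 0) abort("nothing to write: no methods were evaluated")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'", dir))
  coords <- run$dataset$coords
  for (nm in names(run$labelings)) {
    readr::write_csv(
      tibble(x = coords$x, y = coords$y, label = run$labelings[[nm]]),
      file.path(dir, paste0("labels_", nm, ".csv")),
      progress = FALSE
    )
  }
  readr::write_csv(run$metrics, file.path(dir, "metrics.csv"), progress = FALSE)
  readr::write_csv(run$quality, file.path(dir, "sns_quality.csv"), progress = FALSE)
  if (!is.null(run$nmi_matrix)) {
    nmi_df <- as.data.frame(run$nmi_matrix)
    nmi_df <- cbind(method = rownames(run$nmi_matrix), nmi_df)
    readr::write_csv(as_tibble(nmi_df), file.path(dir, "nmi_matrix.csv"), progress = FALSE)
  }
  summary <- list(
    config = run$config,
    stage_log = run$stage_log,
    runtimes_s = stats::setNames(
      as.list(run$metrics$runtime_s), run$metrics$method
    ),
    errors = as.list(run$errors)
  )
  jsonlite::write_json(
    summary, file.path(dir, "run_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a labels CSV written by [write_outputs()]
#'
#' Validates that the label file's coordinates match the dataset's pixels
#' (same grid positions, same order after matching), so externally produced
#' labelings are ingested under the same contract as built-in adapters.
#'
#' @param path Labels CSV with columns x, y, label.
#' @param dataset The `msi_dataset` the labels belong to.
#' @return Integer label vector aligned to the dataset's pixels.
#' @export
read_labels_csv <- function(path, dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  df <- readr::read_csv(path, col_types = "ddi", progress = FALSE)
  if (!all(c("x", "y", "label") %in% names(df))) {
    abort("labels CSV must have columns x, y, label")
  }
  if (nrow(df) != n_pixels(dataset)) {
    abort(sprintf(
      "labels file has %d pixels but dataset has %d",
      nrow(df), n_pixels(dataset)
    ))
  }
  idx <- match(
    paste(dataset$coords$x, dataset$coords$y),
    paste(df$x, df$y)
  )
  if (anyNA(idx)) abort("labels file coordinates do not match the dataset's pixels")
  as.integer(df$label[idx])
}
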