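#' Dual-metric pass/fail decisions
#'
#' Applies the dual-metric acceptance rule to a table of per-method metrics:
#' a method passes when its clustering is both spatially continuous
#' (PAS strictly below `pas_threshold`) and metabolically heterogeneous
#' between clusters (median-eta^2 strictly above `eta2_threshold`). The
#' defaults — PAS < 0.2, median-eta^2 > 0.5 — are empirical: clustering maps
#' with PAS above roughly 0.2 show visible salt-and-pepper fragmentation,
#' while a median-eta^2 above 0.5 means that for a typical ion more than half
#' of the spatial variance is explained by between-cluster differences.
#' Inequalities are strict, so a method sitting exactly at a threshold does
#' not pass.
#'
#' @param metrics A data frame with columns `method`, `pas`, `median_eta2`
#'   (e.g., built by row-binding [glance()] of several [evaluate_clustering()]
#'   reports), or a single `msi_report`.
#' @param pas_threshold PAS upper threshold, in \[0, 1\].
#' @param eta2_threshold Median-eta^2 lower threshold, in \[0, 1\].
#' @return The input metrics tibble with added columns `pas_threshold`,
#'   `eta2_threshold`, `pass_pas`, `pass_eta2`, `pass_both`. Methods whose
#'   metrics are `NA` (e.g., a crashed run) count as non-passing.
#' @export
evaluate_dual <- function(metrics, pas_threshold = 0.2, eta2_threshold = 0.5) {
  if (inherits(metrics, "msi_report")) metrics <- glance(metrics)
  check_threshold(pas_threshold, "pas_threshold")
  check_threshold(eta2_threshold, "eta2_threshold")
  stopifnot(all(c("method", "pas", "median_eta2") %in% names(metrics)))
  as_tibble(metrics) %>%
    mutate(
      pas_threshold = pas_threshold,
      eta2_threshold = eta2_threshold,
      pass_pas = !is.na(.data$pas) & .data$pas < pas_threshold,
      pass_eta2 = !is.na(.data$median_eta2) & .data$median_eta2 > eta2_threshold,
      pass_both = .data$pass_pas & .data$pass_eta2
    )
}

check_threshold <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  }
  invisible(x)
}

#' Composite dual-metric ranking of methods
#'
#' Ranks methods jointly on both metrics. The default composite score is the
#' mean of the two metric ranks — PAS ranked ascending (lower is better) and
#' median-eta^2 ranked descending (higher is better) — with average ranks on
#' ties; being rank-based, it is invariant to any strictly monotone transform
#' of either metric. A score-based alternative (`score = "norm_mean"`) uses
#' the mean of min-max normalized (1 - PAS) and median-eta^2 instead. Output
#' is sorted by ascending composite score; exact score ties break
#' alphabetically by method name.
#'
#' @param metrics Data frame with columns `method`, `pas`, `median_eta2`.
#' @param score `"rank_mean"` (default) or `"norm_mean"`.
#' @return The metrics tibble with `composite_score` and integer
#'   `composite_rank` columns, sorted best-first.
#' @export
composite_ranking <- function(metrics, score = c("rank_mean", "norm_mean")) {
  score <- arg_match(score)
  stopifnot(all(c("method", "pas", "median_eta2") %in% names(metrics)))
  if (nrow(metrics) < 2) abort("composite ranking needs at least 2 methods")
  m <- as_tibble(metrics)
  if (score == "rank_mean") {
    cs <- (rank(m$pas, ties.method = "average") +
             rank(-m$median_eta2, ties.method = "average")) / 2
  } else {
    norm <- function(v) if (diff(range(v)) == 0) rep(0.5, length(v)) else (v - min(v)) / diff(range(v))
    cs <- 1 - (norm(1 - m$pas) + norm(m$median_eta2)) / 2
  }
  m %>%
    mutate(composite_score = cs) %>%
    arrange(.data$composite_score, .data$method) %>%
    mutate(composite_rank = row_number())
}

#' Per-method dual-metric pass rates over a dataset grid
#'
#' Summarizes dual-metric decisions across datasets: for each method, the
#' number and fraction of datasets on which it passed both criteria. A method
#' that errored on a dataset should appear in the grid with `pass_both = NA`
#' or `FALSE`; either counts as non-passing there.
#'
#' @param decisions Data frame with columns `method`, `dataset`, `pass_both`
#'   (one row per method x dataset cell; the grid must be rectangular).
#' @return Tibble with `method`, `n_pass`, `n_datasets`, `pass_rate`, sorted
#'   by descending pass rate.
#' @export
pass_rate_summary <- function(decisions) {
  stopifnot(all(c("method", "dataset", "pass_both") %in% names(decisions)))
  grid_count <- table(decisions$method)
  if (length(unique(grid_count)) != 1) {
    abort("grid is not rectangular: every method must be evaluated (or marked failed) on every dataset")
  }
  as_tibble(decisions) %>%
    group_by(.data$method) %>%
    summarise(
      n_pass = sum(.data$pass_both %in% TRUE),
      n_datasets = n(),
      .groups = "drop"
    ) %>%
    mutate(pass_rate = .data$n_pass / .data$n_datasets) %>%
    arrange(desc(.data$pass_rate), .data$method)
}

#' Threshold sensitivity of dual-metric pass rates
#'
#' Re-applies the dual-metric rule under several threshold settings (typically
#' strict, default, relaxed) and reports pass counts per setting, plus the
#' Spearman correlation of the composite ranking between each setting and the
#' first one. Settings must be nested: each successive setting's acceptance
#' region (PAS below, median-eta^2 above) must contain the previous one, so a
#' method's pass set can only grow from strict to relaxed. The composite
#' ranking itself is threshold-free, so its correlation across settings is 1
#' by construction within a dataset; it is reported for grids where metrics
#' vary by dataset subset.
#'
#' @param metrics Data frame with columns `method`, `pas`, `median_eta2`, and
#'   optionally `dataset`.
#' @param settings Named list of `c(pas_threshold, eta2_threshold)` pairs,
#'   ordered from strict to relaxed.
#' @return Tibble with one row per setting x method: `setting`,
#'   `pas_threshold`, `eta2_threshold`, `method`, `n_pass`, `n_cells`.
#' @export
threshold_sensitivity <- function(metrics,
                                  settings = list(
                                    strict = c(0.15, 0.55),
                                    default = c(0.20, 0.50),
                                    relaxed = c(0.25, 0.45)
                                  )) {
  stopifnot(is.list(settings), length(settings) >= 1)
  pas_t <- vapply(settings, `[`, numeric(1), 1)
  eta_t <- vapply(settings, `[`, numeric(1), 2)
  if (is.unsorted(pas_t) || is.unsorted(rev(eta_t))) {
    abort("settings must be nested: PAS thresholds non-decreasing and eta2 thresholds non-increasing from strict to relaxed")
  }
  nm <- names(settings) %||% paste0("setting_", seq_along(settings))
  purrr::map_dfr(seq_along(settings), function(i) {
    evaluate_dual(metrics, pas_t[i], eta_t[i]) %>%
      group_by(.data$method) %>%
      summarise(
        n_pass = sum(.data$pass_both),
        n_cells = n(),
        .groups = "drop"
      ) %>%
      mutate(
        setting = nm[i], pas_threshold = pas_t[i], eta2_threshold = eta_t[i],
        .before = 1
      )
  })
}

#' External biological validation of the composite ranking
#'
#' Scores every method's concordance with an external reference annotation
#' (e.g., cell-type labels from an adjacent spatial transcriptomics section)
#' by NMI, and correlates the dual-metric composite ranking with the
#' NMI-based concordance ranking using Spearman's rho (average ranks on
#' ties). A high rho means the dual-metric framework, computed without any
#' reference, recovers the ordering an external ground truth would give.
#'
#' @param labelings Named list of per-pixel label vectors, one per method.
#' @param reference Per-pixel reference annotation, same length.
#' @param metrics Data frame with `method`, `pas`, `median_eta2` for the same
#'   methods.
#' @return A list with `table` (tibble: method, nmi_vs_reference,
#'   composite_rank, nmi_rank) and `spearman_rho`.
#' @export
external_validation <- function(labelings, reference, metrics) {
  if (!is.list(labelings) || length(labelings) < 3) {
    abort("need at least 3 methods for a meaningful rank correlation")
  }
  len <- lengths(labelings)
  if (length(unique(c(len, length(reference)))) != 1) {
    abort("reference annotation is not aligned to the labelings")
  }
  nm <- names(labelings)
  if (is.null(nm) || any(nm == "")) abort("labelings must be a named list")
  ranked <- composite_ranking(metrics)
  nmis <- purrr::map_dbl(labelings, compute_nmi, labels_b = reference)
  tab <- tibble(method = nm, nmi_vs_reference = unname(nmis)) %>%
    left_join(
      select(ranked, "method", "composite_score", "composite_rank"),
      by = "method"
    ) %>%
    mutate(nmi_rank = rank(-.data$nmi_vs_reference, ties.method = "average"))
  rho <- cor(rank(tab$composite_score, ties.method = "average"),
             tab$nmi_rank, method = "spearman")
  list(table = tab, spearman_rho = rho)
}
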