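# Registry of clustering adapters. Built-ins are registered at load time;
# external adapters can be added with register_adapter().
.adapters <- new.env(parent = emptyenv())

#' Available clustering methods
#'
#' @return Character vector of registered adapter names.
#' @export
cluster_methods <- function() sort(ls(.adapters))

#' Register a clustering adapter
#'
#' An adapter is a function `f(dataset, k, seed, ...)` returning an integer
#' label vector of length `n_pixels(dataset)`. Registered adapters become
#' available to [run_baseline()] and [run_pipeline()] under `name`. The
#' returned labels are validated (length, no NA) before use, so external
#' methods are ingested under the same contract as the built-ins.
#'
#' @param name Method identifier.
#' @param fn Adapter function.
#' @return `name`, invisibly.
#' @examples
#' register_adapter("constant", function(dataset, k, seed, ...) {
#'   rep(1L, n_pixels(dataset))
#' })
#' "constant" %in% cluster_methods()
#' @export
register_adapter <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .adapters)
  invisible(name)
}

#' Run a clustering baseline
#'
#' Runs one of the registered clustering adapters on a dataset and returns
#' the labeling together with its wall-clock runtime. The built-in baselines
#' follow the common non-spatial MSI pipeline: intensities are log1p
#' transformed and per-ion z-scored (zero-variance ions dropped), reduced by
#' PCA to `n_components` dimensions, then clustered by k-means (`pca_kmeans`),
#' a Gaussian mixture (`pca_gmm`, via mclust) or Ward agglomeration
#' (`pca_hclust`). All built-ins are deterministic given `seed` and never
#' modify the dataset.
#'
#' @param dataset An `msi_dataset`.
#' @param method Adapter name; see [cluster_methods()].
#' @param k Target cluster count (1 <= k <= n_pixels).
#' @param n_components PCA dimensionality (capped at the data's rank).
#' @param seed Integer seed; recorded in the result.
#' @param ... Passed on to the adapter.
#' @return An object of class `msi_clustering`: a list with `labels`
#'   (integer vector), `method`, `k`, `n_components`, `seed`, `runtime_s`,
#'   and `preprocessing` (a record of the transform applied).
#' @examples
#' ph <- generate_phantom(phantom_spec(n_rows = 12, n_cols = 12, seed = 1))
#' cl <- run_baseline(ph$dataset, "pca_kmeans", k = 4, seed = 1)
#' compute_nmi(cl$labels, ph$truth)
#' @export
run_baseline <- function(dataset, method = "pca_kmeans", k, n_components = 20,
                         seed = 1L, ...) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be a positive integer")
  if (k > n_pixels(dataset)) {
    abort(sprintf("k = %d exceeds the number of pixels (%d)", k, n_pixels(dataset)))
  }
  if (!exists(method, envir = .adapters)) {
    abort(sprintf(
      "unknown method '%s'; available: %s",
      method, paste(cluster_methods(), collapse = ", ")
    ))
  }
  fn <- get(method, envir = .adapters)
  t0 <- proc.time()[["elapsed"]]
  labels <- withr::with_seed(
    as.integer(seed),
    fn(dataset, k = as.integer(k), seed = as.integer(seed),
       n_components = n_components, ...)
  )
  runtime <- proc.time()[["elapsed"]] - t0
  if (length(labels) != n_pixels(dataset) || anyNA(labels)) {
    abort(sprintf(
      "adapter '%s' returned %d labels for %d pixels (or NA labels)",
      method, length(labels), n_pixels(dataset)
    ))
  }
  structure(
    list(
      labels = as.integer(factor(labels)),
      method = method,
      k = as.integer(k),
      n_components = as.integer(n_components),
      seed = as.integer(seed),
      runtime_s = runtime,
      preprocessing = "log1p + per-ion z-score + PCA"
    ),
    class = "msi_clustering"
  )
}

#' @export
print.msi_clustering <- function(x, ...) {
  cat(sprintf(
    "<msi_clustering> %s: %d pixels, %d clusters (seed %d, %.3fs)\n",
    x$method, length(x$labels), length(unique(x$labels)), x$seed, x$runtime_s
  ))
  invisible(x)
}

# log1p + per-ion z-score + PCA scores. Zero-variance ions carry no signal
# and are dropped before scaling.
reduce_pca <- function(dataset, n_components) {
  x <- log1p(dataset$intensities)
  sds <- apply(x, 2L, sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0) abort("all ions have zero variance after log1p transform")
  x <- scale(x)
  rank_max <- min(nrow(x) - 1L, ncol(x))
  d <- min(as.integer(n_components), rank_max)
  p <- prcomp(x, center = FALSE, scale. = FALSE, rank. = d)
  p$x
}

builtin_pca_kmeans <- function(dataset, k, seed, n_components = 20, ...) {
  scores <- reduce_pca(dataset, n_components)
  if (k == 1) return(rep(1L, nrow(scores)))
  kmeans(scores, centers = k, nstart = 10, iter.max = 100)$cluster
}

builtin_pca_gmm <- function(dataset, k, seed, n_components = 20, ...) {
  scores <- reduce_pca(dataset, n_components)
  if (k == 1) return(rep(1L, nrow(scores)))
  # Mclust() resolves its helpers (mclustBIC etc.) in the caller's frame, so
  # evaluate the call with the mclust namespace as enclosure
  fit <- eval(
    quote(Mclust(scores, G = k, verbose = FALSE)),
    list(scores = scores, k = k),
    asNamespace("mclust")
  )
  if (is.null(fit)) abort("mclust failed to fit a Gaussian mixture")
  fit$classification
}

builtin_pca_hclust <- function(dataset, k, seed, n_components = 20, ...) {
  scores <- reduce_pca(dataset, n_components)
  cutree(hclust(dist(scores), method = "ward.D2"), k = k)
}

register_builtin_adapters <- function() {
  register_adapter("pca_kmeans", builtin_pca_kmeans)
  register_adapter("pca_gmm", builtin_pca_gmm)
  register_adapter("pca_hclust", builtin_pca_hclust)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_adapters()
}
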