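#' Specification of a synthetic MSI phantom
#'
#' A phantom emulates the post-peak-picking structure of background-removed
#' MSI data: a 2-D pixel grid partitioned into spatially contiguous regions
#' (anatomical domains), a set of informative ions whose mean intensity
#' differs by region, a set of spatially random noise ions (matrix
#' interference and stochastic detection noise), multiplicative lognormal
#' intensity noise, and an optional elliptical tissue mask.
#'
#' `effect_size` is the ratio of the between-region spread of an informative
#' ion's log-mean to the within-region lognormal noise scale `noise_sd`;
#' noise ions are i.i.d. lognormal with total log-scale matched to the
#' informative ions, so at `effect_size = 0` the two groups are
#' distributionally identical.
#'
#' @param n_rows,n_cols Grid size in pixels.
#' @param k_regions Number of planted contiguous regions.
#' @param layout `"blocks"` (equal horizontal bands, straight boundaries) or
#'   `"voronoi"` (nearest-center cells, irregular boundaries).
#' @param n_informative_ions,n_noise_ions Ion counts per group.
#' @param effect_size Between-region log-mean spread in units of `noise_sd`.
#' @param noise_sd Within-region multiplicative lognormal scale (sdlog).
#' @param mask_fraction Fraction of pixels removed (those farthest from the
#'   grid centre), emulating a tissue boundary.
#' @param seed Integer seed; `generate_phantom()` is a pure function of the
#'   spec including this seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_rows = 40, n_cols = 40, k_regions = 4,
                         layout = c("blocks", "voronoi"),
                         n_informative_ions = 30, n_noise_ions = 10,
                         effect_size = 3, noise_sd = 0.3,
                         mask_fraction = 0, seed = 1L) {
  layout <- arg_match(layout)
  stopifnot(
    n_rows >= 1, n_cols >= 1, k_regions >= 1,
    n_informative_ions >= 0, n_noise_ions >= 0,
    n_informative_ions + n_noise_ions >= 1,
    effect_size >= 0, noise_sd >= 0,
    mask_fraction >= 0, mask_fraction < 1,
    k_regions <= n_rows * n_cols
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      k_regions = as.integer(k_regions), layout = layout,
      n_informative_ions = as.integer(n_informative_ions),
      n_noise_ions = as.integer(n_noise_ions),
      effect_size = effect_size, noise_sd = noise_sd,
      mask_fraction = mask_fraction, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Generate a synthetic MSI phantom
#'
#' Builds an `msi_dataset` with planted ground-truth regions according to a
#' [phantom_spec()]. Informative ion `j` receives per-region log-means with
#' spread `effect_size * noise_sd`; each pixel's intensity is the region mean
#' times lognormal(0, `noise_sd`) noise. Noise ions are i.i.d. lognormal with
#' no region dependence. Identical spec (including seed) gives bit-identical
#' output. If masking empties or disconnects a planted region, generation is
#' retried (voronoi layouts re-draw centres) up to 10 times before erroring
#' with diagnostics.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `msi_phantom`: `dataset` (`msi_dataset`), `truth`
#'   (integer region labels per pixel), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_rows = 16, n_cols = 16, seed = 7))
#' compute_pas(ph$truth, ph$dataset)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  last_diag <- NULL
  for (attempt in seq_len(10L)) {
    res <- withr::with_seed(spec$seed + (attempt - 1L) * 1000003L, {
      grid <- phantom_grid(spec, attempt)
      ok <- regions_valid(grid, spec$k_regions)
      if (!isTRUE(ok)) {
        list(fail = ok)
      } else {
        list(fail = NULL, grid = grid, data = phantom_intensities(spec, grid$region))
      }
    })
    if (is.null(res$fail)) {
      ds <- as_msi_dataset(cbind(
        data.frame(x = res$grid$x, y = res$grid$y),
        res$data
      ))
      return(structure(
        list(dataset = ds, truth = res$grid$region, spec = spec),
        class = "msi_phantom"
      ))
    }
    last_diag <- res$fail
  }
  abort(sprintf(
    "could not generate a phantom with %d non-empty 4-connected regions after 10 attempts: %s",
    spec$k_regions, last_diag
  ))
}

# Pixel grid with region assignment; masking removes the pixels farthest
# from the grid centre (elliptical tissue shape).
phantom_grid <- function(spec, attempt = 1L) {
  g <- expand.grid(col = seq_len(spec$n_cols) - 1L, row = seq_len(spec$n_rows) - 1L)
  region <- switch(spec$layout,
    blocks = block_regions(g$row, g$col, spec$n_rows, spec$n_cols, spec$k_regions),
    voronoi = voronoi_regions(g$row, g$col, spec$n_rows, spec$n_cols, spec$k_regions)
  )
  keep <- rep(TRUE, nrow(g))
  if (spec$mask_fraction > 0) {
    cr <- (spec$n_rows - 1) / 2
    cc <- (spec$n_cols - 1) / 2
    d <- ((g$row - cr) / max(cr, 0.5))^2 + ((g$col - cc) / max(cc, 0.5))^2
    n_drop <- floor(spec$mask_fraction * nrow(g))
    if (n_drop > 0) keep[order(d, decreasing = TRUE)[seq_len(n_drop)]] <- FALSE
  }
  list(
    x = g$col[keep], y = g$row[keep],
    row = g$row[keep], col = g$col[keep],
    region = region[keep]
  )
}

# Equal-height horizontal bands: straight region boundaries along which no
# pixel disagrees with a strict majority of its neighbors (truth PAS = 0).
block_regions <- function(row, col, n_rows, n_cols, k) {
  as.integer(pmin(floor(row / (n_rows / k)), k - 1) + 1L)
}

voronoi_regions <- function(row, col, n_rows, n_cols, k) {
  idx <- sample.int(n_rows * n_cols, k)
  cr <- (idx - 1) %/% n_cols
  cc <- (idx - 1) %% n_cols
  d2 <- outer(row, cr, function(a, b) (a - b)^2) +
    outer(col, cc, function(a, b) (a - b)^2)
  max.col(-d2, ties.method = "first")
}

# Every region non-empty and 4-connected after masking; returns TRUE or a
# diagnostic string.
regions_valid <- function(grid, k) {
  present <- sort(unique(grid$region))
  if (length(present) < k) {
    return(sprintf("region(s) %s emptied by masking",
                   paste(setdiff(seq_len(k), present), collapse = ", ")))
  }
  M <- matrix(0L, nrow = max(grid$row) + 1L, ncol = max(grid$col) + 1L)
  M[cbind(grid$row + 1L, grid$col + 1L)] <- grid$region
  for (r in present) {
    cells <- which(M == r, arr.ind = TRUE)
    if (!is_4_connected(cells, M, r)) {
      return(sprintf("region %d is not 4-connected after masking", r))
    }
  }
  TRUE
}

is_4_connected <- function(cells, M, r) {
  n <- nrow(cells)
  if (n <= 1) return(TRUE)
  visited <- rep(FALSE, n)
  key <- paste(cells[, 1], cells[, 2])
  lookup <- stats::setNames(seq_len(n), key)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nb <- lookup[paste(cells[cur, 1] + d[1], cells[cur, 2] + d[2])]
      if (!is.na(nb) && !visited[nb]) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  all(visited)
}

# Intensity matrix: informative ions get per-region lognormal means, noise
# ions are i.i.d. lognormal with matched marginal log-variance.
phantom_intensities <- function(spec, region) {
  n <- length(region)
  k <- spec$k_regions
  cols <- vector("list", spec$n_informative_ions + spec$n_noise_ions)
  for (j in seq_len(spec$n_informative_ions)) {
    mu <- rnorm(k)
    if (k > 1 && sd(mu) > 0) mu <- (mu - mean(mu)) / sd(mu)
    mu <- mu * spec$effect_size * spec$noise_sd
    cols[[j]] <- exp(mu[region] + rnorm(n, 0, spec$noise_sd))
  }
  sd_noise <- spec$noise_sd * sqrt(1 + spec$effect_size^2)
  for (j in seq_len(spec$n_noise_ions)) {
    cols[[spec$n_informative_ions + j]] <- exp(rnorm(n, 0, sd_noise))
  }
  out <- as.data.frame(cols, check.names = FALSE)
  names(out) <- c(
    sprintf("sig_%03d", seq_len(spec$n_informative_ions)),
    sprintf("noise_%03d", seq_len(spec$n_noise_ions))
  )
  out
}

#' @export
print.msi_phantom <- function(x, ...) {
  cat(sprintf(
    "<msi_phantom> %d x %d grid, %d regions (%s), %d informative + %d noise ions, effect %.2g, noise_sd %.2g, seed %d\n",
    x$spec$n_rows, x$spec$n_cols, x$spec$k_regions, x$spec$layout,
    x$spec$n_informative_ions, x$spec$n_noise_ions,
    x$spec$effect_size, x$spec$noise_sd, x$spec$seed
  ))
  print(x$dataset)
  invisible(x)
}

#' Corrupt a labeling with random label flips
#'
#' Reassigns exactly `round(flip_fraction * n)` pixels, chosen without
#' replacement, to a uniformly random *different* label from the set of
#' labels present. Used to build graded degradations of a ground-truth
#' labeling for validating the metric and ranking machinery.
#'
#' @param labels Integer label vector with at least 2 distinct values (unless
#'   `flip_fraction` is 0).
#' @param flip_fraction Fraction of pixels to flip, in \[0, 1\].
#' @param seed Integer seed.
#' @return A label vector of the same length.
#' @export
add_label_noise <- function(labels, flip_fraction, seed = 1L) {
  stopifnot(is.numeric(flip_fraction), length(flip_fraction) == 1,
            flip_fraction >= 0, flip_fraction <= 1)
  labels <- as.integer(labels)
  uniq <- unique(labels)
  if (flip_fraction == 0) return(labels)
  if (length(uniq) < 2) {
    abort("cannot flip labels of a single-cluster labeling")
  }
  n_flip <- round(flip_fraction * length(labels))
  if (n_flip == 0) return(labels)
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(length(labels), n_flip)
    for (i in idx) {
      others <- uniq[uniq != labels[i]]
      labels[i] <- if (length(others) == 1) others else sample(others, 1)
    }
  })
  labels
}

#' Randomly permute one ion's pixel intensities
#'
#' Destroys the spatial structure of a single ion image while keeping its
#' intensity histogram exactly; all other ions are untouched. A structured
#' (low-SNS) ion's shuffled copy behaves like a noise ion.
#'
#' @param dataset An `msi_dataset`.
#' @param ion Ion column index or id.
#' @param seed Integer seed.
#' @return A new `msi_dataset`.
#' @export
shuffle_ion <- function(dataset, ion, seed = 1L) {
  stopifnot(inherits(dataset, "msi_dataset"))
  j <- resolve_ion(dataset, ion)
  perm <- withr::with_seed(as.integer(seed), sample.int(n_pixels(dataset)))
  ints <- dataset$intensities
  ints[, j] <- ints[perm, j]
  structure(
    list(coords = dataset$coords, intensities = ints, ion_ids = dataset$ion_ids),
    class = "msi_dataset"
  )
}
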