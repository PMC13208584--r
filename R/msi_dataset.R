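#' MSI dataset container
#'
#' An `msi_dataset` bundles pixel coordinates, their inferred integer grid
#' positions, and a nonnegative pixel-by-ion intensity matrix. It is the
#' common currency of all filtering, clustering and evaluation functions.
#'
#' Coordinates may be real-valued instrument units (MSI pitches typically run
#' 20–100 µm); all neighborhood logic operates on the inferred integer grid.
#' Non-rectangular tissue masks are implicit: pixels that are absent simply do
#' not appear, and neighbor queries only ever return existing pixels.
#'
#' @param data A data frame whose first two columns are the pixel X and Y
#'   coordinates and whose remaining columns are per-ion intensities
#'   (one column per ion; headers are kept verbatim as ion identifiers).
#' @return An object of class `msi_dataset` with components:
#'   \describe{
#'     \item{coords}{tibble with columns `x`, `y`, `row`, `col` (integer grid).}
#'     \item{intensities}{numeric matrix, `n_pixels` rows by `n_ions` columns.}
#'     \item{ion_ids}{character vector of ion labels in file/column order.}
#'   }
#' @examples
#' df <- expand.grid(x = 0:3, y = 0:3)
#' df$`104.1` <- runif(16)
#' ds <- as_msi_dataset(df)
#' ds
#' @export
as_msi_dataset <- function(data) {
  data <- as.data.frame(data, check.names = FALSE)
  if (ncol(data) < 3) {
    abort("input must have at least 3 columns: x, y, then one column per ion")
  }
  if (nrow(data) < 2) {
    abort("input must have at least 2 pixels")
  }
  xy <- data[, 1:2]
  if (!all(vapply(xy, is.numeric, logical(1)))) {
    abort("the first two columns (coordinates) must be numeric")
  }
  if (anyNA(xy) || !all(is.finite(as.matrix(xy)))) {
    abort("coordinates must be finite")
  }
  ints <- data[, -(1:2), drop = FALSE]
  for (j in seq_along(ints)) {
    col <- ints[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      abort(sprintf(
        "non-numeric intensity in column '%s' (row %d)",
        names(ints)[j], if (is.na(bad)) 1L else bad
      ))
    }
    if (anyNA(col) || any(!is.finite(col))) {
      abort(sprintf(
        "non-finite intensity in column '%s' (row %d)",
        names(ints)[j], which(!is.finite(col))[1]
      ))
    }
    if (any(col < 0)) {
      abort(sprintf(
        "negative intensity in column '%s' (row %d)",
        names(ints)[j], which(col < 0)[1]
      ))
    }
  }
  ion_ids <- names(ints)
  if (anyDuplicated(ion_ids)) {
    abort(sprintf(
      "duplicated ion identifiers: %s",
      paste(unique(ion_ids[duplicated(ion_ids)]), collapse = ", ")
    ))
  }
  grid <- infer_grid(xy[[1]], xy[[2]])
  key <- paste(grid$row, grid$col)
  if (anyDuplicated(key)) {
    dup <- which(key %in% key[duplicated(key)])
    abort(sprintf(
      "duplicate pixel coordinates at rows: %s (x = %s, y = %s)",
      paste(head(dup, 10), collapse = ", "),
      paste(head(xy[[1]][dup], 10), collapse = ", "),
      paste(head(xy[[2]][dup], 10), collapse = ", ")
    ))
  }
  m <- as.matrix(ints)
  dimnames(m) <- list(NULL, ion_ids)
  structure(
    list(
      coords = tibble(
        x = as.numeric(xy[[1]]), y = as.numeric(xy[[2]]),
        row = grid$row, col = grid$col
      ),
      intensities = m,
      ion_ids = ion_ids
    ),
    class = "msi_dataset"
  )
}

#' Read an MSI peak-intensity matrix from CSV
#'
#' The CSV convention: a header row, the first two columns give the pixel
#' spatial coordinates (X, Y), and every remaining column holds one ion's
#' intensities across pixels. Ion identifiers are the verbatim header strings
#' (typically m/z values).
#'
#' @param path Path to a CSV file.
#' @param quiet If `FALSE` (default), print a short data overview
#'   (pixel count, ion count, coordinate ranges) after reading.
#' @return An [as_msi_dataset()] object.
#' @seealso [write_msi_csv()]
#' @export
read_msi_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (length(header) < 3) {
    abort("CSV must have at least 3 columns: x, y, then one column per ion")
  }
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_double()),
    name_repair = "minimal", progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "non-numeric value at data row %d, column '%s'",
      probs$row[1], header[probs$col[1]]
    ))
  }
  names(raw) <- header
  ds <- as_msi_dataset(raw)
  if (!quiet) {
    inform(sprintf(
      "msi_dataset: %d pixels, %d ions; x range [%g, %g], y range [%g, %g]",
      n_pixels(ds), n_ions(ds),
      min(ds$coords$x), max(ds$coords$x),
      min(ds$coords$y), max(ds$coords$y)
    ))
  }
  ds
}

#' Write an MSI dataset to CSV
#'
#' Writes the dataset in the same convention read by [read_msi_csv()]:
#' columns `x`, `y`, then one column per ion, full double precision
#' (round-trips exactly).
#'
#' @param dataset An [as_msi_dataset()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_msi_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  df <- as_tibble(dataset)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @method as_tibble msi_dataset
#' @export
as_tibble.msi_dataset <- function(x, ...) {
  xs <- x$coords$x
  ys <- x$coords$y
  out <- tibble(x = xs, y = ys)
  ints <- as_tibble(as.data.frame(x$intensities, check.names = FALSE))
  dplyr::bind_cols(out, ints)
}

#' Number of pixels / ions in a dataset
#' @param dataset An `msi_dataset`.
#' @return Integer count.
#' @export
n_pixels <- function(dataset) nrow(dataset$intensities)

#' @rdname n_pixels
#' @export
n_ions <- function(dataset) ncol(dataset$intensities)

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf(
    "<msi_dataset> %d pixels x %d ions; grid %d x %d (%.0f%% occupied)\n",
    n_pixels(x), n_ions(x),
    max(x$coords$row) + 1L, max(x$coords$col) + 1L,
    100 * n_pixels(x) / ((max(x$coords$row) + 1) * (max(x$coords$col) + 1))
  ))
  cat("ions: ", paste(head(x$ion_ids, 6), collapse = ", "),
      if (n_ions(x) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.msi_dataset <- function(x) dim(x$intensities)

#' Infer integer grid indices from raw pixel coordinates
#'
#' The grid pitch per axis is the minimum positive difference among sorted
#' unique coordinate values; each coordinate is snapped to
#' `round((coord - min)/pitch)`. A coordinate farther than 10% of the pitch
#' from its snapped grid position raises an irregular-grid error. The mapping
#' is order-preserving per axis.
#'
#' @param x,y Numeric coordinate vectors of equal length.
#' @return A list with integer vectors `row` (from `y`) and `col` (from `x`).
#' @export
infer_grid <- function(x, y) {
  if (length(unique(x)) < 2 && length(unique(y)) < 2) {
    abort("need at least 2 distinct coordinate values on one axis")
  }
  list(row = snap_axis(y, "y"), col = snap_axis(x, "x"))
}

snap_axis <- function(v, axis) {
  u <- sort(unique(v))
  if (length(u) == 1) {
    return(rep(0L, length(v)))
  }
  pitch <- min(diff(u))
  idx <- round((v - u[1]) / pitch)
  off <- abs(v - (u[1] + idx * pitch))
  if (any(off > 0.1 * pitch)) {
    bad <- which(off > 0.1 * pitch)[1]
    abort(sprintf(
      "irregular grid on %s axis: coordinate %g is %.3g from its nearest grid position (pitch %g, tolerance 10%%)",
      axis, v[bad], off[bad], pitch
    ))
  }
  as.integer(idx)
}

# Integer matrix of pixel indices on the bounding grid; NA where no pixel.
grid_index_matrix <- function(dataset) {
  r <- dataset$coords$row
  c <- dataset$coords$col
  M <- matrix(NA_integer_, nrow = max(r) + 1L, ncol = max(c) + 1L)
  M[cbind(r + 1L, c + 1L)] <- seq_along(r)
  M
}

# All (i, j) directed pairs of 8-adjacent existing pixels, as a two-column
# integer matrix. Each undirected pair appears twice (both directions).
neighbor_pairs <- function(dataset) {
  M <- grid_index_matrix(dataset)
  nr <- nrow(M); nc <- ncol(M)
  offs <- cbind(
    dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  out <- vector("list", 8L)
  for (o in seq_len(8L)) {
    dr <- offs[o, 1L]; dc <- offs[o, 2L]
    r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
    c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
    if (r1 > r2 || c1 > c2) next
    A <- M[r1:r2, c1:c2, drop = FALSE]
    B <- M[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
    keep <- !is.na(A) & !is.na(B)
    if (any(keep)) out[[o]] <- cbind(A[keep], B[keep])
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' 8-neighborhood of a pixel
#'
#' Returns the indices of the pixels whose inferred grid position differs by
#' at most 1 in both row and column from pixel `i` (excluding `i` itself) and
#' that exist in the dataset. On masked tissue, absent grid cells contribute
#' nothing: an isolated pixel has no neighbors.
#'
#' @param dataset An `msi_dataset`.
#' @param i Pixel index (1-based).
#' @return Integer vector of 0–8 pixel indices.
#' @export
neighbors_8 <- function(dataset, i) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (length(i) != 1 || i < 1 || i > n_pixels(dataset)) {
    abort("invalid pixel index")
  }
  r <- dataset$coords$row; cc <- dataset$coords$col
  sel <- abs(r - r[i]) <= 1L & abs(cc - cc[i]) <= 1L
  sel[i] <- FALSE
  which(sel)
}

# Per-pixel neighbor counts and disagreement counts for an integer label
# vector, on the dataset's grid. Core primitive behind PAS and SNS.
disagreement_counts <- function(dataset, labels) {
  n <- n_pixels(dataset)
  stopifnot(length(labels) == n)
  pr <- neighbor_pairs(dataset)
  n_nb <- tabulate(pr[, 1L], nbins = n)
  diff <- labels[pr[, 1L]] != labels[pr[, 2L]]
  n_diff <- tabulate(pr[, 1L][diff], nbins = n)
  list(n_nb = n_nb, n_diff = n_diff)
}
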