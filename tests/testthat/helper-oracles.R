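# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately written against the definitions, not the package's
# vectorized implementations.

# Dataset on an integer grid with a single dummy ion; `drop` removes pixels.
grid_dataset <- function(n_rows, n_cols, drop = integer(0), values = NULL) {
  g <- expand.grid(x = seq_len(n_cols) - 1, y = seq_len(n_rows) - 1)
  if (length(drop) > 0) g <- g[-drop, , drop = FALSE]
  g$ion <- if (is.null(values)) seq_len(nrow(g)) else values
  as_msi_dataset(g)
}

# Brute-force PAS: for each pixel, scan all other pixels for Chebyshev
# distance 1 on the grid and apply the strict-majority disagreement rule.
brute_pas <- function(labels, dataset) {
  r <- dataset$coords$row
  cc <- dataset$coords$col
  n <- length(labels)
  abnormal <- logical(n)
  for (i in seq_len(n)) {
    nb <- which(pmax(abs(r - r[i]), abs(cc - cc[i])) == 1)
    if (length(nb) == 0) next
    abnormal[i] <- sum(labels[nb] != labels[i]) > length(nb) / 2
  }
  mean(abnormal)
}

# One-way ANOVA sums of squares via stats::lm/anova, one ion at a time.
brute_eta2 <- function(x, labels) {
  apply(x, 2, function(v) {
    if (var(v) == 0) return(NA_real_)
    a <- anova(lm(v ~ factor(labels)))
    a[["Sum Sq"]][1] / sum(a[["Sum Sq"]])
  })
}

# Direct contingency/entropy NMI with explicit loops.
brute_nmi <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  n <- length(a)
  ha <- 0
  for (v in ua) {
    p <- mean(a == v)
    ha <- ha - p * log(p)
  }
  hb <- 0
  for (v in ub) {
    p <- mean(b == v)
    hb <- hb - p * log(p)
  }
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (va in ua) {
    for (vb in ub) {
      pij <- mean(a == va & b == vb)
      if (pij > 0) mi <- mi + pij * log(pij / (mean(a == va) * mean(b == vb)))
    }
  }
  mi / ((ha + hb) / 2)
}

# Spearman rho from first principles: Pearson correlation of average ranks.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Expected SNS of an i.i.d. continuous image on a full n_rows x n_cols grid:
# binarization is ~Bernoulli(1/2) per pixel, so P(abnormal | m neighbors) =
# P(Binomial(m, 1/2) > m/2), enumerated per neighbor-count class
# (4 corners m=3, edge pixels m=5, interior m=8).
expected_iid_sns <- function(n_rows, n_cols) {
  p_abn <- function(m) sum(dbinom(seq_len(m)[2 * seq_len(m) > m], m, 0.5))
  n <- n_rows * n_cols
  n_corner <- 4
  n_edge <- 2 * (n_rows - 2) + 2 * (n_cols - 2)
  n_int <- n - n_corner - n_edge
  (n_corner * p_abn(3) + n_edge * p_abn(5) + n_int * p_abn(8)) / n
}

# A small phantom suite: ground truth plus graded label corruptions.
corruption_family <- function(ph, fractions = c(0, 0.05, 0.1, 0.2, 0.3), seed = 1) {
  labs <- lapply(seq_along(fractions), function(i) {
    add_label_noise(ph$truth, fractions[i], seed = seed + i)
  })
  names(labs) <- sprintf("corrupt_%02.0f", 100 * fractions)
  labs
}

# append a shuffled copy of ion j as a new column
cbind_shuffled <- function(ds, j, seed) {
  df <- as_tibble(ds)
  shuf <- shuffle_ion(ds, j, seed = seed)
  df[[paste0("shuf_", j)]] <- shuf$intensities[, j]
  as_msi_dataset(df)
}
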