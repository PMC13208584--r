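test_that("PAS analytic geometries behave as derived", {
  ds <- grid_dataset(6, 6)
  expect_equal(compute_pas(rep(1, 36), ds), 0)
  stripes <- ds$coords$row %% 2
  expect_equal(compute_pas(stripes, ds), 1)
  halves <- as.integer(ds$coords$col < 3)
  expect_equal(compute_pas(halves, ds), 0)
})

test_that("PAS matches the brute-force oracle on random masked grids", {
  set.seed(101)
  for (rep in 1:100) {
    ds <- grid_dataset(8, 8, drop = sample(64, sample(5:20, 1)))
    k <- sample(2:4, 1)
    labels <- sample(k, n_pixels(ds), replace = TRUE)
    expect_identical(compute_pas(labels, ds), brute_pas(labels, ds))
  }
})

test_that("PAS is relabeling-invariant and rises with label noise", {
  ph <- generate_phantom(phantom_spec(n_rows = 16, n_cols = 16, seed = 4))
  labels <- ph$truth
  perm <- sample(max(labels))
  expect_equal(compute_pas(perm[labels], ph$dataset), compute_pas(labels, ph$dataset))

  mean_pas <- vapply(c(0.05, 0.15, 0.3, 0.45), function(f) {
    mean(vapply(1:10, function(s) {
      compute_pas(add_label_noise(labels, f, seed = s), ph$dataset)
    }, numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(mean_pas))
})

test_that("eta-squared analytic cases and the ANOVA oracle agree", {
  ds <- grid_dataset(6, 6)
  labels <- rep(1:3, each = 12)
  # distinct constant per cluster -> eta2 = 1
  df <- as_tibble(ds)
  df$pure <- c(1, 5, 9)[labels]
  # two clusters, identical means, nonzero spread -> eta2 = 0
  df$flat <- rep(c(0, 2), 18) # alternating within each cluster: mean 1 everywhere
  ds2 <- as_msi_dataset(df)
  e <- compute_eta2(ds2, labels)
  expect_equal(e$eta2[e$ion_id == "pure"], 1)
  expect_equal(e$eta2[e$ion_id == "flat"], 0)

  set.seed(11)
  for (rep in 1:10) {
    df <- expand.grid(x = 0:11, y = 0:11)
    for (j in 1:10) df[[paste0("i", j)]] <- rexp(144)
    dsr <- as_msi_dataset(df)
    lab <- sample(4, 144, replace = TRUE)
    expect_equal(
      compute_eta2(dsr, lab)$eta2,
      unname(brute_eta2(dsr$intensities, lab)),
      tolerance = 1e-10
    )
  }
})

test_that("eta-squared is affine-invariant and internally consistent", {
  ph <- generate_phantom(phantom_spec(n_rows = 10, n_cols = 10, seed = 6))
  lab <- sample(3, 100, replace = TRUE)
  e1 <- compute_eta2(ph$dataset, lab)$eta2

  df <- as_tibble(ph$dataset)
  for (j in seq(3, ncol(df))) df[[j]] <- 2.5 * df[[j]] + 7
  e2 <- compute_eta2(as_msi_dataset(df), lab)$eta2
  expect_equal(e1, e2, tolerance = 1e-10)

  # eta2 = 1 - SSW/SST computed independently
  x <- ph$dataset$intensities
  ssw <- vapply(seq_len(ncol(x)), function(j) {
    sum(tapply(x[, j], lab, function(v) sum((v - mean(v))^2)))
  }, numeric(1))
  sst <- vapply(seq_len(ncol(x)), function(j) sum((x[, j] - mean(x[, j]))^2), numeric(1))
  expect_equal(e1, 1 - ssw / sst, tolerance = 1e-12)
})

test_that("zero-variance ions are excluded, not scored", {
  df <- expand.grid(x = 0:3, y = 0:3)
  df$const <- 5
  df$vary <- runif(16)
  ds <- as_msi_dataset(df)
  lab <- rep(1:2, 8)
  e <- compute_eta2(ds, lab)
  expect_true(is.na(e$eta2[e$ion_id == "const"]))
  rep <- evaluate_clustering(ds, lab)
  expect_equal(rep$n_excluded_ions, 1L)
  expect_equal(rep$median_eta2, e$eta2[e$ion_id == "vary"])

  df_all <- expand.grid(x = 0:3, y = 0:3)
  df_all$a <- 1
  expect_error(compute_eta2(as_msi_dataset(df_all), lab), "zero variance")
})

test_that("median eta2 follows the standard median", {
  expect_equal(median_eta2(c(0.2, 0.8, 0.5)), 0.5)
  expect_equal(median_eta2(c(0.2, 0.4, 0.6, 0.8)), 0.5)
  expect_equal(median_eta2(rep(0.37, 5)), 0.37)
  expect_error(median_eta2(numeric(0)), "empty")
  expect_error(median_eta2(c(NA_real_, NA_real_)), "empty")
})

test_that("NMI handles identity, relabeling and degenerate partitions", {
  a <- sample(4, 200, replace = TRUE)
  expect_equal(compute_nmi(a, a), 1)
  expect_equal(compute_nmi(a, c(9, 2, 7, 5)[a]), 1)
  expect_equal(compute_nmi(rep(1, 50), rep(2, 50)), 1) # both entropies zero
  expect_equal(compute_nmi(rep(1, 50), rep(1:2, 25)), 0) # one entropy zero
  expect_error(compute_nmi(1:4, 1:5), "equal length")
})

test_that("NMI agrees with the contingency-entropy oracle", {
  set.seed(21)
  for (rep in 1:50) {
    a <- sample(sample(2:6, 1), 200, replace = TRUE)
    b <- sample(sample(2:6, 1), 200, replace = TRUE)
    expect_equal(compute_nmi(a, b), brute_nmi(a, b), tolerance = 1e-12)
  }
})

test_that("pairwise NMI matrices are symmetric with unit diagonal", {
  set.seed(31)
  labs <- lapply(1:5, function(i) sample(3, 100, replace = TRUE))
  names(labs) <- paste0("m", 1:5)
  M <- pairwise_nmi(labs)
  expect_identical(M, t(M))
  expect_equal(diag(M), setNames(rep(1, 5), paste0("m", 1:5)))
  expect_true(all(M >= 0 & M <= 1))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(M[i, j], compute_nmi(labs[[i]], labs[[j]]))
    }
  }
  expect_identical(pairwise_nmi(labs[c(1, 1)])[1, 2], 1)
  expect_error(pairwise_nmi(list(1:4, 1:5)), "equal length")
})

test_that("Moran's I separates compact, random and alternating labelings", {
  ds <- grid_dataset(10, 10)
  halves <- as.integer(ds$coords$col < 5) + 1L
  expect_gt(compute_morans_i(halves, ds), 0.8)

  stripes <- ds$coords$row %% 2 + 1
  expect_lt(compute_morans_i(stripes, ds), 0)

  ds20 <- grid_dataset(20, 20)
  vals <- vapply(1:50, function(s) {
    set.seed(s)
    compute_morans_i(sample(2, 400, replace = TRUE), ds20)
  }, numeric(1))
  expect_lt(abs(mean(vals) - (-1 / 399)), 0.05)

  expect_error(compute_morans_i(rep(1, 100), ds), "constant")
})

test_that("PAS and Moran's I disagree in direction on graded corruption", {
  ph <- generate_phantom(phantom_spec(n_rows = 16, n_cols = 16, seed = 8))
  labs <- corruption_family(ph, fractions = c(0, 0.1, 0.2, 0.3, 0.4))
  pas <- vapply(labs, compute_pas, numeric(1), dataset = ph$dataset)
  mor <- vapply(labs, compute_morans_i, numeric(1), dataset = ph$dataset)
  expect_lt(cor(pas, mor, method = "spearman"), 0)
})

test_that("median eta2 and mean silhouette rank clusterings concordantly", {
  ph <- generate_phantom(phantom_spec(n_rows = 16, n_cols = 16, seed = 12))
  labs <- corruption_family(ph, fractions = c(0, 0.1, 0.25, 0.4), seed = 7)
  x <- scale(log1p(ph$dataset$intensities))
  d <- dist(x)
  eta <- vapply(labs, function(l) median_eta2(compute_eta2(ph$dataset, l)), numeric(1))
  sil <- vapply(labs, function(l) {
    mean(cluster::silhouette(as.integer(l), d)[, "sil_width"])
  }, numeric(1))
  expect_gt(cor(eta, sil, method = "spearman"), 0)
})

test_that("evaluate_clustering assembles a coherent report", {
  ph <- generate_phantom(phantom_spec(n_rows = 12, n_cols = 12, seed = 14))
  rep <- evaluate_clustering(ph$dataset, ph$truth, reference = ph$truth,
                             morans_i = TRUE, method = "truth")
  g <- glance(rep)
  expect_equal(g$method, "truth")
  expect_equal(g$nmi_vs_reference, 1)
  expect_equal(g$pas, compute_pas(ph$truth, ph$dataset))
  expect_equal(g$median_eta2, median(tidy(rep)$eta2, na.rm = TRUE))
  expect_gt(g$morans_i_median, 0.5)
  expect_error(
    evaluate_clustering(ph$dataset, ph$truth, reference = 1:3),
    "aligned"
  )
})
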