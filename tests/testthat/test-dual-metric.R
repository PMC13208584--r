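test_that("dual-metric thresholds use strict inequalities", {
  m <- tibble::tibble(
    method = c("a", "b", "c"),
    pas = c(0.10, 0.20, 0.10),
    median_eta2 = c(0.60, 0.60, 0.50)
  )
  d <- evaluate_dual(m)
  expect_equal(d$pass_both, c(TRUE, FALSE, FALSE))
  expect_equal(d$pass_pas, c(TRUE, FALSE, TRUE))
  expect_equal(d$pass_eta2, c(TRUE, TRUE, FALSE))
  expect_error(evaluate_dual(m, pas_threshold = 1.2), "\\[0, 1\\]")
  expect_error(evaluate_dual(m, eta2_threshold = -0.1), "\\[0, 1\\]")
})

test_that("pass_both is monotone when thresholds relax", {
  set.seed(41)
  m <- tibble::tibble(
    method = sprintf("m%02d", 1:20),
    pas = runif(20, 0, 0.5),
    median_eta2 = runif(20, 0.2, 0.8)
  )
  for (i in 1:20) {
    t1 <- sort(runif(2, 0.05, 0.45))
    e1 <- sort(runif(2, 0.25, 0.75), decreasing = TRUE)
    strict <- evaluate_dual(m, t1[1], e1[1])$pass_both
    relaxed <- evaluate_dual(m, t1[2], e1[2])$pass_both
    expect_true(all(relaxed[strict]))
  }
})

test_that("composite ranking follows dominance and breaks ties by name", {
  m <- tibble::tibble(
    method = c("A", "B"),
    pas = c(0.1, 0.3),
    median_eta2 = c(0.7, 0.4)
  )
  r <- composite_ranking(m)
  expect_equal(r$method[r$composite_rank == 1], "A")

  m2 <- tibble::tibble(
    method = c("B", "A"),
    pas = c(0.3, 0.1),
    median_eta2 = c(0.7, 0.4)
  )
  r2 <- composite_ranking(m2)
  expect_equal(length(unique(r2$composite_score)), 1)
  expect_equal(r2$method, c("A", "B"))
})

test_that("composite ranking matches a rank-sum oracle and is monotone-invariant", {
  set.seed(51)
  m <- tibble::tibble(
    method = sprintf("m%02d", 1:30),
    pas = round(runif(30, 0, 0.6), 2),       # rounding forces some ties
    median_eta2 = round(runif(30, 0.2, 0.9), 2)
  )
  r <- composite_ranking(m)
  oracle <- (rank(m$pas) + rank(-m$median_eta2)) / 2
  expect_equal(
    r$composite_score[match(m$method, r$method)],
    oracle
  )

  # strictly monotone transform of all PAS values leaves the order unchanged
  m_t <- dplyr::mutate(m, pas = exp(3 * pas) - 0.5)
  expect_equal(composite_ranking(m_t)$method, r$method)
})

test_that("pass rates summarize the method-by-dataset grid", {
  grid <- tidyr::expand_grid(method = c("ssc", "kmeans"), dataset = sprintf("d%02d", 1:12))
  grid$pass_both <- c(rep(c(TRUE, FALSE), c(9, 3)), rep(FALSE, 12))
  s <- pass_rate_summary(grid)
  expect_equal(s$pass_rate[s$method == "ssc"], 0.75)
  expect_equal(s$n_pass[s$method == "ssc"], 9)
  expect_equal(s$pass_rate[s$method == "kmeans"], 0)
  expect_equal(sum(s$n_pass), sum(grid$pass_both))

  # failed runs (NA) count as non-passing
  grid$pass_both[1] <- NA
  expect_equal(pass_rate_summary(grid)$n_pass[1], 8)

  expect_error(pass_rate_summary(grid[-1, ]), "rectangular")
})

test_that("threshold sensitivity is nested from strict to relaxed", {
  set.seed(61)
  m <- tidyr::expand_grid(method = sprintf("m%d", 1:8), dataset = sprintf("d%d", 1:4))
  m$pas <- runif(32, 0.05, 0.35)
  m$median_eta2 <- runif(32, 0.3, 0.7)
  tab <- threshold_sensitivity(m)
  wide <- tidyr::pivot_wider(tab[, c("setting", "method", "n_pass")],
                             names_from = "setting", values_from = "n_pass")
  expect_true(all(wide$strict <= wide$default))
  expect_true(all(wide$default <= wide$relaxed))

  same <- threshold_sensitivity(m, settings = list(a = c(0.2, 0.5), b = c(0.2, 0.5)))
  expect_equal(
    same$n_pass[same$setting == "a"],
    same$n_pass[same$setting == "b"]
  )

  expect_error(
    threshold_sensitivity(m, settings = list(a = c(0.25, 0.5), b = c(0.2, 0.5))),
    "nested"
  )
})

test_that("external validation recovers graded degradation and a perfect rho", {
  ph <- generate_phantom(phantom_spec(n_rows = 16, n_cols = 16, seed = 17))
  fr <- seq(0.05, 0.45, by = 0.05)
  labs <- list(truth = ph$truth)
  for (i in seq_along(fr)) {
    labs[[sprintf("noise_%02d", round(100 * fr[i]))]] <-
      add_label_noise(ph$truth, fr[i], seed = 300 + i)
  }
  nmis <- vapply(labs, compute_nmi, numeric(1), labels_b = ph$truth)
  expect_true(all(diff(nmis) < 0))

  metrics <- purrr::map_dfr(names(labs), function(nm) {
    glance(evaluate_clustering(ph$dataset, labs[[nm]], method = nm))
  })
  ev <- external_validation(labs, ph$truth, metrics)
  expect_equal(ev$table$nmi_vs_reference[ev$table$method == "truth"], 1)
  expect_equal(
    ev$spearman_rho,
    brute_spearman(
      rank(ev$table$composite_score),
      rank(-ev$table$nmi_vs_reference)
    ),
    tolerance = 1e-12
  )
  expect_gt(ev$spearman_rho, 0.9)

  expect_error(external_validation(labs, ph$truth[-1], metrics), "aligned")
  expect_error(external_validation(labs[1:2], ph$truth, metrics), "3 methods")
})
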