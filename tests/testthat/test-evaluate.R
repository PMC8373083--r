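test_that("per-cell correlation is 1 for identical and rowwise-affine copies", {
  x <- tiny_scep(n_cells = 10, n_genes = 80, seed = 3)
  cc <- cell_correlations(x, x)
  expect_equal(unname(cc$per_cell_rho), rep(1, 10), tolerance = 1e-12)
  expect_equal(cc$mean_rho, 1, tolerance = 1e-12)
  cc2 <- cell_correlations(x, 2 * x + 7)
  expect_equal(unname(cc2$per_cell_rho), rep(1, 10), tolerance = 1e-12)
})

test_that("per-cell correlation matches the textbook formula on a toy case", {
  X <- rbind(c(1, 2, 3, 5), c(0, 1, 0, 2), c(4, 4, 1, 0))
  Xh <- rbind(c(2, 1, 4, 4), c(1, 1, 0, 3), c(5, 3, 2, 1))
  cc <- cell_correlations(X, Xh)
  for (i in 1:3) {
    expect_equal(unname(cc$per_cell_rho[i]), pearson_manual(X[i, ], Xh[i, ]),
                 tolerance = 1e-12)
  }
  expect_equal(cc$mean_rho, mean(cc$per_cell_rho), tolerance = 1e-12)
})

test_that("zero-variance cells are excluded from the mean with a warning", {
  X <- rbind(c(1, 1, 1), c(1, 2, 3))
  Xh <- rbind(c(1, 2, 3), c(1, 2, 3.5))
  expect_warning(cc <- cell_correlations(X, Xh), "zero variance")
  expect_true(is.na(cc$per_cell_rho[1]))
  expect_equal(cc$mean_rho, cor(c(1, 2, 3), c(1, 2, 3.5)))
  expect_error(cell_correlations(X, Xh[, 1:2]), "identical shape")
})

test_that("detection sensitivity counts and stratifies lost genes", {
  X <- cbind(a = c(2, 0), b = c(0, 3), c = c(1, 1), d = c(0.4, 0.2))
  expect_equal(detection_sensitivity(X, X)$detection_fraction, 1)
  Xh <- X; Xh[, "b"] <- 0
  det <- detection_sensitivity(X, Xh)
  expect_equal(det$detected_original, 4L)
  expect_equal(det$detected_inferred, 3L)
  expect_equal(det$detection_fraction, 0.75)
  # exactly one lost gene has original total > 1
  expect_equal(det$lost_genes_above_threshold, 1L)
  Xh2 <- X; Xh2[, "d"] <- 0
  expect_equal(detection_sensitivity(X, Xh2)$lost_genes_above_threshold, 0L)
})

test_that("raising the detection tolerance never detects more genes", {
  x <- tiny_scep(seed = 17)
  xh <- x * matrix(runif(length(x), 0.5, 1.5), nrow(x))
  tols <- c(0.001, 0.1, 1, 10, 100)
  counts <- vapply(tols, function(tt) {
    detection_sensitivity(x, xh, detect_tol = tt)$detected_inferred
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gene correlation profile bins genes like an independent sort-and-split", {
  X <- cbind(g1 = c(1, 0, 0, 0), g2 = c(1, 2, 0, 0), g3 = c(1, 2, 3, 0),
             g4 = c(1, 2, 3, 4), g5 = c(5, 5, 1, 2))
  Xh <- X + matrix(rnorm(20, sd = 0.1), 4)
  prof <- gene_correlation_profile(X, Xh, ranking = "sparsity_level",
                                   bins = 5)
  # independent sort-and-split: ascending expressing-cell count, ties in
  # column order, one gene per bin here
  cells <- colSums(X > 0)            # 1, 2, 3, 4, 4
  oracle_bins <- integer(5)
  oracle_bins[order(cells, seq_along(cells))] <- seq_len(5)
  got <- prof$per_gene$bin[match(names(cells), prof$per_gene$gene)]
  expect_equal(got, oracle_bins)

  # identical matrices: every defined gene correlates at 1
  p2 <- gene_correlation_profile(X, X)
  expect_true(all(abs(p2$per_gene$correlation - 1) < 1e-12))

  # ranking orientation: total_expression ranks g5 (largest total) last
  p3 <- gene_correlation_profile(X, Xh, ranking = "total_expression", bins = 5)
  expect_equal(p3$per_gene$bin[p3$per_gene$gene == "g5"], 5L)
})

test_that("library savings reproduce the published accounting", {
  s <- library_savings(54, 28)
  expect_identical(s$libraries_saved, 26L)
  expect_equal(s$savings_percent, 48.15)
  expect_identical(library_savings(64, 35)$libraries_saved, 29L)
  s0 <- library_savings(10, 10)
  expect_identical(s0$libraries_saved, 0L)
  expect_equal(s0$savings_percent, 0)
})

test_that("the evaluation report is internally consistent", {
  x <- tiny_scep(n_cells = 12, n_genes = 90, seed = 29)
  M <- generate_measurement_matrix(9, 12, 0.5, seed = 30)
  xh <- ridge_solve(M, measure(M, x))
  rep <- evaluate_reconstruction(x, xh, n_pools = 9)
  expect_equal(rep$mean_rho,
               mean(rep$per_cell_rho[is.finite(rep$per_cell_rho)]))
  expect_equal(unname(diag(rep$cell_by_cell_corr)),
               unname(rep$per_cell_rho), tolerance = 1e-12)
  expect_identical(rep$libraries_saved, 3L)
  expect_output(print(rep), "mean per-cell Pearson")
})
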