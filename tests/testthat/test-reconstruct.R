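test_that("ridge closed form matches hand arithmetic and the invertible limit", {
  x <- ridge_solve(diag(2), cbind(c(2, 3)), lambda = 0.01)
  expect_equal(as.vector(x), c(2, 3) / 1.01, tolerance = 1e-12)

  withr::with_seed(8, {
    M <- matrix(rnorm(16), 4)
    y <- cbind(rnorm(4))
  })
  expect_equal(as.vector(ridge_solve(M, y, lambda = 1e-12)),
               as.vector(solve(M, y)), tolerance = 1e-6)
})

test_that("ridge agrees with an augmented least-squares oracle to 1e-10", {
  withr::with_seed(13, {
    for (i in 1:25) {
      M <- matrix(rnorm(60), 6, 10)
      Y <- matrix(rnorm(6 * 3), 6)
      lam <- 0.01
      ours <- ridge_solve(M, Y, lambda = lam)
      # independent formulation: ridge as least squares on [M; sqrt(lam) I]
      aug <- rbind(M, sqrt(lam) * diag(10))
      oracle <- qr.coef(qr(aug), rbind(Y, matrix(0, 10, 3)))
      expect_lt(max(abs(ours - oracle)), 1e-10)
    }
  })
})

test_that("basis pursuit solves the hand-checkable cases", {
  M <- measurement_matrix(rbind(c(1, 1, 0), c(0, 1, 1)))
  # zero measurements: zero is the minimum-l1 feasible point
  expect_equal(as.vector(basis_pursuit_solve(M, cbind(c(0, 0)))),
               c(0, 0, 0))
  # feasible line x = (a, 1-a, a): |a| + |1-a| + |a| is minimized at a = 0
  x <- basis_pursuit_solve(M, cbind(c(1, 1)), bp_tight())
  expect_equal(as.vector(x), c(0, 1, 0), tolerance = 1e-6)
  expect_equal(sum(abs(x)), 1, tolerance = 1e-6)
})

test_that("basis pursuit exactly recovers 1-sparse signals and matches enumeration", {
  M <- generate_measurement_matrix(6, 8, 0.5, seed = 11)
  stopifnot(!any(duplicated(t(unclass(M)))), all(colSums(M) > 0))
  X <- diag(8)                       # signal j: amplitude 1 at position j
  Xhat <- basis_pursuit_solve(M, measure(M, X), bp_tight())
  expect_lt(max(abs(Xhat - X)), 1e-6)
  for (j in c(1, 4, 8)) {
    oracle <- brute_force_bp(unclass(M), unclass(measure(M, X))[, j], k_max = 1)
    expect_equal(as.vector(Xhat[, j]), oracle, tolerance = 1e-6)
  }
})

test_that("basis pursuit matches brute-force support enumeration for 2-sparse signals", {
  M <- generate_measurement_matrix(9, 12, 0.5, seed = 24)
  stopifnot(!any(duplicated(t(unclass(M)))))  # all cells identifiable
  withr::with_seed(5, {
    supports <- list(c(1, 7), c(3, 12), c(5, 6), c(2, 10))
    for (s in supports) {
      x0 <- numeric(12); x0[s] <- c(2, 1.5)
      y <- as.vector(unclass(M) %*% x0)
      xhat <- basis_pursuit_solve(M, cbind(y), bp_tight())
      oracle <- brute_force_bp(unclass(M), y, k_max = 2)
      expect_equal(as.vector(xhat), oracle, tolerance = 1e-5)
      expect_equal(as.vector(xhat), x0, tolerance = 1e-5)
    }
  })
})

test_that("nonnegative basis pursuit never returns negatives and stays feasible", {
  M <- generate_measurement_matrix(7, 10, 0.5, seed = 31)
  withr::with_seed(6, {
    x0 <- numeric(10); x0[c(2, 5, 9)] <- rexp(3) * 10
  })
  y <- unclass(M) %*% cbind(x0)
  xhat <- basis_pursuit_solve(M, y, bp_tight(nonneg = TRUE))
  expect_gt(min(xhat), -1e-8 * max(y))   # nonnegative to solver tolerance
  expect_lt(max(abs(unclass(M) %*% xhat - y)), 1e-6 * max(y))
})

test_that("with pools >= cells both solvers invert noiseless measurements", {
  x <- tiny_scep(n_cells = 12, n_genes = 60, seed = 14)
  # random invertible square design: basis pursuit inverts it exactly
  M <- generate_measurement_matrix(12, 12, 0.5, seed = 20)
  stopifnot(abs(det(unclass(M))) > 1e-6)
  Y <- measure(M, x)
  expect_lt(max(abs(basis_pursuit_solve(M, Y) - x)), 1e-6 * max(x))
  # ridge's lambda bias is amplified by the design's conditioning; on the
  # identity-like uncompressed control (one cell per pool) it rescales
  # uniformly and per-cell Pearson correlation is exactly 1
  rr <- cell_correlations(x, ridge_solve(M, Y))
  expect_gt(rr$mean_rho, 0.98)
  I <- measurement_matrix(diag(12))
  ri <- cell_correlations(x, ridge_solve(I, measure(I, x)))
  expect_gt(ri$mean_rho, 1 - 1e-9)
})

test_that("inconsistent overdetermined measurements are flagged infeasible", {
  M <- measurement_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
  y <- cbind(c(1, 1, 5))             # rank-2 design cannot reach this y
  expect_warning(out <- basis_pursuit_solve(M, y), "feasibility tolerance")
  expect_gt(attr(out, "feasibility")[1], 1)
})

test_that("cell partitioning reproduces the published block layouts", {
  p1 <- partition_cells(5063, 500, 1600)
  expect_equal(p1$block_sizes, c(rep(500L, 9), 563L))
  expect_equal(p1$pools_per_block, c(rep(158L, 9), 178L))

  p2 <- partition_cells(45423, 500, 22700)
  expect_equal(length(p2$block_sizes), 91L)
  expect_equal(p2$block_sizes, c(rep(500L, 90), 423L))
  expect_equal(p2$pools_per_block, c(rep(250L, 90), 200L))

  p3 <- partition_cells(10, 20, 5)
  expect_equal(p3$block_sizes, 10L)
  expect_equal(p3$pools_per_block, 5L)

  expect_error(partition_cells(100, 10, 5), "less than the number of blocks")
})

test_that("block reconstruction matches the manual per-block pipeline", {
  x <- tiny_scep(n_cells = 24, n_genes = 150, seed = 33)
  cfg <- solver_config("ridge")

  # single block: identical to the unblocked path at the derived seed
  part1 <- partition_cells(24, 30, 14)
  got <- block_reconstruct(x, part1, cfg, inclusion_prob = 0.5, seed = 101)
  M <- generate_measurement_matrix(14, 24, 0.5, seed = derive_seed(101, 1))
  want <- ridge_solve(M, measure(M, x))
  expect_identical(got[, ], want[, ])

  # two blocks: row-concatenation of the two independent recoveries
  part2 <- partition_cells(24, 12, 16)
  got2 <- block_reconstruct(x, part2, cfg, inclusion_prob = 0.5, seed = 55)
  halves <- lapply(1:2, function(b) {
    rows <- seq(part2$starts[b], length.out = part2$block_sizes[b])
    Mb <- generate_measurement_matrix(part2$pools_per_block[b], 12, 0.5,
                                      seed = derive_seed(55, b))
    ridge_solve(Mb, measure(Mb, x[rows, ]))
  })
  expect_identical(unname(got2[, ]), unname(do.call(rbind, halves)[, ]))
})

test_that("block reconstruction is identical for any worker count", {
  x <- tiny_scep(n_cells = 30, n_genes = 100, seed = 44)
  part <- partition_cells(30, 10, 18)
  serial <- block_reconstruct(x, part, solver_config("ridge", n_workers = 1),
                              seed = 7, turbulence = 0.2)
  parallel <- block_reconstruct(x, part, solver_config("ridge", n_workers = 2),
                                seed = 7, turbulence = 0.2)
  expect_identical(serial, parallel)
})

test_that("blocked ridge recovery tracks the unblocked run at matched pool ratio", {
  x <- simulate_scep(synthetic_profile_spec(400, 400, 0.25, n_types = 4,
                                            seed = 61))
  cfg <- solver_config("ridge")
  M <- generate_measurement_matrix(240, 400, 0.5, seed = derive_seed(62, 1))
  rho_full <- cell_correlations(x, ridge_solve(M, measure(M, x)))$mean_rho
  part <- partition_cells(400, 100, 240)
  rho_block <- cell_correlations(
    x, block_reconstruct(x, part, cfg, seed = 62))$mean_rho
  expect_lt(abs(rho_full - rho_block), 0.02)
})

test_that("thresholding floors, clamps and flags undetected genes", {
  expect_equal(as.vector(threshold_expression(cbind(c(4.9, 5.0, 7.2)),
                                              floor_value = 5)),
               c(0, 5.0, 7.2))
  x <- matrix(c(-1, 2, 3, 4), 2)
  expect_equal(unclass(threshold_expression(x))[, ],
               matrix(c(0, 2, 3, 4), 2), ignore_attr = TRUE)
  # identity when both stages disabled (negatives aside)
  pos <- matrix(runif(6), 2)
  expect_equal(unclass(threshold_expression(pos, detect_tol = 0))[, ], pos,
               ignore_attr = TRUE)
  # a gene entirely below 0.001 total is flagged, and only that one
  m <- cbind(gene_a = c(1e-5, 2e-5), gene_b = c(3, 4))
  th <- threshold_expression(m, detect_tol = 0.001)
  expect_identical(attr(th, "undetected_genes"), "gene_a")
  dropped <- threshold_expression(m, detect_tol = 0.001, drop_undetected = TRUE)
  expect_equal(ncol(dropped), 1L)
})
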