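test_that("generated designs have the requested shape, density and validity", {
  m <- generate_measurement_matrix(40, 54, 0.5, seed = 1)
  expect_equal(dim(m), c(40L, 54L))
  expect_true(all(m %in% c(0, 1)))
  expect_true(all(rowSums(m) > 0) && all(colSums(m) > 0))

  # probability-1 degenerate case: the all-ones matrix
  expect_equal(unclass(generate_measurement_matrix(3, 4, 1, seed = 9))[, ],
               matrix(1, 3, 4), ignore_attr = TRUE)

  # empirical ones-fraction lands inside an exact 99% binomial interval
  m3 <- generate_measurement_matrix(200, 100, 0.3, seed = 7)
  n <- 200L * 100L
  lo <- qbinom(0.005, n, 0.3); hi <- qbinom(0.995, n, 0.3)
  expect_gte(sum(m3), lo)
  expect_lte(sum(m3), hi)
})

test_that("design generation is seed-deterministic and leaves the caller RNG alone", {
  a <- generate_measurement_matrix(20, 30, 0.5, seed = 123)
  b <- generate_measurement_matrix(20, 30, 0.5, seed = 123)
  expect_identical(unclass(a), unclass(b))
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(generate_measurement_matrix(5, 5, 0.8, seed = 5))
  expect_identical(runif(1), before)
})

test_that("impossible densities fail with a clear message after the retry budget", {
  expect_error(
    suppressMessages(generate_measurement_matrix(6, 6, 0.01, seed = 1,
                                                 max_retries = 20)),
    "no valid.*design")
})

test_that("the RIP pool-count heuristic matches closed-form arithmetic", {
  expect_identical(required_pool_count(5, 100), 15L)       # ceil(5 ln 20)
  expect_identical(required_pool_count(7, 7, c_const = 3), 0L)  # K = N
  expect_identical(required_pool_count(1, 2, c_const = 2, log_base = "base2"),
                   2L)
  expect_error(required_pool_count(10, 5), "cannot exceed")
})

test_that("row normalization divides by row sums and preserves zeros", {
  m <- measurement_matrix(rbind(c(1, 1, 0, 1), c(1, 0, 1, 0)))
  nm <- normalize_rows(m)
  expect_equal(nm[1, ], c(1/3, 1/3, 0, 1/3), ignore_attr = TRUE)
  expect_equal(nm[2, ], c(0.5, 0, 0.5, 0), ignore_attr = TRUE)
  expect_equal(unclass(normalize_rows(measurement_matrix(diag(4))))[, ],
               diag(4), ignore_attr = TRUE)
  bad <- matrix(c(1, 0, 1, 0), 2, 2)
  bad[2, ] <- 0
  expect_error(normalize_rows(bad), "pool\\(s\\) 2")
})

test_that("row sums are exactly 1 within 1e-12 across random designs", {
  for (s in 1:20) {
    m <- generate_measurement_matrix(sample(3:30, 1), sample(5:40, 1),
                                     runif(1, 0.2, 0.9), seed = s)
    nm <- normalize_rows(m)
    expect_lt(max(abs(rowSums(nm) - 1)), 1e-12)
    expect_identical(nm == 0, unclass(m) == 0, ignore_attr = TRUE)
  }
})

test_that("pool-design export reads off memberships and round-trips", {
  m <- measurement_matrix(rbind(c(1, 0, 1), c(0, 1, 0)))
  tab <- export_pool_design(m, c("A", "B", "C"))
  expect_equal(tab$cell_id[tab$pool_id == "pool1"], c("A", "C"))
  expect_equal(tab$cell_id[tab$pool_id == "pool2"], "B")
  expect_error(export_pool_design(m, c("A", "B")), "2 cell labels for 3")

  # conservation + round-trip identity at experimental scale
  big <- generate_measurement_matrix(40, 54, 0.5, seed = 4)
  tab2 <- export_pool_design(big)
  expect_identical(nrow(tab2), as.integer(sum(big)))
  expect_equal(length(unique(tab2$pool_id)), 40L)
  back <- import_pool_design(tab2, pool_ids = rownames(big),
                             cell_labels = colnames(big))
  expect_equal(unclass(back)[, ], unclass(big)[, ], ignore_attr = TRUE)
})
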