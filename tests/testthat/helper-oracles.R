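# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, exhaustive enumeration and
# textbook formulas only.

# plain triple-loop matrix product
naive_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (k in seq_len(ncol(A)))
        out[i, j] <- out[i, j] + A[i, k] * B[k, j]
  out
}

# textbook Pearson correlation
pearson_manual <- function(x, y) {
  xm <- sum(x) / length(x); ym <- sum(y) / length(y)
  sum((x - xm) * (y - ym)) /
    sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

# exhaustive minimum-l1 solver: enumerate all supports up to size k_max,
# solve least squares on each support, keep feasible solutions (||Mx-y||
# small), return the one with smallest l1 norm. Exact for k-sparse ground
# truth when the design identifies it.
brute_force_bp <- function(M, y, k_max, feas_tol = 1e-8) {
  n <- ncol(M)
  best <- NULL; best_l1 <- Inf
  for (k in 0:k_max) {
    supports <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(n, k), 2)
    for (s in supports) {
      x <- numeric(n)
      if (length(s)) {
        fit <- qr.coef(qr(M[, s, drop = FALSE]), y)
        if (anyNA(fit)) next
        x[s] <- fit
      }
      if (max(abs(M %*% x - y)) <= feas_tol * max(1, max(abs(y)))) {
        if (sum(abs(x)) < best_l1 - 1e-12) {
          best <- x; best_l1 <- sum(abs(x))
        }
      }
    }
  }
  best
}

# small, fast synthetic fixture used by several files
tiny_scep <- function(n_cells = 16, n_genes = 120, frac = 0.3, types = 2,
                      seed = 42) {
  simulate_scep(synthetic_profile_spec(n_cells, n_genes, frac,
                                       n_types = types, seed = seed))
}

# a tight solver config for oracle-equivalence checks
bp_tight <- function(nonneg = FALSE) {
  solver_config("basis_pursuit", max_iter = 20000, rel_tol = 1e-10,
                nonneg = nonneg)
}
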