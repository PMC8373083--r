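# Recovery of the cells x genes expression matrix from pooled measurements:
# ridge regression (closed form, shared factorization across genes) and
# basis pursuit (equality-constrained l1 minimization solved by ADMM,
# vectorized over gene columns), plus the block-parallel scheme and
# post-reconstruction thresholding.

#' Solver configuration
#'
#' @param method `"ridge"` (l2; closed form, robust to noise, suited to dense
#'   profiles) or `"basis_pursuit"` (l1; favors sparse profiles).
#' @param lambda ridge trade-off between sparsity and accuracy; default 0.01.
#' @param bp_feasibility_tol relative infinity-norm feasibility tolerance for
#'   basis pursuit: a gene's solution is flagged infeasible when
#'   `max|Mx - y| > tol * max(1, max|y|)`.
#' @param nonneg if `TRUE`, basis pursuit constrains the solution to be
#'   nonnegative (expression can't be negative); default `FALSE` so solver
#'   output stays directly comparable to unconstrained oracles. Negative
#'   values are clamped later, in [threshold_expression()].
#' @param n_workers workers for [block_reconstruct()]; results are identical
#'   for any worker count.
#' @param max_iter,rel_tol ADMM iteration cap and relative convergence
#'   tolerance for basis pursuit.
#' @return a `solver_config` list.
#' @export
solver_config <- function(method = c("ridge", "basis_pursuit"),
                          lambda = 0.01, bp_feasibility_tol = 1e-8,
                          nonneg = FALSE, n_workers = 1L,
                          max_iter = 500L, rel_tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(lambda > 0, bp_feasibility_tol > 0, n_workers >= 1,
            max_iter >= 1, rel_tol > 0)
  structure(list(method = method, lambda = lambda,
                 bp_feasibility_tol = bp_feasibility_tol,
                 nonneg = isTRUE(nonneg), n_workers = as.integer(n_workers),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol),
            class = "solver_config")
}

#' Ridge-regression reconstruction
#'
#' Closed-form l2-regularized recovery, gene by gene:
#' \deqn{\hat x = (\lambda I + M^T M)^{-1} M^T y.}
#' The Cholesky factorization of \eqn{\lambda I + M^T M} is computed once and
#' reused for every gene column.
#'
#' @param design pools x cells design: a [measurement_matrix()] or, for
#'   TPM-normalized measurements, its [normalize_rows()] version.
#' @param Y pools x genes pooled measurements.
#' @param lambda positive ridge penalty; default 0.01.
#' @return cells x genes reconstructed expression matrix.
#' @export
#' @examples
#' ridge_solve(diag(2), cbind(c(2, 3)), lambda = 0.01)  # y / 1.01
ridge_solve <- function(design, Y, lambda = 0.01) {
  M <- as_dense_matrix(design)
  Y <- as_dense_matrix(Y)
  stopifnot(lambda > 0)
  if (nrow(M) != nrow(Y)) {
    stop_dims("design rows (pools) must match Y rows", nrow(M), nrow(Y))
  }
  A <- crossprod(M)
  diag(A) <- diag(A) + lambda
  R <- tryCatch(chol(A), error = function(e) {
    stop("ridge system numerically singular (should not happen for lambda > 0): ",
         conditionMessage(e), call. = FALSE)
  })
  Xhat <- backsolve(R, backsolve(R, crossprod(M, Y), transpose = TRUE))
  dimnames(Xhat) <- list(colnames(M), colnames(Y))
  Xhat
}

# soft threshold, vectorized
.soft <- function(v, k) sign(v) * pmax(abs(v) - k, 0)

#' Basis-pursuit reconstruction
#'
#' Minimum-l1 recovery, gene by gene: \eqn{\min \|x\|_1} subject to
#' \eqn{M x = y}. All gene columns are solved simultaneously by ADMM
#' (alternating projection onto the affine constraint set with soft
#' thresholding); each column is scaled to unit magnitude before solving and
#' rescaled after, so convergence behaviour is independent of TPM scale.
#' When the design has at least as many pools as cells the constraint
#' determines the solution and it is taken directly by least squares.
#'
#' @inheritParams ridge_solve
#' @param config a [solver_config()]; `nonneg = TRUE` adds `x >= 0`.
#' @return cells x genes reconstructed matrix with attributes
#'   `feasibility` (per-gene max residual `max|Mx - y|`) and
#'   `infeasible_genes` (labels failing `bp_feasibility_tol`); a warning
#'   lists infeasible or non-converged genes.
#' @export
basis_pursuit_solve <- function(design, Y, config = solver_config("basis_pursuit")) {
  M <- as_dense_matrix(design)
  Y <- as_dense_matrix(Y)
  if (nrow(M) != nrow(Y)) {
    stop_dims("design rows (pools) must match Y rows", nrow(M), nrow(Y))
  }
  p <- nrow(M); cc <- ncol(M); g <- ncol(Y)

  dup <- duplicated(t(M)) | colSums(abs(M)) == 0
  if (any(dup)) {
    warning(sprintf("design has %d duplicate or all-zero column(s): those cells are not identifiable",
                    sum(dup)), call. = FALSE)
  }

  scale_y <- apply(abs(Y), 2, max)
  active <- scale_y > 0
  Xhat <- matrix(0, cc, g)

  if (p >= cc) {
    # fully determined (or overdetermined): l1 objective is moot
    qrM <- qr(M)
    if (qrM$rank < cc) {
      warning("design is rank-deficient; least-squares solution returned",
              call. = FALSE)
    }
    Xhat[, active] <- qr.coef(qrM, Y[, active, drop = FALSE])
    Xhat[is.na(Xhat)] <- 0
  } else if (any(active)) {
    Ys <- sweep(Y[, active, drop = FALSE], 2, scale_y[active], `/`)
    # projection onto {x : Mx = y}: x -> x - M^T (M M^T)^{-1} (M x - y)
    MMt <- tcrossprod(M)
    R <- chol(MMt + diag(1e-12 * max(diag(MMt)), p))
    Minv <- function(B) backsolve(R, backsolve(R, B, transpose = TRUE))
    MtMMtinv <- t(Minv(M))                      # c x p
    Py <- MtMMtinv %*% Ys                       # constant part of projection
    proj <- function(V) V - MtMMtinv %*% (M %*% V) + Py

    # rho = 10 (soft threshold 0.1 on unit-scaled columns) converges fastest
    # over the design densities used here; alpha is standard over-relaxation
    rho <- 10; kappa <- 1 / rho; alpha <- 1.6
    Z <- proj(matrix(0, cc, sum(active))); U <- Z * 0
    converged <- FALSE
    for (it in seq_len(config$max_iter)) {
      X <- proj(Z - U)
      Xr <- alpha * X + (1 - alpha) * Z
      Znew <- if (config$nonneg) pmax(Xr + U - kappa, 0) else .soft(Xr + U, kappa)
      U <- U + Xr - Znew
      pri <- sqrt(sum((X - Znew)^2)); dua <- rho * sqrt(sum((Znew - Z)^2))
      Z <- Znew
      eps <- config$rel_tol * max(sqrt(sum(X^2)), sqrt(sum(Z^2)), 1e-12)
      if (pri < eps && dua < eps) { converged <- TRUE; break }
    }
    if (!converged) {
      warning(sprintf("basis pursuit ADMM did not converge in %d iterations (relative tolerance %g)",
                      config$max_iter, config$rel_tol), call. = FALSE)
    }
    # final projection: the returned iterate satisfies Mx = y to machine
    # precision even if the l1 objective is still converging
    Xhat[, active] <- sweep(proj(Z), 2, scale_y[active], `*`)
  }

  dimnames(Xhat) <- list(colnames(M), colnames(Y))
  resid <- apply(abs(M %*% Xhat - Y), 2, max)
  tolv <- config$bp_feasibility_tol * pmax(1, scale_y)
  infeasible <- which(resid > tolv)
  if (length(infeasible)) {
    labs <- colnames(Y) %||% as.character(seq_len(g))
    warning(sprintf("basis pursuit: %d gene(s) exceed the feasibility tolerance (e.g. %s)",
                    length(infeasible),
                    paste(utils::head(labs[infeasible], 5), collapse = ", ")),
            call. = FALSE)
  }
  structure(Xhat, feasibility = resid, infeasible_genes = names(infeasible))
}

#' Reconstruct expression from pooled measurements
#'
#' Dispatcher over the two regularization models. For TPM-normalized pool
#' matrices (from [measure_tpm()]) pass the row-normalized design.
#'
#' @inheritParams basis_pursuit_solve
#' @param config a [solver_config()].
#' @return cells x genes reconstructed matrix.
#' @export
reconstruct_expression <- function(design, Y, config = solver_config()) {
  stopifnot(inherits(config, "solver_config"))
  switch(config$method,
         ridge = ridge_solve(design, Y, lambda = config$lambda),
         basis_pursuit = basis_pursuit_solve(design, Y, config))
}

#' Partition cells into blocks for parallel reconstruction
#'
#' Large cell numbers are handled by splitting the cell set into contiguous
#' blocks, reconstructing each block from its own independent pool design,
#' and concatenating the results. All blocks hold `block_size` cells; a
#' remainder shorter than half a block joins the last block (e.g. 5063 cells
#' at 500 per block gives 10 blocks, the last of 563), a longer one forms its
#' own block (45423 cells gives 91 blocks, the last of 423). Full blocks
#' receive `round(total_pools * block_size / n_cells)` pools; the last block
#' receives the remaining pools.
#'
#' @param n_cells total number of cells.
#' @param block_size target cells per block; if it exceeds `n_cells` a single
#'   block is used.
#' @param total_pools total pool (library) budget across all blocks.
#' @return a `block_partition`: list with `block_sizes`, `pools_per_block`
#'   and `starts` (first cell index of each block).
#' @export
#' @examples
#' partition_cells(5063, 500, 1600)   # 10 blocks; last: 563 cells, 178 pools
#' partition_cells(45423, 500, 22700) # 91 blocks; last: 423 cells, 200 pools
partition_cells <- function(n_cells, block_size, total_pools) {
  stopifnot(n_cells >= 1, block_size >= 1, total_pools >= 1)
  n_full <- n_cells %/% block_size
  rem <- n_cells %% block_size
  if (n_full == 0L) {
    sizes <- n_cells
  } else if (rem == 0L) {
    sizes <- rep(block_size, n_full)
  } else if (rem < block_size / 2) {
    sizes <- c(rep(block_size, n_full - 1L), block_size + rem)
  } else {
    sizes <- c(rep(block_size, n_full), rem)
  }
  nb <- length(sizes)
  if (total_pools < nb) {
    stop(sprintf("total_pools (%d) is less than the number of blocks (%d)",
                 total_pools, nb), call. = FALSE)
  }
  if (nb == 1L) {
    pools <- total_pools
  } else {
    per_full <- round(total_pools * block_size / n_cells)
    pools <- c(rep(per_full, nb - 1L), total_pools - per_full * (nb - 1L))
  }
  if (any(pools < 1)) {
    stop("pool budget leaves a block with no pools; increase total_pools or block_size",
         call. = FALSE)
  }
  structure(list(block_sizes = as.integer(sizes),
                 pools_per_block = as.integer(pools),
                 starts = as.integer(cumsum(c(1L, sizes[-nb])))),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("block partition: %d blocks, %d cells, %d pools\n",
              length(x$block_sizes), sum(x$block_sizes), sum(x$pools_per_block)))
  cat("  cells per block:", paste(x$block_sizes, collapse = " "), "\n")
  cat("  pools per block:", paste(x$pools_per_block, collapse = " "), "\n")
  invisible(x)
}

#' Block-parallel reconstruction
#'
#' Runs the full compress-and-recover cycle independently on each block of
#' cells: a fresh Bernoulli design per block (seeded deterministically from
#' `seed` and the block index, so results do not depend on the worker count
#' or execution order), optional turbulence on the measurements,
#' reconstruction with `config`, and row-wise concatenation in the original
#' cell order.
#'
#' @param X cells x genes expression matrix (ground truth / input profile).
#' @param partition a [partition_cells()] result consistent with `nrow(X)`.
#' @param config a [solver_config()]; `config$n_workers > 1` uses forked
#'   workers via [parallel::mclapply()].
#' @param inclusion_prob Bernoulli design density per block.
#' @param seed master seed; block `b` uses `derive_seed(seed, b)` for its
#'   design and `derive_seed(seed, b + n_blocks)` for turbulence.
#' @param turbulence multiplicative noise level in `[0, 1)` applied to the
#'   measuring copy of each block design (the solver still sees the nominal
#'   binary design).
#' @param tpm_mode if `TRUE`, use [measure_tpm()] and hand the solver the
#'   row-normalized design.
#' @return cells x genes reconstructed matrix.
#' @export
block_reconstruct <- function(X, partition, config = solver_config(),
                              inclusion_prob = 0.5, seed = 1L,
                              turbulence = 0, tpm_mode = FALSE) {
  X <- as_dense_matrix(X)
  stopifnot(inherits(partition, "block_partition"))
  if (sum(partition$block_sizes) != nrow(X)) {
    stop_dims("partition covers a different number of cells than X",
              sum(partition$block_sizes), nrow(X))
  }
  nb <- length(partition$block_sizes)
  one_block <- function(b) {
    rows <- seq(partition$starts[b], length.out = partition$block_sizes[b])
    tryCatch({
      M <- generate_measurement_matrix(partition$pools_per_block[b],
                                       length(rows), inclusion_prob,
                                       seed = derive_seed(seed, b))
      Mmeas <- if (turbulence > 0) {
        perturb_design(M, turbulence, seed = derive_seed(seed, b + nb))
      } else M
      if (tpm_mode) {
        Y <- measure(normalize_rows(Mmeas), X[rows, , drop = FALSE])
        reconstruct_expression(normalize_rows(M), Y, config)
      } else {
        Y <- measure(Mmeas, X[rows, , drop = FALSE])
        reconstruct_expression(M, Y, config)
      }
    }, error = function(e) {
      stop(sprintf("block %d failed: %s", b, conditionMessage(e)), call. = FALSE)
    })
  }
  blocks <- if (config$n_workers > 1L) {
    parallel::mclapply(seq_len(nb), one_block, mc.cores = config$n_workers)
  } else {
    lapply(seq_len(nb), one_block)
  }
  errs <- vapply(blocks, function(b) inherits(b, "try-error") || is.character(b),
                 logical(1))
  if (any(errs)) stop(blocks[[which(errs)[1]]], call. = FALSE)
  Xhat <- do.call(rbind, lapply(blocks, as_dense_matrix))
  rownames(Xhat) <- rownames(X)
  colnames(Xhat) <- colnames(X)
  Xhat
}

#' Threshold a reconstructed expression matrix
#'
#' Post-processing mirroring TPM practice: negative reconstructed values are
#' clamped to 0; values below `floor_value` TPM are set to 0 (a floor of 5
#' removes the unreliable low range); genes whose total across cells falls
#' below `detect_tol` (0.001 TPM by default) are flagged undetected and
#' optionally dropped.
#'
#' @param X cells x genes (reconstructed) matrix.
#' @param detect_tol per-gene total below which a gene counts as undetected.
#' @param floor_value per-entry floor; 0 disables flooring.
#' @param drop_undetected drop flagged gene columns from the result.
#' @return the thresholded matrix with attribute `undetected_genes` (labels).
#' @export
#' @examples
#' threshold_expression(cbind(c(4.9, 5.0, 7.2)), floor_value = 5)
threshold_expression <- function(X, detect_tol = 0.001, floor_value = 0,
                                 drop_undetected = FALSE) {
  X <- as_dense_matrix(X)
  stopifnot(detect_tol >= 0, floor_value >= 0)
  X[X < 0] <- 0
  if (floor_value > 0) X[X < floor_value] <- 0
  undetected <- which(colSums(X) < detect_tol)
  labs <- (colnames(X) %||% as.character(seq_len(ncol(X))))[undetected]
  if (drop_undetected && length(undetected)) {
    X <- X[, -undetected, drop = FALSE]
  }
  structure(X, undetected_genes = labs)
}
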