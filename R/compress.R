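# Forward model: pooled measurements from an expression matrix, with
# optional multiplicative "turbulence" noise and TPM depth-sharing
# normalization.

#' Perturb a pool design with multiplicative turbulence
#'
#' Models sampling error, sample degradation and sequencing error on the
#' cells actually added to a pool: every 1 in the design is replaced by an
#' independent uniform draw from the open interval (1 - t, 1 + t); zeros
#' (cells absent from a pool) are untouched. Reconstruction should still use
#' the nominal binary design — the mismatch is what degrades recovery.
#'
#' @param M a [measurement_matrix()].
#' @param t turbulence level in `[0, 1)`; `t = 0` returns the design
#'   unchanged.
#' @param seed integer RNG seed.
#' @return a `perturbed_design` matrix with the source design and `t`
#'   attached.
#' @export
#' @examples
#' m <- generate_measurement_matrix(4, 6, 0.5, seed = 1)
#' p <- perturb_design(m, 0.2, seed = 2)
#' range(p[m == 1])
perturb_design <- function(M, t, seed = NULL) {
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t >= 1) {
    stop("turbulence t must be a single value in [0, 1)", call. = FALSE)
  }
  vals <- as_dense_matrix(M)
  out <- vals
  if (t > 0) {
    ones <- which(vals == 1)
    out[ones] <- with_seed_if(seed, {
      u <- runif(length(ones), 1 - t, 1 + t)
      # open interval: redraw the (measure-zero) endpoint hits for determinism
      while (any(bad <- u <= 1 - t | u >= 1 + t)) {
        u[bad] <- runif(sum(bad), 1 - t, 1 + t)
      }
      u
    })
  }
  structure(out, source = M, turbulence = t,
            seed = if (is.null(seed)) NULL else as.integer(seed),
            class = c("perturbed_design", "matrix", "array"))
}

#' @export
print.perturbed_design <- function(x, ...) {
  cat(sprintf("perturbed design: %d pools x %d cells, turbulence = %g\n",
              nrow(x), ncol(x), attr(x, "turbulence")))
  invisible(x)
}

pool_matrix <- function(values, normalized, design) {
  structure(values, normalized = normalized,
            design_dim = dim(as_dense_matrix(design)),
            class = c("pool_matrix", "matrix", "array"))
}

#' @export
print.pool_matrix <- function(x, ...) {
  cat(sprintf("pool matrix: %d pools x %d genes (%s)\n", nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "TPM-normalized" else "raw sums"))
  invisible(x)
}

#' Pooled measurements Y = M X
#'
#' The forward model of the pooling experiment: each pool's profile is the
#' sum of its member cells' profiles, `Y[pools x genes] = M X[cells x genes]`.
#'
#' @param design a [measurement_matrix()] or [perturb_design()] output.
#' @param X cells x genes expression matrix.
#' @return a `pool_matrix` (pools x genes), `normalized` flag `FALSE`.
#' @export
#' @examples
#' measure(measurement_matrix(rbind(c(1, 1), c(1, 0))),
#'         rbind(c(1, 2), c(3, 4)))
measure <- function(design, X) {
  D <- as_dense_matrix(design)
  X <- as_dense_matrix(X)
  if (ncol(D) != nrow(X)) {
    stop_dims("design/expression mismatch (design is pools x cells, X is cells x genes)",
              c(nrow(D), ncol(D)), c(nrow(X), ncol(X)))
  }
  Y <- D %*% X
  rownames(Y) <- rownames(D)
  colnames(Y) <- colnames(X)
  pool_matrix(Y, normalized = FALSE, design = design)
}

#' TPM-normalized pooled measurements
#'
#' When pools are sequenced to a fixed depth, the member cells share that
#' depth equally (the same cDNA mass per cell goes into every pool), so a
#' pool's TPM profile is the average, not the sum, of its members:
#' `Y_TPM = diag(1/rowsum(M)) M X_TPM`. Reconstruction from `Y_TPM` must use
#' the matching row-normalized design ([normalize_rows()]).
#'
#' @param M a [measurement_matrix()] (binary; no empty pools).
#' @param X_tpm cells x genes TPM expression matrix.
#' @return a `pool_matrix` with `normalized` flag `TRUE`.
#' @export
measure_tpm <- function(M, X_tpm) {
  Y <- measure(normalize_rows(M), X_tpm)
  pool_matrix(as_dense_matrix(Y), normalized = TRUE, design = M)
}
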