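# Pool design (measurement matrix) generation, validation, normalization,
# RIP pool-count heuristic and plate-map export/import.

#' Construct a measurement-matrix object
#'
#' A measurement matrix is a binary pools x cells design: entry `[i, j]` is 1
#' iff pool `i` contains an aliquot of cell `j`'s cDNA. This constructor
#' validates an existing 0/1 matrix; use [generate_measurement_matrix()] to
#' sample one.
#'
#' @param values numeric matrix of 0/1 indicators, pools in rows, cells in
#'   columns.
#' @param inclusion_prob the Bernoulli probability the design was (or would
#'   be) drawn with; stored as metadata.
#' @param seed the RNG seed the design was drawn with, or `NULL`.
#' @param validate if `TRUE` (default), reject empty pools (all-zero rows) and
#'   unpooled cells (all-zero columns): an empty pool wastes a library and an
#'   unpooled cell can never be recovered.
#' @return a `measurement_matrix`: the 0/1 matrix with design metadata
#'   attached.
#' @export
#' @examples
#' m <- measurement_matrix(rbind(c(1, 0, 1), c(0, 1, 1)))
#' n_pools(m); n_cells(m)
measurement_matrix <- function(values, inclusion_prob = NA_real_, seed = NULL,
                               validate = TRUE) {
  values <- as_dense_matrix(values)
  if (!all(values %in% c(0, 1))) {
    stop("measurement matrix entries must all be 0 or 1", call. = FALSE)
  }
  if (validate) {
    zr <- which(rowSums(values) == 0)
    if (length(zr)) {
      stop(sprintf("empty pool(s) (all-zero row): %s",
                   paste(zr, collapse = ", ")), call. = FALSE)
    }
    zc <- which(colSums(values) == 0)
    if (length(zc)) {
      stop(sprintf("unpooled cell(s) (all-zero column): %s",
                   paste(zc, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("pool%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("cell%d", seq_len(ncol(values)))
  }
  structure(values,
            inclusion_prob = inclusion_prob,
            seed = if (is.null(seed)) NULL else as.integer(seed),
            class = c("measurement_matrix", "matrix", "array"))
}

#' @rdname measurement_matrix
#' @param x a design matrix.
#' @export
n_pools <- function(x) nrow(x)

#' @rdname measurement_matrix
#' @export
n_cells <- function(x) ncol(x)

#' @export
print.measurement_matrix <- function(x, ...) {
  cat(sprintf("measurement matrix: %d pools x %d cells, %d ones (density %.3f)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  cat(sprintf("  inclusion_prob = %s, seed = %s\n",
              format(attr(x, "inclusion_prob")),
              format(attr(x, "seed") %||% NA)))
  invisible(x)
}

#' Generate a random Bernoulli pool design
#'
#' Samples a pools x cells binary matrix with i.i.d. Bernoulli entries
#' (`inclusion_prob` chance of 1; the classic setting is 0.5, and 0.3 is the
#' documented preset for very large cell numbers to keep pool sizes
#' manageable). Draws containing an empty pool or an unpooled cell are
#' rejected and resampled, up to `max_retries` times; each retry is reported
#' via `message()`.
#'
#' @param n_pools number of pools (sequencing libraries), >= 1.
#' @param n_cells number of cells, >= 1.
#' @param inclusion_prob probability in (0, 1] that any given cell enters any
#'   given pool.
#' @param seed integer RNG seed; the same (dims, prob, seed) triple always
#'   yields the identical matrix.
#' @param max_retries resampling budget before giving up.
#' @return a [measurement_matrix()].
#' @export
#' @examples
#' m <- generate_measurement_matrix(40, 54, 0.5, seed = 1)
#' dim(m)
generate_measurement_matrix <- function(n_pools, n_cells, inclusion_prob = 0.5,
                                        seed = NULL, max_retries = 1000L) {
  stopifnot(n_pools >= 1, n_cells >= 1,
            inclusion_prob > 0, inclusion_prob <= 1)
  n_pools <- as.integer(n_pools)
  n_cells <- as.integer(n_cells)
  with_seed_if(seed, {
    for (attempt in seq_len(max_retries + 1L)) {
      vals <- matrix(rbinom(n_pools * n_cells, 1L, inclusion_prob),
                     nrow = n_pools, ncol = n_cells)
      ok <- all(rowSums(vals) > 0) && all(colSums(vals) > 0)
      if (ok) {
        if (attempt > 1L) {
          message(sprintf("design accepted after %d resample(s)", attempt - 1L))
        }
        return(measurement_matrix(vals, inclusion_prob = inclusion_prob,
                                  seed = seed))
      }
      if (attempt <= max_retries) {
        message(sprintf(
          "resampling design (attempt %d): empty pool or unpooled cell",
          attempt))
      }
    }
    stop(sprintf(paste0(
      "no valid %d x %d design found in %d attempts at inclusion_prob = %g; ",
      "empty pools / unpooled cells are near-certain at this probability"),
      n_pools, n_cells, max_retries, inclusion_prob), call. = FALSE)
  })
}

#' Advisory pool count from the RIP heuristic
#'
#' Compressed-sensing theory suggests a random Bernoulli design supports
#' recovery of K-sparse signals of length N with high probability once the
#' number of measurements reaches about `c_const * K * log(N / K)` (the
#' restricted isometry property). Both the constant and the logarithm base
#' are conventions, so they are explicit arguments; the result is advisory
#' and never gates design generation.
#'
#' @param K sparsity level: nonzero entries per gene column (cells expressing
#'   the gene).
#' @param N signal length: the number of cells.
#' @param c_const positive proportionality constant (default 1).
#' @param log_base `"natural"`, `"base2"` or `"base10"`.
#' @return the ceiling of `c_const * K * log(N/K)`; 0 when `K == N`.
#' @export
#' @examples
#' required_pool_count(5, 100) # ceil(5 * ln 20) = 15
required_pool_count <- function(K, N, c_const = 1,
                                log_base = c("natural", "base2", "base10")) {
  log_base <- match.arg(log_base)
  stopifnot(K >= 1, N >= 1, c_const > 0)
  if (K > N) stop("sparsity K cannot exceed signal length N", call. = FALSE)
  lg <- switch(log_base,
               natural = log(N / K),
               base2 = log2(N / K),
               base10 = log10(N / K))
  as.integer(ceiling(c_const * K * lg))
}

#' Row-normalize a pool design
#'
#' Divides each row of the design by its row sum:
#' `M_normalized = diag(1/rowsum(M)) M`. This models equal depth sharing
#' among the cells of a pool and is the design handed to the solver when the
#' pooled measurements are TPM-normalized (see [measure_tpm()]).
#'
#' @param M a [measurement_matrix()] (or plain 0/1 matrix).
#' @return a `row_normalized_matrix`: nonnegative matrix whose rows sum to 1,
#'   same zero pattern as `M`, with the source design attached.
#' @export
#' @examples
#' normalize_rows(measurement_matrix(rbind(c(1, 1, 0, 1), c(0, 1, 0, 0))))
normalize_rows <- function(M) {
  vals <- as_dense_matrix(M)
  rs <- rowSums(vals)
  bad <- which(rs == 0)
  if (length(bad)) {
    stop(sprintf("cannot row-normalize: pool(s) %s are empty (all-zero row)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- vals / rs
  dimnames(out) <- dimnames(vals)
  structure(out, source = M,
            class = c("row_normalized_matrix", "matrix", "array"))
}

#' @export
print.row_normalized_matrix <- function(x, ...) {
  cat(sprintf("row-normalized design: %d pools x %d cells\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Export a pool design as a membership table
#'
#' Turns the binary design into a long-format plate map: one record per
#' (pool, cell) membership, the form a bench scientist pipettes from. The
#' table round-trips losslessly through [import_pool_design()].
#'
#' @param M a [measurement_matrix()].
#' @param cell_labels character vector naming the cells (columns of `M`);
#'   defaults to the design's column names.
#' @return a data.frame with columns `pool_id` and `cell_id`, ordered by pool
#'   then cell.
#' @export
#' @examples
#' export_pool_design(measurement_matrix(rbind(c(1, 0, 1), c(0, 1, 0))),
#'                    c("A", "B", "C"))
export_pool_design <- function(M, cell_labels = colnames(M)) {
  vals <- as_dense_matrix(M)
  if (length(cell_labels) != ncol(vals)) {
    stop(sprintf("got %d cell labels for %d cells",
                 length(cell_labels), ncol(vals)), call. = FALSE)
  }
  pool_ids <- rownames(vals) %||% sprintf("pool%d", seq_len(nrow(vals)))
  idx <- which(t(vals) == 1)  # column-major over t() -> pool-major order
  pool_of <- (idx - 1L) %/% ncol(vals) + 1L
  cell_of <- (idx - 1L) %% ncol(vals) + 1L
  data.frame(pool_id = pool_ids[pool_of],
             cell_id = as.character(cell_labels)[cell_of],
             stringsAsFactors = FALSE)
}

#' Rebuild a measurement matrix from a membership table
#'
#' Inverse of [export_pool_design()].
#'
#' @param design data.frame with columns `pool_id` and `cell_id`.
#' @param pool_ids,cell_labels optional explicit orderings; by default the
#'   order of first appearance in the table is used.
#' @return a [measurement_matrix()].
#' @export
import_pool_design <- function(design, pool_ids = NULL, cell_labels = NULL) {
  stopifnot(all(c("pool_id", "cell_id") %in% names(design)))
  pool_ids <- pool_ids %||% unique(as.character(design$pool_id))
  cell_labels <- cell_labels %||% unique(as.character(design$cell_id))
  vals <- matrix(0, length(pool_ids), length(cell_labels),
                 dimnames = list(pool_ids, cell_labels))
  i <- match(as.character(design$pool_id), pool_ids)
  j <- match(as.character(design$cell_id), cell_labels)
  if (anyNA(i) || anyNA(j)) {
    stop("membership table refers to unknown pool or cell ids", call. = FALSE)
  }
  vals[cbind(i, j)] <- 1
  measurement_matrix(vals)
}
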