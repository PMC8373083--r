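# Reconstruction quality metrics: per-cell Pearson correlation, gene
# detection sensitivity, gene-level correlation profiles and library-cost
# accounting.

#' Per-cell Pearson correlation between original and inferred profiles
#'
#' The headline consistency metric: for each cell, the Pearson correlation
#' between its original and reconstructed gene expression vector (rho_c), and
#' their mean over cells (rho). Cells with zero variance in either matrix
#' have undefined correlation; they are reported as `NA` and excluded from
#' the mean, with a warning.
#'
#' @param X,Xhat cells x genes matrices of identical shape (and label order,
#'   if labelled).
#' @return list with `per_cell_rho` (named, `NA` where undefined) and
#'   `mean_rho`.
#' @export
#' @examples
#' x <- matrix(rnorm(20), 4)
#' cell_correlations(x, 2 * x + 7)$mean_rho  # affine invariance: 1
cell_correlations <- function(X, Xhat) {
  X <- as_dense_matrix(X); Xhat <- as_dense_matrix(Xhat)
  if (!all(dim(X) == dim(Xhat))) {
    stop_dims("X and Xhat must have identical shape", dim(X), dim(Xhat))
  }
  if (!is.null(rownames(X)) && !is.null(rownames(Xhat)) &&
      !identical(rownames(X), rownames(Xhat))) {
    stop("cell labels of X and Xhat disagree", call. = FALSE)
  }
  sx <- apply(X, 1, stats::sd); sy <- apply(Xhat, 1, stats::sd)
  defined <- sx > 0 & sy > 0
  rho <- rep(NA_real_, nrow(X))
  if (any(defined)) {
    Xc <- X[defined, , drop = FALSE] - rowMeans(X[defined, , drop = FALSE])
    Yc <- Xhat[defined, , drop = FALSE] - rowMeans(Xhat[defined, , drop = FALSE])
    rho[defined] <- rowSums(Xc * Yc) /
      sqrt(rowSums(Xc^2) * rowSums(Yc^2))
  }
  names(rho) <- rownames(X)
  if (any(!defined)) {
    warning(sprintf("%d cell(s) with zero variance excluded from mean rho",
                    sum(!defined)), call. = FALSE)
  }
  list(per_cell_rho = rho, mean_rho = mean(rho[defined]))
}

#' Gene detection sensitivity
#'
#' A gene counts as detected when its total across cells reaches
#' `detect_tol` (0.001 TPM by default — below that is indistinguishable from
#' rounding error). Reports counts for both matrices, the inferred/original
#' ratio, and how many genes lost by the reconstruction had an original
#' total above `lost_gene_threshold` (the biologically meaningful stratum).
#'
#' @param X,Xhat cells x genes matrices over the same gene set.
#' @param detect_tol detection threshold on the per-gene total.
#' @param lost_gene_threshold stratum cut for lost genes (default 1 TPM).
#' @return list with `detected_original`, `detected_inferred`,
#'   `detection_fraction`, `lost_genes`, `lost_genes_above_threshold`.
#' @export
detection_sensitivity <- function(X, Xhat, detect_tol = 0.001,
                                  lost_gene_threshold = 1) {
  X <- as_dense_matrix(X); Xhat <- as_dense_matrix(Xhat)
  if (ncol(X) != ncol(Xhat)) {
    stop_dims("X and Xhat must share the gene set", ncol(X), ncol(Xhat))
  }
  tot_x <- colSums(X); tot_h <- colSums(pmax(Xhat, 0))
  det_x <- tot_x >= detect_tol; det_h <- tot_h >= detect_tol
  lost <- det_x & !det_h
  list(detected_original = sum(det_x),
       detected_inferred = sum(det_h),
       detection_fraction = if (sum(det_x) == 0) NA_real_ else
         sum(det_h & det_x) / sum(det_x),
       lost_genes = sum(lost),
       lost_genes_above_threshold = sum(lost & tot_x > lost_gene_threshold))
}

#' Gene-level correlation profile by sparsity or expression rank
#'
#' Per-gene Pearson correlation across cells between original and inferred
#' values, grouped into quantile bins by either sparsity level (genes
#' expressed in fewer cells have higher sparsity level; bin 1 = sparsest) or
#' total expression (bin 1 = lowest total). This is the source table for the
#' violin-plot style summaries of recovery quality versus gene class.
#'
#' @param X,Xhat cells x genes matrices of identical shape.
#' @param ranking `"sparsity_level"` or `"total_expression"`.
#' @param bins number of quantile bins (default 5).
#' @param zero_tol tolerance defining "expressed" for the sparsity ranking.
#' @return list with `per_gene` (data.frame: gene, correlation,
#'   cells_expressing, total_expression, bin), `bin_summary` (per-bin median
#'   and quartiles) and `n_excluded` (genes constant in both matrices).
#' @export
gene_correlation_profile <- function(X, Xhat,
                                     ranking = c("sparsity_level",
                                                 "total_expression"),
                                     bins = 5L, zero_tol = 0) {
  ranking <- match.arg(ranking)
  X <- as_dense_matrix(X); Xhat <- as_dense_matrix(Xhat)
  if (!all(dim(X) == dim(Xhat))) {
    stop_dims("X and Xhat must have identical shape", dim(X), dim(Xhat))
  }
  stopifnot(bins >= 1)
  genes <- colnames(X) %||% sprintf("gene%d", seq_len(ncol(X)))
  sx <- apply(X, 2, stats::sd); sh <- apply(Xhat, 2, stats::sd)
  defined <- sx > 0 | sh > 0
  corr <- rep(NA_real_, ncol(X))
  both <- sx > 0 & sh > 0
  if (any(both)) {
    corr[both] <- vapply(which(both),
                         function(j) cor(X[, j], Xhat[, j]), numeric(1))
  }
  corr[defined & !both] <- 0  # one side constant, the other not: no linear fit
  cells_expr <- colSums(X > zero_tol)
  totals <- colSums(X)
  key <- switch(ranking,
                # sparsity level rises as expressing-cell count falls:
                # bin 1 holds the sparsest genes (fewest expressing cells)
                sparsity_level = cells_expr,
                total_expression = totals)
  ord <- rank(key, ties.method = "first")
  bin <- as.integer(ceiling(ord / length(ord) * bins))
  keep <- defined
  per_gene <- data.frame(gene = genes, correlation = corr,
                         cells_expressing = cells_expr,
                         total_expression = totals, bin = bin,
                         stringsAsFactors = FALSE)[keep, , drop = FALSE]
  qs <- lapply(split(per_gene$correlation, per_gene$bin), function(v) {
    quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  })
  bin_summary <- data.frame(bin = as.integer(names(qs)),
                            q25 = vapply(qs, `[`, numeric(1), 1),
                            median = vapply(qs, `[`, numeric(1), 2),
                            q75 = vapply(qs, `[`, numeric(1), 3),
                            n = as.integer(table(per_gene$bin)))
  list(per_gene = per_gene, bin_summary = bin_summary,
       n_excluded = sum(!defined))
}

#' Library-construction savings from pooling
#'
#' Pooling replaces one library per cell with one per pool.
#'
#' @param n_cells,n_pools counts of cells and pools (libraries built).
#' @return list with `libraries_saved` (`max(n_cells - n_pools, 0)`) and
#'   `savings_percent` (share of `n_cells`, rounded to 2 decimals).
#' @export
#' @examples
#' library_savings(54, 28)  # 26 saved, 48.15%
library_savings <- function(n_cells, n_pools) {
  stopifnot(n_cells >= 1, n_pools >= 1)
  saved <- max(n_cells - n_pools, 0)
  list(libraries_saved = as.integer(saved),
       savings_percent = round(100 * saved / n_cells, 2))
}

#' Full evaluation report
#'
#' Bundles all reconstruction metrics: per-cell and mean Pearson correlation,
#' the cells x cells original-vs-inferred correlation matrix (heat-map
#' source), the gene correlation profile, detection sensitivity and library
#' savings.
#'
#' @param X,Xhat cells x genes original and reconstructed matrices.
#' @param n_pools number of pools used (for the savings accounting).
#' @param detect_tol detection threshold (see [detection_sensitivity()]).
#' @param bins gene-profile quantile bins.
#' @return an `evaluation_report` list.
#' @export
evaluate_reconstruction <- function(X, Xhat, n_pools = NULL,
                                    detect_tol = 0.001, bins = 5L) {
  cc <- cell_correlations(X, Xhat)
  det <- detection_sensitivity(X, Xhat, detect_tol = detect_tol)
  prof <- gene_correlation_profile(X, Xhat, bins = bins)
  Xd <- as_dense_matrix(X); Hd <- as_dense_matrix(Xhat)
  cmat <- suppressWarnings(cor(t(Xd), t(Hd)))
  savings <- if (!is.null(n_pools)) library_savings(nrow(Xd), n_pools) else
    list(libraries_saved = NA_integer_, savings_percent = NA_real_)
  structure(list(per_cell_rho = cc$per_cell_rho, mean_rho = cc$mean_rho,
                 cell_by_cell_corr = cmat,
                 gene_corr_profile = prof,
                 detected_original = det$detected_original,
                 detected_inferred = det$detected_inferred,
                 detection_fraction = det$detection_fraction,
                 lost_genes_above_threshold = det$lost_genes_above_threshold,
                 libraries_saved = savings$libraries_saved,
                 savings_percent = savings$savings_percent),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("reconstruction evaluation\n")
  cat(sprintf("  mean per-cell Pearson rho : %.4f (n = %d cells, %d undefined)\n",
              x$mean_rho, length(x$per_cell_rho), sum(is.na(x$per_cell_rho))))
  cat(sprintf("  genes detected            : %d / %d (fraction %.4f)\n",
              x$detected_inferred, x$detected_original, x$detection_fraction))
  if (!is.na(x$libraries_saved)) {
    cat(sprintf("  libraries saved           : %d (%.2f%%)\n",
                x$libraries_saved, x$savings_percent))
  }
  invisible(x)
}
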