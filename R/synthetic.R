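# Synthetic zero-inflated single-cell expression profiles (SCEPs) with
# cell-type block structure, plus gene-level sparsity profiling.

#' Specification for a synthetic expression profile
#'
#' Bundles and validates the parameters of [simulate_scep()]. The two
#' sparsity regimes of interest are a high-sparsity profile with about 24.49%
#' non-zero entries (heterogeneous cell types, e.g. pancreatic islet) and a
#' low-sparsity one with about 32.30% (closely related T lymphocytes).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param target_nonzero_frac desired fraction of non-zero entries, in
#'   (0, 1]; the realized fraction lands within about 2 percentage points.
#' @param n_types number of cell types (blocks of cells sharing marker-gene
#'   support).
#' @param marker_frac fraction of genes that are type-specific markers;
#'   ignored (treated as 0) when `n_types == 1`.
#' @param dispersion gamma-shape dispersion of expressed magnitudes
#'   (variance = dispersion * mean^2); 1 gives the heavy exponential-like
#'   tail typical of TPM data.
#' @param mean_expression typical TPM-scale magnitude of an expressed entry.
#' @param seed integer RNG seed.
#' @return a validated `synthetic_profile_spec` list.
#' @export
synthetic_profile_spec <- function(n_cells, n_genes, target_nonzero_frac,
                                   n_types = 1L, marker_frac = 0.3,
                                   dispersion = 1, mean_expression = 100,
                                   seed = NULL) {
  stopifnot(n_cells >= 1, n_genes >= 1,
            target_nonzero_frac > 0, target_nonzero_frac <= 1,
            n_types >= 1, marker_frac >= 0, marker_frac <= 1,
            dispersion > 0, mean_expression > 0)
  if (n_types > n_cells) {
    stop("n_types cannot exceed n_cells", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 target_nonzero_frac = target_nonzero_frac,
                 n_types = as.integer(n_types), marker_frac = marker_frac,
                 dispersion = dispersion, mean_expression = mean_expression,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "synthetic_profile_spec")
}

# expression probabilities per entry class. Markers of a type are expressed
# mostly in that type's cells; the shared-gene probability q is solved so the
# expected overall non-zero fraction equals the target.
.support_probs <- function(f, n_types, marker_frac) {
  if (n_types == 1L || marker_frac == 0) {
    return(list(p_own = f, p_other = f, q = f, marker_frac = 0))
  }
  if (f >= 1) return(list(p_own = 1, p_other = 1, q = 1,
                          marker_frac = marker_frac))
  p_own <- f + 0.8 * (1 - f)
  p_other <- 0.2 * f
  marker_mean <- (p_own + (n_types - 1) * p_other) / n_types
  q <- (f - marker_frac * marker_mean) / (1 - marker_frac)
  if (q > 1) {
    # markers alone can't dilute enough; relax enrichment instead
    p_other <- (n_types * (f - (1 - marker_frac)) / marker_frac - p_own) /
      (n_types - 1)
    q <- 1
  }
  if (q < 0 || p_other < 0 || p_other > 1) {
    stop(sprintf(paste0(
      "infeasible sparsity structure: target_nonzero_frac = %g with ",
      "marker_frac = %g and %d types requires a shared-gene expression ",
      "probability outside [0, 1]"), f, marker_frac, n_types), call. = FALSE)
  }
  list(p_own = p_own, p_other = p_other, q = q, marker_frac = marker_frac)
}

#' Simulate a zero-inflated single-cell expression profile
#'
#' Generates a cells x genes TPM-scale matrix with (i) a structured support
#' (zero/non-zero) mask whose expected non-zero fraction equals the target:
#' marker genes of a cell type are expressed mainly in that type's cells,
#' the remaining genes at per-gene probabilities drawn from a descending
#' beta density whose mean is solved so the overall non-zero fraction hits
#' the target (most genes expressed in few cells, a small dense tail in
#' nearly all — the gene-sparsity profile real SCEPs show); and (ii)
#' gamma-distributed positive magnitudes around per-gene lognormal means —
#' the continuous analogue of the negative-binomial character of single-cell
#' expression data — with marker genes up-regulated in their own type.
#' Same-type cells therefore share support and magnitudes, so within-type
#' correlation exceeds between-type correlation.
#'
#' @param spec a [synthetic_profile_spec()], or arguments to build one via
#'   `...`.
#' @param ... passed to [synthetic_profile_spec()] when `spec` is missing.
#' @return a cells x genes numeric matrix with `cell_labels`/`gene_labels`
#'   dimnames and a `cell_types` attribute (integer type per cell).
#' @export
#' @examples
#' x <- simulate_scep(synthetic_profile_spec(64, 500, 0.2449,
#'                                           n_types = 7, seed = 1))
#' mean(x > 0)
simulate_scep <- function(spec, ...) {
  if (missing(spec)) spec <- synthetic_profile_spec(...)
  stopifnot(inherits(spec, "synthetic_profile_spec"))
  f <- spec$target_nonzero_frac
  pr <- .support_probs(f, spec$n_types, spec$marker_frac)

  with_seed_if(spec$seed %||% stop("spec must carry a seed", call. = FALSE), {
    nc <- spec$n_cells; ng <- spec$n_genes; nt <- spec$n_types
    cell_types <- rep(seq_len(nt), length.out = nc)
    n_marker <- round(pr$marker_frac * ng)
    gene_type <- rep(0L, ng)          # 0 = shared gene
    if (n_marker > 0) gene_type[seq_len(n_marker)] <- rep(seq_len(nt),
                                                          length.out = n_marker)

    # per-entry expression probability. Shared genes get heterogeneous
    # per-gene probabilities from a descending (beta, shape < 1) density with
    # mean q: most genes expressed in few cells, a small dense tail expressed
    # in nearly all — the characteristic gene-sparsity profile of SCEP data.
    shared_prob <- if (pr$q >= 1) {
      rep(1, ng)
    } else if (pr$q <= 0) {
      rep(0, ng)
    } else {
      a <- 0.6
      stats::rbeta(ng, a, a * (1 - pr$q) / pr$q)
    }
    P <- matrix(shared_prob, nc, ng, byrow = TRUE)
    if (n_marker > 0) {
      marker_cols <- which(gene_type > 0L)
      own <- outer(cell_types, gene_type[marker_cols], `==`)
      P[, marker_cols] <- ifelse(own, pr$p_own, pr$p_other)
    }
    support <- matrix(runif(nc * ng) < P, nc, ng)

    # magnitudes: per-gene lognormal mean, marker boost in own type,
    # gamma noise with the requested dispersion
    mu_gene <- rlnorm(ng, meanlog = log(spec$mean_expression), sdlog = 1)
    MU <- matrix(mu_gene, nc, ng, byrow = TRUE)
    if (n_marker > 0) {
      boost <- outer(cell_types, gene_type, `==`)
      MU[boost] <- MU[boost] * 3
    }
    shape <- 1 / spec$dispersion
    vals <- matrix(0, nc, ng)
    vals[support] <- rgamma(sum(support), shape = shape,
                            rate = shape / MU[support])
    vals[support & vals <= 0] <- 1e-6  # guard underflow: support must stay exact

    dimnames(vals) <- list(sprintf("cell%d", seq_len(nc)),
                           sprintf("gene%d", seq_len(ng)))
    structure(vals, cell_types = cell_types)
  })
}

#' Per-gene sparsity profile
#'
#' For each gene, the number of cells expressing it (value above `zero_tol`);
#' fewer expressing cells = higher sparsity level. Also reports the
#' matrix-wide non-zero fraction.
#'
#' @param X cells x genes expression matrix.
#' @param zero_tol detection tolerance: 0 for exact synthetic data, 0.001 for
#'   TPM data (values below 0.001 TPM are treated as unexpressed).
#' @return list with `cells_expressing` (named integer per gene) and
#'   `nonzero_fraction`.
#' @export
#' @examples
#' gene_sparsity_profile(rbind(c(1, 0), c(3, 2)))
gene_sparsity_profile <- function(X, zero_tol = 0) {
  X <- as_dense_matrix(X)
  stopifnot(zero_tol >= 0)
  expressed <- X > zero_tol
  list(cells_expressing = colSums(expressed),
       nonzero_fraction = mean(expressed))
}
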