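# Lossless text I/O for expression matrices, pool designs and pool
# matrices: TSV/CSV (dense) and Matrix Market (+ label sidecars).

write_dense_table <- function(X, path, sep) {
  X <- as_dense_matrix(X)
  rn <- rownames(X) %||% sprintf("row%d", seq_len(nrow(X)))
  cn <- colnames(X) %||% sprintf("col%d", seq_len(ncol(X)))
  con <- file(path, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(paste(c("id", cn), collapse = sep), con)
  body <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(rn[i], format_full(X[i, ])), collapse = sep)
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

read_dense_table <- function(path, sep) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               row.names = 1, comment.char = "", quote = ""),
    error = function(e) stop(sprintf("malformed table '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  X
}

ext_of <- function(path) tolower(tools::file_ext(path))

#' Read / write an expression matrix
#'
#' Cells x genes matrices round-trip losslessly through dense TSV (`.tsv`,
#' tab) or CSV (`.csv`, comma) with cell ids in the first column and gene
#' labels in the header, or through Matrix Market (`.mtx`) with `<path>.rows`
#' / `<path>.cols` label sidecars for sparse data.
#'
#' @param X cells x genes matrix.
#' @param path output/input path; format chosen by extension.
#' @return `write_expression()` returns the path invisibly;
#'   `read_expression()` returns the matrix.
#' @export
write_expression <- function(X, path) {
  switch(ext_of(path),
         tsv = write_dense_table(X, path, "\t"),
         csv = write_dense_table(X, path, ","),
         mtx = write_mtx_labeled(X, path),
         stop(sprintf("unsupported expression format '.%s' (use .tsv, .csv or .mtx)",
                      ext_of(path)), call. = FALSE))
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  switch(ext_of(path),
         tsv = read_dense_table(path, "\t"),
         csv = read_dense_table(path, ","),
         mtx = read_mtx_labeled(path),
         stop(sprintf("unsupported expression format '.%s'", ext_of(path)),
              call. = FALSE))
}

write_mtx_labeled <- function(X, path) {
  X <- as_dense_matrix(X)
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), path)
  writeLines(rownames(X) %||% sprintf("row%d", seq_len(nrow(X))),
             paste0(path, ".rows"))
  writeLines(colnames(X) %||% sprintf("col%d", seq_len(ncol(X))),
             paste0(path, ".cols"))
  invisible(path)
}

read_mtx_labeled <- function(path) {
  X <- as_dense_matrix(Matrix::readMM(path))
  rfile <- paste0(path, ".rows"); cfile <- paste0(path, ".cols")
  if (file.exists(rfile)) rownames(X) <- readLines(rfile)
  if (file.exists(cfile)) colnames(X) <- readLines(cfile)
  X
}

#' Read / write a pool design
#'
#' Wide format (`.csv`/`.tsv`): the 0/1 matrix with pool ids in the first
#' column and cell labels in the header. Long format (`format = "long"`,
#' CSV): one `pool_id,cell_id` row per membership — the plate-map table of
#' [export_pool_design()]. Matrix Market (`.mtx`) for sparse designs.
#'
#' @param M a [measurement_matrix()].
#' @param path file path; extension selects the encoding.
#' @param format `"wide"` (default) or `"long"` (CSV only).
#' @return `write_design()` the path, invisibly; `read_design()` a
#'   [measurement_matrix()].
#' @export
write_design <- function(M, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "long") {
    tab <- export_pool_design(M)
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(c("pool_id,cell_id",
                 paste(tab$pool_id, tab$cell_id, sep = ",")), con)
    return(invisible(path))
  }
  switch(ext_of(path),
         csv = write_dense_table(M, path, ","),
         tsv = write_dense_table(M, path, "\t"),
         mtx = write_mtx_labeled(M, path),
         stop(sprintf("unsupported design format '.%s'", ext_of(path)),
              call. = FALSE))
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  if (ext_of(path) == "mtx") {
    return(measurement_matrix(read_mtx_labeled(path)))
  }
  sep <- if (ext_of(path) == "tsv") "\t" else ","
  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  if (identical(header, c("pool_id", "cell_id"))) {
    tab <- read.table(path, header = TRUE, sep = ",",
                      colClasses = "character")
    return(import_pool_design(tab))
  }
  measurement_matrix(read_dense_table(path, sep))
}

#' Read / write pooled measurements
#'
#' Pools x genes matrices as TSV/CSV/Matrix Market, with a YAML sidecar
#' (`<path>.meta.yaml`) recording the `normalized` flag, design dimensions,
#' turbulence and seed, so a pool matrix can be reloaded with its provenance.
#'
#' @param Y a `pool_matrix` (or plain matrix).
#' @param path file path.
#' @param meta optional named list merged into the sidecar.
#' @return `write_pools()` the path, invisibly; `read_pools()` the matrix
#'   with sidecar fields re-attached as attributes.
#' @export
write_pools <- function(Y, path, meta = list()) {
  base_meta <- list(normalized = isTRUE(attr(Y, "normalized")),
                    design_dim = as.integer(attr(Y, "design_dim")))
  switch(ext_of(path),
         tsv = write_dense_table(Y, path, "\t"),
         csv = write_dense_table(Y, path, ","),
         mtx = write_mtx_labeled(Y, path),
         stop(sprintf("unsupported pool format '.%s'", ext_of(path)),
              call. = FALSE))
  yaml::write_yaml(modifyList(base_meta, meta), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_pools
#' @export
read_pools <- function(path) {
  Y <- switch(ext_of(path),
              tsv = read_dense_table(path, "\t"),
              csv = read_dense_table(path, ","),
              mtx = read_mtx_labeled(path),
              stop(sprintf("unsupported pool format '.%s'", ext_of(path)),
                   call. = FALSE))
  metafile <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(metafile)) yaml::read_yaml(metafile) else list()
  structure(Y, normalized = isTRUE(meta$normalized),
            design_dim = meta$design_dim,
            class = c("pool_matrix", "matrix", "array"))
}
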