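#' Read a ragged dataset from a Matrix Market bundle
#'
#' Reads a directory containing a sparse cells-by-genes count matrix in
#' Matrix Market format plus delimited annotation files, and partitions the
#' cells into one matrix per condition. Conditions are ordered by first
#' appearance in the cell annotation file, and cells keep file order within
#' each condition, so factorization output row order is reproducible.
#'
#' Expected bundle layout:
#' \describe{
#'   \item{`matrix.mtx`}{cells x genes sparse matrix}
#'   \item{`genes.tsv`}{one gene identifier per line, no header}
#'   \item{`cells.tsv`}{tab-separated with a header; must contain the column
#'     named by `condition_key`; an optional `label` column is read as
#'     per-cell annotation}
#'   \item{`conditions.tsv`}{optional per-condition metadata, tab-separated
#'     with a header and a `condition_id` column}
#' }
#'
#' @param path directory containing the bundle.
#' @param condition_key name of the column of `cells.tsv` holding the
#'   condition assignment.
#' @return a [ragged_dataset].
#' @export
read_dataset <- function(path, condition_key = "condition") {
  if (!dir.exists(path)) stop("bundle directory not found: ", path, call. = FALSE)
  mtx_file <- file.path(path, "matrix.mtx")
  genes_file <- file.path(path, "genes.tsv")
  cells_file <- file.path(path, "cells.tsv")
  for (f in c(mtx_file, genes_file, cells_file)) {
    if (!file.exists(f)) stop("bundle is missing ", basename(f), call. = FALSE)
  }
  m <- Matrix::readMM(mtx_file)
  genes <- readLines(genes_file)
  cells <- utils::read.delim(cells_file, stringsAsFactors = FALSE)
  if (!condition_key %in% names(cells)) {
    stop("condition_key '", condition_key, "' not found in cells.tsv ",
         "(configuration error)", call. = FALSE)
  }
  if (nrow(cells) != nrow(m)) {
    stop("cells.tsv row count does not match matrix rows (format error)",
         call. = FALSE)
  }
  if (length(genes) != ncol(m)) {
    stop("genes.tsv length does not match matrix columns (format error)",
         call. = FALSE)
  }
  cond <- as.character(cells[[condition_key]])
  if (anyNA(cond) || any(cond == "")) {
    stop("empty condition assignment for some cells (validation error)",
         call. = FALSE)
  }
  cond_ids <- unique(cond)                 # first-appearance order
  idx <- lapply(cond_ids, function(cid) which(cond == cid))
  mats <- lapply(idx, function(i) m[i, , drop = FALSE])
  labs <- if ("label" %in% names(cells)) {
    lapply(idx, function(i) as.character(cells$label[i]))
  } else NULL
  meta_file <- file.path(path, "conditions.tsv")
  meta <- if (file.exists(meta_file)) {
    utils::read.delim(meta_file, stringsAsFactors = FALSE)
  } else NULL
  ragged_dataset(mats, cond_ids, genes, labs, meta)
}

#' Write a ragged dataset as a Matrix Market bundle
#'
#' Inverse of [read_dataset()]: writes `matrix.mtx`, `genes.tsv`, `cells.tsv`
#' (and `conditions.tsv` when metadata is present) into `path`.
#'
#' @param ds a [ragged_dataset].
#' @param path output directory (created if needed).
#' @param condition_key column name to use for the condition assignment.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, condition_key = "condition") {
  stopifnot(inherits(ds, "ragged_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  js <- n_cells(ds)
  m <- methods::as(methods::as(Matrix::Matrix(concat_matrices(ds), sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(ds$gene_ids, file.path(path, "genes.tsv"))
  cells <- data.frame(cond = rep(ds$condition_ids, js),
                      stringsAsFactors = FALSE)
  names(cells) <- condition_key
  if (!is.null(ds$cell_labels)) cells$label <- unlist(ds$cell_labels, use.names = FALSE)
  utils::write.table(cells, file.path(path, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ds$condition_meta)) {
    meta <- ds$condition_meta
    if (!"condition_id" %in% names(meta)) {
      meta <- cbind(condition_id = ds$condition_ids, meta)
    }
    utils::write.table(meta, file.path(path, "conditions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_num_csv <- function(m, file) {
  m <- as.matrix(m)
  out <- apply(m, 2, fmt_num)
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(m))
  utils::write.table(out, file, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

read_num_csv <- function(file) {
  m <- as.matrix(utils::read.table(file, sep = ",", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Persist and restore a fitted Pf2 decomposition
#'
#' `write_decomposition()` writes all factor matrices, projections, component
#' weights and fit diagnostics into a plain-text directory bundle (CSV
#' matrices plus a JSON metadata file). `read_decomposition()` restores the
#' bundle; metadata round-trips exactly and floating point values round-trip
#' to full double precision.
#'
#' @param dec a fitted [pf2] object.
#' @param path output directory for the bundle.
#' @return `write_decomposition()` returns `path` invisibly;
#'   `read_decomposition()` returns the restored `pf2` object.
#' @export
write_decomposition <- function(dec, path) {
  stopifnot(inherits(dec, "pf2"))
  parent <- dirname(path)
  if (!dir.exists(parent)) {
    stop("cannot write decomposition: directory '", parent,
         "' does not exist (I/O error)", call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE)
  write_num_csv(dec$A, file.path(path, "A.csv"))
  write_num_csv(dec$B, file.path(path, "B.csv"))
  write_num_csv(dec$C, file.path(path, "C.csv"))
  write_num_csv(matrix(dec$weights, ncol = 1), file.path(path, "weights.csv"))
  for (i in seq_along(dec$projections)) {
    write_num_csv(dec$projections[[i]],
                  file.path(path, sprintf("projection_%03d.csv", i)))
  }
  meta <- list(rank = dec$rank,
               condition_ids = dec$condition_ids,
               gene_ids = dec$gene_ids,
               r2x = dec$r2x,
               n_iterations = dec$n_iterations,
               converged = dec$converged,
               standardized = dec$standardized)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decomposition
#' @param path directory holding a bundle written by `write_decomposition()`.
#' @export
read_decomposition <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop("no decomposition bundle at ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  proj_files <- sort(list.files(path, pattern = "^projection_\\d+\\.csv$",
                                full.names = TRUE))
  new_pf2(
    A = read_num_csv(file.path(path, "A.csv")),
    B = read_num_csv(file.path(path, "B.csv")),
    C = read_num_csv(file.path(path, "C.csv")),
    projections = lapply(proj_files, read_num_csv),
    weights = drop(read_num_csv(file.path(path, "weights.csv"))),
    rank = as.integer(meta$rank),
    condition_ids = meta$condition_ids,
    gene_ids = meta$gene_ids,
    r2x = meta$r2x,
    n_iterations = as.integer(meta$n_iterations),
    converged = meta$converged,
    standardized = meta$standardized
  )
}

#' Export condition and gene factors as delimited tables
#'
#' Writes the condition factor matrix A (conditions x components) and gene
#' factor matrix C (genes x components) as headered CSV files. Gene rows can
#' be restricted to those with at least one loading of magnitude
#' `min_abs_loading` or more (a display filter, not a model operation).
#'
#' @param dec a fitted [pf2] object.
#' @param a_file,c_file output CSV paths (either may be `NULL` to skip).
#' @param min_abs_loading nonnegative display threshold applied to C rows.
#' @export
export_factors <- function(dec, a_file = NULL, c_file = NULL,
                           min_abs_loading = 0) {
  stopifnot(inherits(dec, "pf2"))
  comp <- paste0("comp", seq_len(dec$rank))
  if (!is.null(a_file)) {
    a <- data.frame(condition_id = dec$condition_ids, dec$A)
    names(a) <- c("condition_id", comp)
    utils::write.csv(a, a_file, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(c_file)) {
    keep <- apply(abs(dec$C), 1, max) >= min_abs_loading
    cc <- data.frame(gene_id = dec$gene_ids[keep],
                     dec$C[keep, , drop = FALSE])
    names(cc) <- c("gene_id", comp)
    utils::write.csv(cc, c_file, row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

#' Concatenated cell projections
#'
#' Row-binds the per-condition projection matrices in condition order into a
#' single (total cells) x R matrix. This is the matrix handed to external
#' low-dimensional embedding tools (e.g. PaCMAP) for cell visualization.
#'
#' @param dec a fitted [pf2] object.
#' @return numeric matrix with `sum(J_i)` rows and `rank` columns.
#' @export
concatenated_projections <- function(dec) {
  stopifnot(inherits(dec, "pf2"))
  do.call(rbind, dec$projections)
}
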