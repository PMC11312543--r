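#' Ragged multi-condition expression dataset
#'
#' Bundles one cell-by-gene matrix per experimental condition. All matrices
#' share the same gene (column) axis; the number of cells (rows) may differ
#' per condition, which is what makes the collection "ragged" and precludes
#' stacking it into a single third-order tensor.
#'
#' @param matrices list of numeric matrices (dense or `Matrix` sparse), one
#'   per condition, each cells x genes with identical column counts.
#' @param condition_ids character vector of unique condition identifiers, one
#'   per matrix. Defaults to names of `matrices` or `cond1..condI`.
#' @param gene_ids character vector of unique gene identifiers, length equal
#'   to the shared column count. Defaults to colnames of the first matrix or
#'   `gene1..geneK`.
#' @param cell_labels optional per-cell annotation: either a list of vectors
#'   (one per condition) or a single vector of length `sum(J_i)` in condition
#'   order.
#' @param condition_meta optional data.frame of per-condition metadata with
#'   one row per condition (matched to `condition_ids` by a `condition_id`
#'   column if present, else by row order).
#' @return an object of class `"ragged_dataset"`: a list with fields
#'   `matrices`, `condition_ids`, `gene_ids`, `cell_labels` (list or NULL),
#'   `condition_meta` (data.frame or NULL).
#' @examples
#' x <- ragged_dataset(list(a = matrix(1:6, 2, 3), b = matrix(1:9, 3, 3)))
#' n_cells(x)
#' @export
ragged_dataset <- function(matrices, condition_ids = NULL, gene_ids = NULL,
                           cell_labels = NULL, condition_meta = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  if (is.null(condition_ids)) {
    condition_ids <- names(matrices)
    if (is.null(condition_ids)) {
      condition_ids <- paste0("cond", seq_along(matrices))
    }
  }
  condition_ids <- as.character(condition_ids)
  if (length(condition_ids) != length(matrices)) {
    stop("condition_ids length must equal the number of matrices", call. = FALSE)
  }
  if (anyDuplicated(condition_ids)) {
    stop("condition_ids must be unique", call. = FALSE)
  }
  ks <- vapply(matrices, ncol, integer(1))
  if (length(unique(ks)) != 1L) {
    stop("all matrices must share the same number of gene columns", call. = FALSE)
  }
  js <- vapply(matrices, nrow, integer(1))
  if (any(js < 1L)) {
    stop("every condition must contain at least one cell", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(matrices[[1]])
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ks[1]))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ks[1] || anyDuplicated(gene_ids)) {
    stop("gene_ids must be unique and match the shared column count", call. = FALSE)
  }
  if (!is.null(cell_labels)) {
    if (!is.list(cell_labels)) {
      if (length(cell_labels) != sum(js)) {
        stop("cell_labels must have one entry per cell", call. = FALSE)
      }
      cell_labels <- split(as.character(cell_labels),
                           rep(seq_along(js), js))
      names(cell_labels) <- condition_ids
    } else {
      if (length(cell_labels) != length(matrices) ||
          !all(lengths(cell_labels) == js)) {
        stop("cell_labels list must mirror the per-condition cell counts",
             call. = FALSE)
      }
      cell_labels <- lapply(cell_labels, as.character)
      names(cell_labels) <- condition_ids
    }
  }
  if (!is.null(condition_meta)) {
    condition_meta <- as.data.frame(condition_meta)
    if (nrow(condition_meta) != length(matrices)) {
      stop("condition_meta must have one row per condition", call. = FALSE)
    }
    if ("condition_id" %in% names(condition_meta)) {
      idx <- match(condition_ids, as.character(condition_meta$condition_id))
      if (anyNA(idx)) stop("condition_meta is missing some conditions", call. = FALSE)
      condition_meta <- condition_meta[idx, , drop = FALSE]
    }
    rownames(condition_meta) <- condition_ids
  }
  names(matrices) <- condition_ids
  structure(
    list(matrices = matrices, condition_ids = condition_ids,
         gene_ids = gene_ids, cell_labels = cell_labels,
         condition_meta = condition_meta),
    class = "ragged_dataset"
  )
}

#' @rdname ragged_dataset
#' @param x a `ragged_dataset`.
#' @export
n_cells <- function(x) {
  stopifnot(inherits(x, "ragged_dataset"))
  vapply(x$matrices, nrow, integer(1))
}

#' @rdname ragged_dataset
#' @export
n_conditions <- function(x) {
  stopifnot(inherits(x, "ragged_dataset"))
  length(x$matrices)
}

#' @rdname ragged_dataset
#' @export
n_genes <- function(x) {
  stopifnot(inherits(x, "ragged_dataset"))
  length(x$gene_ids)
}

#' @export
print.ragged_dataset <- function(x, ...) {
  js <- n_cells(x)
  cat(sprintf("ragged_dataset: %d conditions, %d cells total, %d genes\n",
              length(js), sum(js), n_genes(x)))
  show <- utils::head(sprintf("%s (%d cells)", x$condition_ids, js), 8)
  cat("  ", paste(show, collapse = ", "),
      if (length(js) > 8) ", ..." else "", "\n", sep = "")
  if (!is.null(x$cell_labels)) {
    cat("  cell labels:", paste(utils::head(unique(unlist(x$cell_labels)), 6),
                                collapse = ", "), "\n")
  }
  if (!is.null(x$condition_meta)) {
    cat("  condition metadata:", paste(names(x$condition_meta), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Row-bind all condition matrices (dense) in condition order.
concat_matrices <- function(ds) {
  do.call(rbind, lapply(ds$matrices, as_dense))
}

# Subset a dataset to per-condition row indices (list parallel to matrices).
subset_cells <- function(ds, idx_list) {
  mats <- mapply(function(m, idx) m[idx, , drop = FALSE],
                 ds$matrices, idx_list, SIMPLIFY = FALSE)
  labs <- if (is.null(ds$cell_labels)) NULL else {
    mapply(function(l, idx) l[idx], ds$cell_labels, idx_list, SIMPLIFY = FALSE)
  }
  ragged_dataset(mats, ds$condition_ids, ds$gene_ids, labs, ds$condition_meta)
}
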