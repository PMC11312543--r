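#' Filter genes by pooled mean raw expression
#'
#' Drops genes whose mean raw count across all cells, pooled over every
#' condition, falls below `min_gene_mean`. The thresholds used for the
#' datasets this pipeline was designed around were 0.01 (tens of thousands of
#' cells) and 0.1 (about a million cells).
#'
#' @param ds a [ragged_dataset] of raw counts.
#' @param min_gene_mean nonnegative pooled-mean threshold.
#' @return the filtered [ragged_dataset]; condition structure is unchanged.
#' @export
filter_genes <- function(ds, min_gene_mean = 0.01) {
  stopifnot(inherits(ds, "ragged_dataset"), min_gene_mean >= 0)
  total <- Reduce(`+`, lapply(ds$matrices, function(m) Matrix::colSums(m)))
  mu <- as.numeric(total) / sum(n_cells(ds))
  keep <- mu >= min_gene_mean
  if (!any(keep)) {
    stop("gene filtering removed all genes (validation error)", call. = FALSE)
  }
  mats <- lapply(ds$matrices, function(m) m[, keep, drop = FALSE])
  ragged_dataset(mats, ds$condition_ids, ds$gene_ids[keep],
                 ds$cell_labels, ds$condition_meta)
}

#' Normalize a raw-count dataset for Pf2 fitting
#'
#' Applies, in order: (1) per-cell counts-per-million scaling (each cell row
#' rescaled to total `cpm_scale`); (2) optional per-gene scaling by the
#' gene's pooled total, rescaled by the total cell count so a uniformly
#' expressed gene keeps unit magnitude; (3) the delta-method variance-
#' stabilizing transform `g(y) = log(y + pseudocount)` (natural log); (4)
#' optional per-gene mean-centering pooled across all cells. Centering is
#' pooled rather than per-condition on purpose: per-condition centering
#' would delete exactly the condition-level signal the condition factors are
#' meant to capture.
#'
#' @param ds a [ragged_dataset] of (filtered) raw counts.
#' @param cpm_scale per-cell target total (default 1e6).
#' @param pseudocount positive constant added inside the log (default 100).
#' @param gene_sum_scale scale each gene by its pooled sum (default TRUE).
#' @param center mean-center each gene across all pooled cells (default TRUE).
#' @return the normalized [ragged_dataset] (dense matrices).
#' @export
normalize_dataset <- function(ds, cpm_scale = 1e6, pseudocount = 100,
                              gene_sum_scale = TRUE, center = TRUE) {
  stopifnot(inherits(ds, "ragged_dataset"), cpm_scale > 0, pseudocount > 0)
  mats <- lapply(ds$matrices, as_dense)
  # (1) per-cell CPM
  for (i in seq_along(mats)) {
    rs <- rowSums(mats[[i]])
    if (any(rs == 0)) {
      bad <- which(rs == 0)[1]
      stop(sprintf(
        "cell %d of condition '%s' has zero total count (validation error)",
        bad, ds$condition_ids[i]), call. = FALSE)
    }
    mats[[i]] <- mats[[i]] * (cpm_scale / rs)
  }
  # (2) per-gene scaling by pooled sum, kept at unit scale via the cell count
  if (gene_sum_scale) {
    gs <- Reduce(`+`, lapply(mats, colSums))
    if (any(gs == 0)) gs[gs == 0] <- 1   # all-zero gene: leave as zeros
    ncell <- sum(n_cells(ds))
    for (i in seq_along(mats)) {
      mats[[i]] <- sweep(mats[[i]], 2, gs / ncell, `/`)
    }
  }
  # (3) delta-method log transform
  mats <- lapply(mats, function(m) log(m + pseudocount))
  # (4) pooled per-gene centering
  if (center) {
    ncell <- sum(n_cells(ds))
    mu <- Reduce(`+`, lapply(mats, colSums)) / ncell
    mats <- lapply(mats, function(m) sweep(m, 2, mu, `-`))
  }
  ragged_dataset(mats, ds$condition_ids, ds$gene_ids,
                 ds$cell_labels, ds$condition_meta)
}

#' @describeIn normalize_dataset Convenience wrapper running
#'   [filter_genes()] then [normalize_dataset()].
#' @param min_gene_mean pooled-mean filter threshold passed to
#'   [filter_genes()].
#' @export
preprocess_dataset <- function(ds, min_gene_mean = 0.01, cpm_scale = 1e6,
                               pseudocount = 100, gene_sum_scale = TRUE,
                               center = TRUE) {
  normalize_dataset(filter_genes(ds, min_gene_mean),
                    cpm_scale = cpm_scale, pseudocount = pseudocount,
                    gene_sum_scale = gene_sum_scale, center = center)
}
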