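#' Factor match score between two decompositions
#'
#' Quantifies the similarity of two Pf2 factorizations of the same
#' conditions and genes. For a matched component pair (r, s) the score is
#' `(1 - |w_r - w_s| / max(w_r, w_s)) * |cos(A[, r], A[, s])| *
#' |cos(C[, r], C[, s])|`, where `w` is the per-component magnitude (the
#' component weights once both inputs are standardized), normalized to
#' relative shares within each decomposition so that comparisons across
#' datasets of different cell counts penalize redistributions of weight
#' among components, not the overall data scale. Components are
#' matched by a linear sum assignment maximizing the total score, and the
#' mean matched score over the `R` components is returned, so identical
#' factorizations score exactly 1 regardless of component order or sign
#' convention. The eigen-state factors are excluded: their rows refer to
#' cell eigen-states whose meaning shifts with the cells present. Cosines
#' are compared in magnitude because the eigen-state frame carries an
#' orthogonal gauge freedom (`P_i -> P_i Q`, `B -> Q'B` leaves the model
#' unchanged), which makes the gene factors' signs arbitrary between two
#' independently fitted, otherwise identical decompositions.
#'
#' @param dec1,dec2 fitted [pf2] objects of equal rank over the same
#'   conditions and genes; non-standardized inputs are standardized
#'   internally.
#' @return a number no greater than 1; 1 indicates complete similarity.
#' @export
fms <- function(dec1, dec2) {
  stopifnot(inherits(dec1, "pf2"), inherits(dec2, "pf2"))
  if (dec1$rank != dec2$rank) {
    stop("decompositions have different ranks (validation error)", call. = FALSE)
  }
  if (length(dec1$gene_ids) != length(dec2$gene_ids) ||
      length(dec1$condition_ids) != length(dec2$condition_ids)) {
    stop("decompositions cover different condition or gene sets", call. = FALSE)
  }
  if (!isTRUE(dec1$standardized)) dec1 <- pf2_standardize(dec1)
  if (!isTRUE(dec2$standardized)) dec2 <- pf2_standardize(dec2)
  r <- dec1$rank
  w1 <- dec1$weights; w2 <- dec2$weights
  if (any(w1 == 0) || any(w2 == 0)) {
    stop("zero-norm component (validation error)", call. = FALSE)
  }
  # relative component magnitudes: the penalty compares how weight is shared
  # among components, not the overall dataset scale (which grows with cell
  # count and would otherwise dominate comparisons across data sizes)
  w1 <- w1 / sum(w1)
  w2 <- w2 / sum(w2)
  # columns are unit norm after standardization, so crossprod is the cosine
  cos_a <- abs(crossprod(dec1$A, dec2$A))
  cos_c <- abs(crossprod(dec1$C, dec2$C))
  wpen <- 1 - abs(outer(w1, w2, `-`)) / outer(w1, w2, pmax)
  score <- wpen * cos_a * cos_c
  perm <- solve_lsap(score, maximize = TRUE)
  mean(score[cbind(seq_len(r), perm)])
}

#' Subsample cells within every condition
#'
#' Draws `ceiling(fraction * J_i)` cells per condition without replacement,
#' keeping the drawn cells in their original within-condition order (so
#' projection row order stays reproducible) and carrying labels along.
#'
#' @param ds a [ragged_dataset].
#' @param fraction fraction of cells to keep, in (0, 1].
#' @param seed integer seed.
#' @return the subsampled [ragged_dataset].
#' @export
subsample_cells <- function(ds, fraction, seed = 0L) {
  stopifnot(inherits(ds, "ragged_dataset"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1] (validation error)", call. = FALSE)
  }
  js <- n_cells(ds)
  idx <- with_seed(seed, lapply(js, function(j) {
    sort(sample.int(j, ceiling(fraction * j)))
  }))
  subset_cells(ds, idx)
}

#' Bootstrap-resample cells within every condition
#'
#' Draws `J_i` cells with replacement per condition, producing a dataset of
#' identical shape; drawn cells keep ascending original order.
#'
#' @param ds a [ragged_dataset].
#' @param seed integer seed.
#' @return the resampled [ragged_dataset].
#' @export
bootstrap_cells <- function(ds, seed = 0L) {
  stopifnot(inherits(ds, "ragged_dataset"))
  js <- n_cells(ds)
  idx <- with_seed(seed, lapply(js, function(j) {
    sort(sample.int(j, j, replace = TRUE))
  }))
  subset_cells(ds, idx)
}

#' Factorization stability under subsampling or bootstrapping
#'
#' Two protocols probing how much the condition and gene factors depend on
#' the particular cells measured. `"subsample"`: the full dataset is fitted
#' once, then refitted on each cell-subsampled copy at the same rank, and
#' the factor match score (FMS) against the full fit is recorded per
#' (fraction, seed). `"bootstrap"`: for each rank in `levels`, the original
#' dataset and one bootstrap replicate are both fitted and their FMS
#' recorded per (rank, seed).
#'
#' @param ds a preprocessed [ragged_dataset].
#' @param rank rank used by the subsample protocol.
#' @param protocol `"subsample"` or `"bootstrap"`.
#' @param levels subsample fractions, or ranks for the bootstrap protocol.
#' @param seeds integer vector of resampling seeds.
#' @param ... further arguments passed to [pf2()] (e.g. `tol`, `max_iter`).
#' @return a data.frame of class `"pf2_stability"` with columns `protocol`,
#'   `level`, `seed`, `fms`.
#' @export
stability_curve <- function(ds, rank, protocol = c("subsample", "bootstrap"),
                            levels, seeds = 0L, ...) {
  stopifnot(inherits(ds, "ragged_dataset"), length(levels) >= 1)
  protocol <- match.arg(protocol)
  rows <- list()
  if (protocol == "subsample") {
    full <- pf2(ds, rank, ...)
    for (f in levels) {
      for (s in seeds) {
        sub <- subsample_cells(ds, f, seed = s)
        fit_sub <- tryCatch(pf2(sub, rank, ...), error = function(e) {
          stop(sprintf("fit failed at fraction %g, seed %d: %s",
                       f, s, conditionMessage(e)), call. = FALSE)
        })
        rows[[length(rows) + 1]] <-
          data.frame(protocol = protocol, level = f, seed = s,
                     fms = fms(full, fit_sub))
      }
    }
  } else {
    for (rk in levels) {
      for (s in seeds) {
        fit_full <- pf2(ds, rk, ...)
        boot <- bootstrap_cells(ds, seed = s)
        fit_boot <- tryCatch(pf2(boot, rk, ...), error = function(e) {
          stop(sprintf("fit failed at rank %d, seed %d: %s",
                       rk, s, conditionMessage(e)), call. = FALSE)
        })
        rows[[length(rows) + 1]] <-
          data.frame(protocol = protocol, level = rk, seed = s,
                     fms = fms(fit_full, fit_boot))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pf2_stability", "data.frame")
  out
}

#' Remove or thin a labeled cell type within one condition
#'
#' Emulates an experiment in which a cell type is depleted in a single
#' condition: within `condition_id`, cells carrying `label` are subsampled
#' without replacement to `keep_fraction` of their count (0 removes them
#' all); every other cell, and every other condition, is untouched.
#'
#' @param ds a [ragged_dataset] with cell labels.
#' @param label cell-type label to thin.
#' @param condition_id condition in which to thin it.
#' @param keep_fraction fraction of labeled cells to keep, in `[0, 1]`.
#' @param seed integer seed for the partial-thinning draw.
#' @return the perturbed [ragged_dataset].
#' @export
ablate_cell_type <- function(ds, label, condition_id, keep_fraction = 0,
                             seed = 0L) {
  stopifnot(inherits(ds, "ragged_dataset"))
  if (is.null(ds$cell_labels)) {
    stop("dataset has no cell labels (validation error)", call. = FALSE)
  }
  ci <- match(condition_id, ds$condition_ids)
  if (is.na(ci)) stop("unknown condition '", condition_id, "'", call. = FALSE)
  if (!label %in% unlist(ds$cell_labels)) {
    stop("unknown cell label '", label, "'", call. = FALSE)
  }
  if (keep_fraction < 0 || keep_fraction > 1) {
    stop("keep_fraction must lie in [0, 1] (validation error)", call. = FALSE)
  }
  labs <- ds$cell_labels[[ci]]
  hit <- which(labs == label)
  n_keep <- floor(keep_fraction * length(hit))
  kept <- if (n_keep == 0) integer(0) else {
    with_seed(seed, sort(sample(hit, n_keep)))
  }
  idx_i <- sort(c(setdiff(seq_along(labs), hit), kept))
  if (!length(idx_i)) {
    stop("ablation would empty condition '", condition_id,
         "' (validation error)", call. = FALSE)
  }
  idx <- lapply(seq_along(ds$matrices), function(i) {
    if (i == ci) idx_i else seq_len(nrow(ds$matrices[[i]]))
  })
  subset_cells(ds, idx)
}

#' Condition-weight differences for a matched component
#'
#' Matches the components of a reference and a perturbed (e.g. cell-type
#' ablated) decomposition via the FMS assignment, then returns the
#' difference in standardized condition-factor weights for the requested
#' reference component: `A_ref[, r] - A_perturbed[, matched(r)]`. A positive
#' entry means the perturbed fit assigns that condition less weight on the
#' component — the expected direction for the condition whose driving cells
#' were removed.
#'
#' @param dec_ref,dec_perturbed standardized [pf2] objects of equal rank.
#' @param component reference component index.
#' @param min_gene_cosine matching floor: the matched pair must have at
#'   least this absolute cosine similarity between gene-factor columns.
#' @return named numeric vector of per-condition weight differences, with
#'   attribute `matched_component` (index in `dec_perturbed`).
#' @export
compare_condition_weights <- function(dec_ref, dec_perturbed, component,
                                      min_gene_cosine = 0.5) {
  stopifnot(inherits(dec_ref, "pf2"), inherits(dec_perturbed, "pf2"))
  if (dec_ref$rank != dec_perturbed$rank) {
    stop("rank mismatch (validation error)", call. = FALSE)
  }
  if (!isTRUE(dec_ref$standardized)) dec_ref <- pf2_standardize(dec_ref)
  if (!isTRUE(dec_perturbed$standardized)) {
    dec_perturbed <- pf2_standardize(dec_perturbed)
  }
  component <- as.integer(component)
  stopifnot(component >= 1L, component <= dec_ref$rank)
  cos_a <- abs(crossprod(dec_ref$A, dec_perturbed$A))
  cos_c <- abs(crossprod(dec_ref$C, dec_perturbed$C))
  w1 <- dec_ref$weights; w2 <- dec_perturbed$weights
  wpen <- 1 - abs(outer(w1, w2, `-`)) / outer(w1, w2, pmax)
  perm <- solve_lsap(wpen * cos_a * cos_c, maximize = TRUE)
  s <- perm[component]
  if (abs(cos_c[component, s]) < min_gene_cosine) {
    stop(sprintf(
      "no component matches reference component %d (gene cosine %.3f < %.2f)",
      component, cos_c[component, s], min_gene_cosine), call. = FALSE)
  }
  diff <- dec_ref$A[, component] - dec_perturbed$A[, s]
  names(diff) <- dec_ref$condition_ids
  attr(diff, "matched_component") <- s
  diff
}
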