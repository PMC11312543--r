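#' Gini coefficient of a loading vector
#'
#' Mean-absolute-difference Gini index,
#' `sum_jk |v_j - v_k| / (2 n sum_j v_j)`, computed on absolute values. Used
#' to order components from condition-shared (low Gini) to
#' condition-specific (high Gini).
#'
#' @param v numeric vector, not all zero; absolute values are taken first.
#' @return a number in `[0, 1)`.
#' @examples
#' gini(c(1, 0, 0, 0))  # 0.75
#' @export
gini <- function(v) {
  v <- abs(v)
  stopifnot(length(v) >= 1)
  s <- sum(v)
  if (s == 0) stop("Gini undefined for an all-zero vector", call. = FALSE)
  n <- length(v)
  # sorted form of the double-loop mean absolute difference
  vs <- sort(v)
  sum((2 * seq_len(n) - n - 1) * vs) / (n * s)
}

#' Post-factorization alignment of a Pf2 decomposition
#'
#' Resolves the three indeterminacies of a CP-type factorization into fixed
#' reporting conventions, leaving the reconstruction unchanged:
#' \enumerate{
#'   \item scale: each column of A, B and C is divided by its Euclidean
#'     norm; the product of the three norms becomes that component's weight;
#'   \item sign: per component, signs are flipped so the means of the A and
#'     B columns are nonnegative, with compensating flips moved to the C
#'     column;
#'   \item order: components are sorted by ascending Gini coefficient of the
#'     absolute A column (ties broken by original component index), so
#'     components shared across conditions come first.
#' }
#'
#' @param dec a fitted [pf2] object.
#' @return the standardized `pf2` object (`standardized = TRUE`); applying
#'   the function again is a no-op.
#' @export
pf2_standardize <- function(dec) {
  stopifnot(inherits(dec, "pf2"))
  a <- dec$A; b <- dec$B; cc <- dec$C
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2)); nc <- sqrt(colSums(cc^2))
  if (any(na == 0 | nb == 0 | nc == 0)) {
    bad <- which(na == 0 | nb == 0 | nc == 0)[1]
    stop("component ", bad, " has a zero-norm factor column", call. = FALSE)
  }
  a <- sweep(a, 2, na, `/`)
  b <- sweep(b, 2, nb, `/`)
  cc <- sweep(cc, 2, nc, `/`)
  w <- dec$weights * na * nb * nc
  # sign convention: nonnegative A and B column means, flips absorbed by C
  sa <- ifelse(colMeans(a) < 0, -1, 1)
  sb <- ifelse(colMeans(b) < 0, -1, 1)
  a <- sweep(a, 2, sa, `*`)
  b <- sweep(b, 2, sb, `*`)
  cc <- sweep(cc, 2, sa * sb, `*`)
  ord <- order(apply(a, 2, gini), seq_len(ncol(a)))
  out <- dec
  out$A <- a[, ord, drop = FALSE]
  out$B <- b[, ord, drop = FALSE]
  out$C <- cc[, ord, drop = FALSE]
  out$weights <- w[ord]
  out$standardized <- TRUE
  out
}

#' Per-cell component association scores
#'
#' Multiplies each condition's projection matrix by the eigen-state factor
#' matrix, `W_i = P_i %*% B`, giving every cell a score for every component.
#' These are the values used to color cell embeddings by component.
#'
#' @param dec a standardized [pf2] object (see [pf2_standardize()]).
#' @return list of `J_i x R` score matrices in condition order, with a
#'   `concatenated` attribute holding the row-bound `sum(J_i) x R` matrix.
#' @export
weighted_projections <- function(dec) {
  stopifnot(inherits(dec, "pf2"))
  if (!isTRUE(dec$standardized)) dec <- pf2_standardize(dec)
  w <- lapply(dec$projections, function(p) p %*% dec$B)
  names(w) <- dec$condition_ids
  attr(w, "concatenated") <- do.call(rbind, w)
  w
}
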