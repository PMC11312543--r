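#' Fit the PARAFAC2 (Pf2) decomposition to a ragged dataset
#'
#' Decomposes a collection of cell-by-gene matrices `X_i` (one per condition,
#' with varying cell counts) as `X_i ~ P_i B diag(a_i) C'`, where the `P_i`
#' are per-condition matrices with orthonormal columns projecting cells onto
#' a shared rank-`rank` eigen-state frame, `B` holds the eigen-state factors,
#' `A` (rows `a_i`) the condition factors and `C` the gene factors.
#'
#' The direct fitting algorithm alternates (1) an orthogonal-Procrustes
#' update of every `P_i` given the factors with (2) `cpd_iter` warm-started
#' CP-ALS sweeps on the aligned `I x rank x K` tensor whose slice `i` is
#' `t(P_i) %*% X_i`. Iteration stops when the change in R2X (fraction of
#' variance explained) between successive iterations drops below `tol` or
#' after `max_iter` iterations. An optional all-at-once Nesterov-like
#' extrapolation of the factor matrices accelerates convergence; extrapolated
#' steps that worsen the objective are rejected so the monotone convergence
#' of plain ALS is preserved.
#'
#' @param ds a [ragged_dataset] (normally preprocessed, see
#'   [normalize_dataset()]).
#' @param rank number of components; must not exceed the gene count or the
#'   smallest condition's cell count.
#' @param max_iter maximum number of outer iterations (default 200).
#' @param tol convergence tolerance on the absolute change in R2X between
#'   iterations (default 1e-6).
#' @param cpd_iter CP-ALS sweeps per outer iteration (default 20).
#' @param accelerate use the Nesterov-like extrapolation (default TRUE).
#' @param gamma,gamma_bar,eta,beta0,beta0_bar extrapolation step-size
#'   parameters: on an accepted step the momentum grows by `gamma` up to a
#'   running bound grown by `gamma_bar`; on a rejected step it shrinks by
#'   `eta`. Defaults 1.1, 1.03, 1.5, 0.05, 1.
#' @param svd_method `"exact"` (LAPACK) or `"randomized"` (seeded randomized
#'   SVD, oversampling 10, two power iterations) for initialization.
#' @param seed integer seed controlling every random draw in the fit.
#' @param standardize apply the post-factorization alignment conventions
#'   ([pf2_standardize()]) to the returned object (default TRUE).
#' @param verbose print per-iteration R2X.
#' @return an object of class `"pf2"` with fields `A` (I x R condition
#'   factors), `B` (R x R eigen-state factors), `C` (K x R gene factors),
#'   `projections` (list of J_i x R orthonormal matrices), `weights`
#'   (length-R component scales; all 1 until standardization), `r2x`,
#'   `r2x_trace`, `n_iterations`, `converged`, `standardized`,
#'   `condition_ids`, `gene_ids`, `pinv_used`, `call`.
#' @seealso [pf2_standardize()], [weighted_projections()], [fms()],
#'   [pf2_sim()]
#' @examples
#' sim <- pf2_sim(n_conditions = 4, cells = c(10, 15), n_genes = 12,
#'                rank = 2, noise_sd = 0, seed = 1)
#' fit <- pf2(sim$dataset, rank = 2, seed = 1)
#' fit$r2x
#' @export
pf2 <- function(ds, rank, max_iter = 200L, tol = 1e-6, cpd_iter = 20L,
                accelerate = TRUE, gamma = 1.1, gamma_bar = 1.03, eta = 1.5,
                beta0 = 0.05, beta0_bar = 1.0,
                svd_method = c("exact", "randomized"), seed = 0L,
                standardize = TRUE, verbose = FALSE) {
  stopifnot(inherits(ds, "ragged_dataset"))
  svd_method <- match.arg(svd_method)
  rank <- as.integer(rank)
  js <- n_cells(ds)
  k <- n_genes(ds)
  if (rank < 1L || rank > min(k, min(js))) {
    stop("rank exceeds smallest condition's cell count or gene count",
         call. = FALSE)
  }
  xs <- lapply(ds$matrices, as_dense)
  norm_x2 <- sum(vapply(xs, function(m) sum(m^2), numeric(1)))
  if (norm_x2 == 0) stop("all-zero dataset (validation error)", call. = FALSE)

  fac <- init_factors(ds, rank, svd_method = svd_method, seed = seed)

  # objective evaluation for a candidate factor set: best projections given
  # the factors, the aligned tensor, and the resulting R2X
  eval_state <- function(fac) {
    proj <- update_projections_mats(xs, fac$A, fac$B, fac$C)
    tt <- project_mats(xs, proj, rank, k)
    m <- fac$A %*% t(khatri_rao(fac$C, fac$B))      # I x RK, vs unfold1(tt)
    err <- norm_x2 - sum(tt^2) + sum((unfold1(tt) - m)^2)
    list(proj = proj, tt = tt, r2x = 1 - err / norm_x2)
  }

  state <- eval_state(fac)
  beta <- beta0
  beta_bar <- beta0_bar
  prev_fac <- fac
  r2x_trace <- numeric(0)
  r2x_prev <- -Inf
  converged <- FALSE
  pinv_used <- FALSE
  n_done <- 0L

  for (it in seq_len(max_iter)) {
    cp <- cp_als(state$tt, rank, n_iter = cpd_iter,
                 init = list(A = fac$A, B = fac$B, C = fac$C))
    pinv_used <- pinv_used || cp$pinv_used
    new_fac <- list(A = cp$A, B = cp$B, C = cp$C)
    new_state <- eval_state(new_fac)
    if (!is.finite(new_state$r2x)) {
      stop("non-finite values encountered at iteration ", it,
           " (numeric error)", call. = FALSE)
    }
    if (accelerate && it > 1L) {
      ex_fac <- list(A = new_fac$A + beta * (new_fac$A - prev_fac$A),
                     B = new_fac$B + beta * (new_fac$B - prev_fac$B),
                     C = new_fac$C + beta * (new_fac$C - prev_fac$C))
      ex_state <- tryCatch(eval_state(ex_fac), error = function(e) NULL)
      if (!is.null(ex_state) && is.finite(ex_state$r2x) &&
          ex_state$r2x > new_state$r2x) {
        new_fac <- ex_fac
        new_state <- ex_state
        beta <- min(gamma * beta, beta_bar)
        beta_bar <- gamma_bar * beta_bar
      } else {
        beta <- beta / eta
      }
    }
    prev_fac <- fac
    fac <- new_fac
    state <- new_state
    r2x_trace <- c(r2x_trace, state$r2x)
    if (verbose) {
      message(sprintf("iter %3d  R2X = %.8f", it, state$r2x))
    }
    n_done <- it
    if (is.finite(r2x_prev) && abs(state$r2x - r2x_prev) < tol) {
      converged <- TRUE
      break
    }
    r2x_prev <- state$r2x
  }

  out <- new_pf2(A = fac$A, B = fac$B, C = fac$C, projections = state$proj,
                 weights = rep(1, rank), rank = rank,
                 condition_ids = ds$condition_ids, gene_ids = ds$gene_ids,
                 r2x = state$r2x, n_iterations = n_done,
                 converged = converged, standardized = FALSE)
  out$r2x_trace <- r2x_trace
  out$pinv_used <- pinv_used
  out$call <- match.call()
  if (standardize) out <- pf2_standardize(out)
  out
}

# low-level constructor shared with the bundle reader
new_pf2 <- function(A, B, C, projections, weights, rank, condition_ids,
                    gene_ids, r2x = NA_real_, n_iterations = NA_integer_,
                    converged = NA, standardized = FALSE) {
  structure(
    list(A = as.matrix(A), B = as.matrix(B), C = as.matrix(C),
         projections = lapply(projections, as.matrix),
         weights = as.numeric(weights), rank = as.integer(rank),
         condition_ids = as.character(condition_ids),
         gene_ids = as.character(gene_ids),
         r2x = r2x, n_iterations = n_iterations, converged = converged,
         standardized = isTRUE(standardized)),
    class = "pf2"
  )
}

#' Factor initialization for the Pf2 algorithm
#'
#' Concatenates the condition matrices along the cell axis, takes the
#' truncated SVD of the pooled cells-by-genes matrix, and initializes the
#' gene factors `C` with the first `rank` right singular vectors; the
#' eigen-state factors `B` start at the identity and the condition factors
#' `A` at all ones. Projections are left unset (they are computed in the
#' first fitting iteration).
#'
#' @inheritParams pf2
#' @return list with matrices `A` (I x rank of ones), `B` (rank x rank
#'   identity) and `C` (K x rank, orthonormal columns).
#' @export
init_factors <- function(ds, rank, svd_method = c("exact", "randomized"),
                         seed = 0L) {
  stopifnot(inherits(ds, "ragged_dataset"))
  svd_method <- match.arg(svd_method)
  rank <- as.integer(rank)
  js <- n_cells(ds)
  if (rank > min(n_genes(ds), min(js))) {
    stop("rank exceeds smallest condition's cell count or gene count",
         call. = FALSE)
  }
  concat <- concat_matrices(ds)
  s <- truncated_svd(concat, rank, method = svd_method, seed = seed)
  list(A = matrix(1, n_conditions(ds), rank),
       B = diag(rank),
       C = s$v)
}

# matrix-level Procrustes update (exported wrapper below)
update_projections_mats <- function(xs, A, B, C) {
  r <- ncol(A)
  lapply(seq_along(xs), function(i) {
    m <- B %*% (t(C) * A[i, ])                 # B diag(a_i) C' : R x K
    s <- m %*% t(xs[[i]])                      # R x J_i
    if (all(s == 0)) {
      stop("projection update degenerate for condition ", i,
           ": B diag(a_i) C' X_i' is all zero", call. = FALSE)
    }
    sv <- svd(s, nu = r, nv = r)
    sv$v %*% t(sv$u)                           # J_i x R, orthonormal columns
  })
}

#' Orthogonal-Procrustes projection update
#'
#' Given current factors, updates each condition's projection matrix `P_i`
#' as the orthogonal Procrustes minimizer of `||X_i - P_i B diag(a_i) C'||`
#' over matrices with orthonormal columns: with the SVD
#' `B diag(a_i) C' X_i' = U S V'`, the solution is `P_i = V U'`.
#'
#' @param ds a [ragged_dataset].
#' @param A,B,C factor matrices of shapes I x R, R x R and K x R.
#' @return list of `J_i x R` matrices with orthonormal columns, one per
#'   condition.
#' @export
update_projections <- function(ds, A, B, C) {
  stopifnot(inherits(ds, "ragged_dataset"))
  r <- ncol(A)
  js <- n_cells(ds)
  if (any(js < r)) {
    stop("every condition needs at least as many cells as the rank",
         call. = FALSE)
  }
  stopifnot(nrow(A) == n_conditions(ds), nrow(C) == n_genes(ds),
            nrow(B) == r, ncol(B) == r, ncol(C) == r)
  update_projections_mats(lapply(ds$matrices, as_dense), A, B, C)
}

project_mats <- function(xs, proj, r, k) {
  tt <- array(0, c(length(xs), r, k))
  for (i in seq_along(xs)) tt[i, , ] <- crossprod(proj[[i]], xs[[i]])
  tt
}

#' Project a ragged dataset onto the eigen-state frame
#'
#' Builds the aligned third-order tensor whose slice `i` along the first
#' mode is `t(P_i) %*% X_i` (shape `R x K`). This is the tensor the CP-ALS
#' sub-step of the Pf2 algorithm operates on.
#'
#' @param ds a [ragged_dataset].
#' @param projections list of per-condition `J_i x R` projection matrices.
#' @return numeric array of dim `c(I, R, K)`.
#' @export
project_data <- function(ds, projections) {
  stopifnot(inherits(ds, "ragged_dataset"),
            length(projections) == n_conditions(ds))
  js <- n_cells(ds)
  r <- ncol(projections[[1]])
  ok <- vapply(seq_along(projections), function(i) {
    nrow(projections[[i]]) == js[i] && ncol(projections[[i]]) == r
  }, logical(1))
  if (!all(ok)) stop("projection shapes do not match the dataset", call. = FALSE)
  project_mats(lapply(ds$matrices, as_dense), projections, r, n_genes(ds))
}

#' Reconstruct the dataset from a fitted decomposition
#'
#' Returns the model reconstruction `X_hat_i = P_i B diag(w * a_i) C'` for
#' every condition, with the component weights folded back in when the
#' decomposition has been standardized.
#'
#' @param dec a fitted [pf2] object.
#' @return list of `J_i x K` matrices in condition order.
#' @export
reconstruct <- function(dec) {
  stopifnot(inherits(dec, "pf2"))
  aw <- sweep(dec$A, 2, dec$weights, `*`)
  lapply(seq_along(dec$projections), function(i) {
    dec$projections[[i]] %*% dec$B %*% (t(dec$C) * aw[i, ])
  })
}

#' Fraction of variance explained (R2X)
#'
#' Computes `1 - sum_i ||X_i - X_hat_i||_F^2 / sum_i ||X_i||_F^2`, the
#' fraction of the dataset's total squared Frobenius norm captured by the
#' model reconstruction. Equals 1 exactly when the reconstruction is exact;
#' 0 means the model explains nothing.
#'
#' @param ds the [ragged_dataset] the decomposition was fitted to.
#' @param dec a fitted [pf2] object.
#' @return a number no greater than 1.
#' @export
r2x <- function(ds, dec) {
  stopifnot(inherits(ds, "ragged_dataset"), inherits(dec, "pf2"))
  xs <- lapply(ds$matrices, as_dense)
  denom <- sum(vapply(xs, function(m) sum(m^2), numeric(1)))
  if (denom == 0) {
    stop("R2X undefined for all-zero data (validation error)", call. = FALSE)
  }
  xh <- reconstruct(dec)
  err <- sum(vapply(seq_along(xs), function(i) sum((xs[[i]] - xh[[i]])^2),
                    numeric(1)))
  1 - err / denom
}
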