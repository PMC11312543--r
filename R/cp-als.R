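# Canonical polyadic decomposition by alternating least squares on a
# third-order array. Factors follow t[i,j,k] = sum_r A[i,r] B[j,r] C[k,r];
# scale is carried in the factors themselves (no separate weight vector),
# which suits the warm-started inner loop of the Pf2 algorithm.

unfold1 <- function(t) matrix(t, dim(t)[1], dim(t)[2] * dim(t)[3])
unfold2 <- function(t) matrix(aperm(t, c(2, 1, 3)), dim(t)[2], dim(t)[1] * dim(t)[3])
unfold3 <- function(t) matrix(aperm(t, c(3, 1, 2)), dim(t)[3], dim(t)[1] * dim(t)[2])

#' Reconstruct a third-order tensor from CP factors
#'
#' @param factors list with matrices `A` (I x R), `B` (J x R), `C` (K x R).
#' @return numeric array of dim `c(I, J, K)` equal to the sum of rank-one
#'   outer products of the factor columns.
#' @export
cp_reconstruct <- function(factors) {
  a <- factors$A; b <- factors$B; cc <- factors$C
  m <- a %*% t(khatri_rao(cc, b))
  array(m, c(nrow(a), nrow(b), nrow(cc)))
}

#' CP decomposition by alternating least squares
#'
#' Runs `n_iter` full ALS sweeps (one least-squares update of each factor
#' matrix per sweep) minimizing the squared Frobenius error between `t` and
#' the rank-`rank` CP reconstruction. Rank-deficient normal equations fall
#' back to the Moore-Penrose pseudoinverse and are flagged in the result.
#'
#' @param t numeric third-order array.
#' @param rank number of components.
#' @param n_iter number of ALS sweeps (default 20).
#' @param init optional warm start: list with `A`, `B`, `C` of matching
#'   shapes. When omitted, factors are initialized from the leading singular
#'   vectors of the unfoldings (padded with random columns if needed).
#' @param seed seed for the random part of the default initialization.
#' @return list with `A`, `B`, `C`, `fit` (final relative squared error),
#'   and `pinv_used` (logical).
#' @export
cp_als <- function(t, rank, n_iter = 20, init = NULL, seed = 0L) {
  stopifnot(length(dim(t)) == 3, rank >= 1, n_iter >= 0)
  dims <- dim(t)
  t1 <- unfold1(t); t2 <- unfold2(t); t3 <- unfold3(t)
  nrm2 <- sum(t^2)
  if (is.null(init)) {
    init <- with_seed(seed, list(
      A = svd_init(t1, rank),
      B = svd_init(t2, rank),
      C = svd_init(t3, rank)
    ))
  }
  a <- init$A; b <- init$B; cc <- init$C
  stopifnot(nrow(a) == dims[1], nrow(b) == dims[2], nrow(cc) == dims[3],
            ncol(a) == rank, ncol(b) == rank, ncol(cc) == rank)
  pinv_used <- FALSE
  if (nrm2 == 0) {
    return(list(A = a * 0, B = b * 0, C = cc * 0, fit = 0, pinv_used = FALSE))
  }
  for (it in seq_len(n_iter)) {
    s <- solve_gram(t1 %*% khatri_rao(cc, b),
                    crossprod(cc) * crossprod(b))
    a <- s$coef; pinv_used <- pinv_used || s$pinv_used
    s <- solve_gram(t2 %*% khatri_rao(cc, a),
                    crossprod(cc) * crossprod(a))
    b <- s$coef; pinv_used <- pinv_used || s$pinv_used
    s <- solve_gram(t3 %*% khatri_rao(b, a),
                    crossprod(b) * crossprod(a))
    cc <- s$coef; pinv_used <- pinv_used || s$pinv_used
  }
  resid <- t1 - a %*% t(khatri_rao(cc, b))
  list(A = a, B = b, C = cc, fit = sum(resid^2) / nrm2, pinv_used = pinv_used)
}

# Leading-singular-vector initialization of one CP factor from an unfolding,
# padded with small random columns when the unfolding has fewer than `rank`
# usable directions.
svd_init <- function(m, rank) {
  k <- min(rank, dim(m))
  s <- svd(m, nu = k, nv = 0)
  u <- s$u
  if (k < rank) {
    u <- cbind(u, matrix(stats::rnorm(nrow(m) * (rank - k), sd = 0.1),
                         nrow(m), rank - k))
  }
  u
}
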