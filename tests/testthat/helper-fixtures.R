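# Shared fixture builders; everything is generated in code at test time.

rand_orthonormal <- function(n, k) parafac2sc:::random_orthonormal(n, k)

# small ragged dataset of i.i.d. noise
toy_noise_ds <- function(I = 3, js = c(5, 7, 2), K = 10, seed = 1) {
  set.seed(seed)
  mats <- lapply(js, function(j) matrix(rnorm(j * K), j, K))
  ragged_dataset(mats, paste0("s", seq_len(I)), paste0("g", seq_len(K)))
}

# pf2 object with prescribed pieces (bypassing the fit) for contract tests
manual_pf2 <- function(A, B, C, projections, weights = rep(1, ncol(A)),
                       standardized = FALSE) {
  parafac2sc:::new_pf2(A = A, B = B, C = C, projections = projections,
                       weights = weights, rank = ncol(A),
                       condition_ids = paste0("s", seq_len(nrow(A))),
                       gene_ids = paste0("g", seq_len(nrow(C))),
                       r2x = NA_real_, n_iterations = 0L, converged = TRUE,
                       standardized = standardized)
}

# column permutation of a pf2 object's components
permute_components <- function(dec, perm) {
  dec$A <- dec$A[, perm, drop = FALSE]
  dec$B <- dec$B[, perm, drop = FALSE]
  dec$C <- dec$C[, perm, drop = FALSE]
  dec$weights <- dec$weights[perm]
  dec
}
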