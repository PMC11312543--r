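test_that("FMS is exact on self-comparison and invariant to permutation and standardization", {
  sim <- pf2_sim(5, c(10, 16), 12, 3, noise_sd = 0.2, seed = 30)
  fit <- pf2(sim$dataset, 3, seed = 1)
  expect_equal(fms(fit, fit), 1, tolerance = 1e-12)
  perm <- permute_components(fit, c(3, 1, 2))
  expect_equal(fms(fit, perm), 1, tolerance = 1e-12)
  raw <- pf2(sim$dataset, 3, seed = 1, standardize = FALSE)
  expect_equal(fms(raw, fit), 1, tolerance = 1e-10)
  expect_equal(fms(fit, raw), fms(raw, fit), tolerance = 1e-12)
  bad <- pf2(sim$dataset, 2, seed = 1)
  expect_error(fms(fit, bad), "rank")
})

test_that("mutually random factors score near zero", {
  # null scale of the score itself, no fitting involved
  set.seed(31)
  vals <- replicate(100, {
    mk <- function() {
      manual_pf2(A = matrix(rnorm(20 * 4), 20, 4),
                 B = rand_orthonormal(4, 4),
                 C = matrix(rnorm(200 * 4), 200, 4),
                 projections = list(rand_orthonormal(6, 4)))
    }
    fms(mk(), mk())
  })
  expect_lt(max(abs(vals)), 0.2)
})

test_that("subsampling keeps condition structure, order, and determinism", {
  ds <- toy_noise_ds(I = 2, js = c(10, 7), K = 6, seed = 32)
  ds$cell_labels <- list(s1 = paste0("c", 1:10), s2 = paste0("d", 1:7))
  sub <- subsample_cells(ds, 0.5, seed = 4)
  expect_equal(unname(n_cells(sub)), c(5, 4))   # ceiling arithmetic
  # drawn cells keep original relative order: labels strictly increasing
  expect_true(!is.unsorted(match(sub$cell_labels[[1]], ds$cell_labels[[1]])))
  expect_identical(subsample_cells(ds, 0.5, seed = 4), sub)
  full <- subsample_cells(ds, 1, seed = 9)
  expect_identical(full$matrices, ds$matrices)
  expect_error(subsample_cells(ds, 0), "validation error")
  expect_error(subsample_cells(ds, 1.2), "validation error")
})

test_that("bootstrapping preserves shape and draws ~63% unique cells", {
  ds <- toy_noise_ds(I = 2, js = c(9, 5), K = 4, seed = 33)
  bs <- bootstrap_cells(ds, seed = 2)
  expect_equal(n_cells(bs), n_cells(ds))
  expect_identical(bootstrap_cells(ds, seed = 2), bs)
  # unique-cell fraction over many seeds approaches 1 - exp(-1)
  big <- ragged_dataset(list(matrix(rnorm(400 * 2), 400, 2)))
  fr <- vapply(1:50, function(s) {
    b <- bootstrap_cells(big, seed = s)
    nrow(unique(b$matrices[[1]])) / 400
  }, numeric(1))
  expect_equal(mean(fr), 1 - exp(-1), tolerance = 0.01)
})

test_that("stability curves have one row per (level, seed) and hit 1 at fraction 1", {
  sim <- pf2_sim(4, c(10, 14), 10, 2, noise_sd = 0.1, seed = 34)
  rep <- stability_curve(sim$dataset, rank = 2, protocol = "subsample",
                         levels = c(1, 0.8), seeds = c(0, 1), seed = 1)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$fms[rep$level == 1], c(1, 1), tolerance = 1e-9)
  boot <- stability_curve(sim$dataset, rank = 2, protocol = "bootstrap",
                          levels = 2, seeds = 0, seed = 1)
  expect_equal(nrow(boot), 1)
  expect_true(boot$fms <= 1)
})

test_that("cell-type ablation edits exactly the requested condition", {
  ds <- toy_noise_ds(I = 3, js = c(8, 50, 6), K = 5, seed = 35)
  labs <- list(rep(c("T", "B"), c(4, 4)),
               rep(c("T", "B"), c(10, 40)),
               rep("T", 6))
  ds <- ragged_dataset(ds$matrices, ds$condition_ids, ds$gene_ids, labs)
  # keep_fraction 1: unchanged
  expect_identical(ablate_cell_type(ds, "B", "s2", 1)$matrices, ds$matrices)
  # full removal only in the named condition
  out <- ablate_cell_type(ds, "B", "s2", 0)
  expect_equal(sum(out$cell_labels[[2]] == "B"), 0)
  expect_equal(sum(out$cell_labels[[1]] == "B"), 4)
  expect_equal(unname(n_cells(out)), c(8, 10, 6))
  # partial thinning: 0.25 of 40 labeled cells leaves 10
  out2 <- ablate_cell_type(ds, "B", "s2", 0.25, seed = 1)
  expect_equal(sum(out2$cell_labels[[2]] == "B"), 10)
  expect_error(ablate_cell_type(ds, "NK", "s2", 0), "unknown cell label")
  expect_error(ablate_cell_type(ds, "B", "nope", 0), "unknown condition")
  expect_error(ablate_cell_type(ds, "T", "s3", 0), "empty condition")
})

test_that("condition-weight comparison is zero on self and permutation-invariant", {
  sim <- pf2_sim(5, c(12, 18), 12, 3, noise_sd = 0.1, seed = 36)
  fit <- pf2(sim$dataset, 3, seed = 1)
  d0 <- compare_condition_weights(fit, fit, 2)
  expect_equal(as.numeric(d0), rep(0, 5))
  perm <- permute_components(fit, c(2, 3, 1))
  dp <- compare_condition_weights(fit, perm, 2)
  expect_equal(as.numeric(dp), rep(0, 5), tolerance = 1e-12)
  expect_error(compare_condition_weights(fit, pf2(sim$dataset, 2, seed = 1), 1),
               "rank mismatch")
})
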