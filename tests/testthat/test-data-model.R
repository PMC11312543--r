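test_that("ragged_dataset partitions and validates its structure", {
  ds <- toy_noise_ds(I = 3, js = c(5, 7, 2), K = 10)
  expect_s3_class(ds, "ragged_dataset")
  expect_equal(n_conditions(ds), 3)
  expect_equal(unname(n_cells(ds)), c(5, 7, 2))
  expect_equal(n_genes(ds), 10)

  m <- matrix(1, 2, 3)
  expect_error(ragged_dataset(list(m, matrix(1, 2, 4))), "same number of gene")
  expect_error(ragged_dataset(list(a = m, b = m), condition_ids = c("x", "x")),
               "unique")
  expect_error(ragged_dataset(list(m), cell_labels = c("a")), "one entry per cell")
})

test_that("MTX bundle write/read round trip preserves the dataset", {
  ds <- toy_noise_ds(I = 3, js = c(4, 6, 3), K = 8, seed = 7)
  ds$cell_labels <- split(sample(c("T", "B"), 13, replace = TRUE),
                          rep(1:3, c(4, 6, 3)))
  names(ds$cell_labels) <- ds$condition_ids
  ds$condition_meta <- data.frame(condition_id = ds$condition_ids,
                                  status = c("ctrl", "drug", "drug"))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, condition_key = "sample")
  back <- read_dataset(dir, condition_key = "sample")
  expect_equal(back$condition_ids, ds$condition_ids)
  expect_equal(back$gene_ids, ds$gene_ids)
  expect_equal(back$cell_labels, ds$cell_labels)
  expect_equal(back$condition_meta$status, ds$condition_meta$status)
  for (i in 1:3) {
    expect_equal(as.matrix(back$matrices[[i]]), ds$matrices[[i]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(read_dataset(dir, condition_key = "nope"), "configuration error")
})

test_that("conditions are ordered by first appearance in the cell file", {
  dir <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(rpois(5 * 4, 3), 5, 4), sparse = TRUE)
  Matrix::writeMM(methods::as(m, "TsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(paste0("g", 1:4), file.path(dir, "genes.tsv"))
  write.table(data.frame(condition = c("z", "a", "z", "a", "z")),
              file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ds <- read_dataset(dir)
  expect_equal(ds$condition_ids, c("z", "a"))
  expect_equal(unname(n_cells(ds)), c(3, 2))
})

test_that("decomposition bundle round trip is lossless", {
  sim <- pf2_sim(4, c(8, 12), 15, 3, noise_sd = 0.1, seed = 3)
  fit <- pf2(sim$dataset, 3, seed = 3)
  dir <- file.path(withr::local_tempdir(), "dec")
  write_decomposition(fit, dir)
  back <- read_decomposition(dir)
  expect_equal(fms(back, fit), 1, tolerance = 1e-12)
  expect_identical(back$condition_ids, fit$condition_ids)
  expect_identical(back$gene_ids, fit$gene_ids)
  expect_identical(back$rank, fit$rank)
  expect_identical(back$converged, fit$converged)
  expect_equal(back$A, fit$A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$C, fit$C, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$projections, fit$projections, tolerance = 1e-12)
  expect_equal(back$r2x, fit$r2x, tolerance = 1e-12)
  expect_error(write_decomposition(fit, "/nonexistent/dir/bundle"), "I/O error")
})

test_that("concatenated projections stack in condition order and obey the Bessel bound", {
  set.seed(5)
  p1 <- rand_orthonormal(3, 2)
  p2 <- rand_orthonormal(4, 2)
  dec <- manual_pf2(A = matrix(1, 2, 2), B = diag(2),
                    C = rand_orthonormal(6, 2), projections = list(p1, p2))
  cp <- concatenated_projections(dec)
  expect_equal(dim(cp), c(7, 2))
  expect_equal(cp[1:3, ], p1)
  # single condition returns P_1 unchanged
  dec1 <- manual_pf2(matrix(1, 1, 2), diag(2), rand_orthonormal(6, 2),
                     list(p1))
  expect_equal(concatenated_projections(dec1), p1)
  # rows of an orthonormal-column matrix have norm at most 1
  for (rep in 1:20) {
    p <- rand_orthonormal(sample(3:12, 1), 2)
    expect_true(all(rowSums(p^2) <= 1 + 1e-12))
  }
})
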