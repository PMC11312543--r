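test_that("factor initialization has the documented structure", {
  ds <- toy_noise_ds(I = 3, js = c(6, 8, 5), K = 5, seed = 2)
  fac <- init_factors(ds, 3)
  expect_equal(fac$A, matrix(1, 3, 3))
  expect_equal(fac$B, diag(3))
  expect_equal(crossprod(fac$C), diag(3), tolerance = 1e-10)
  # rank = K gives a complete orthonormal basis
  fac_k <- init_factors(ds, 5)
  expect_equal(crossprod(fac_k$C), diag(5), tolerance = 1e-10)
  expect_error(init_factors(ds, 6), "rank exceeds")
})

test_that("initialization spans the row space of exactly low-rank data", {
  set.seed(9)
  basis <- rand_orthonormal(12, 2)
  mats <- lapply(c(5, 7), function(j) matrix(rnorm(j * 2), j, 2) %*% t(basis))
  ds <- ragged_dataset(mats)
  fac <- init_factors(ds, 2)
  # principal angles between span(C) and the true row space are ~0
  expect_equal(svd(crossprod(fac$C, basis))$d, c(1, 1), tolerance = 1e-8)
})

test_that("Procrustes update solves the orthogonal alignment in closed form", {
  set.seed(12)
  R <- 3; K <- 8
  B <- diag(R) + 0.1 * matrix(rnorm(R * R), R, R)
  C <- rand_orthonormal(K, R)
  A <- matrix(runif(2 * R, 0.5, 1.5), 2, R)
  m1 <- B %*% (t(C) * A[1, ])
  # X_i = M_i with J_i = R: the Procrustes factor is the identity
  ds <- ragged_dataset(list(m1, m1))
  p <- update_projections(ds, A[c(1, 1), ], B, C)
  expect_equal(p[[1]], diag(R), tolerance = 1e-10)
  # X_i = Q M_i with orthonormal Q: recovers Q
  q <- rand_orthonormal(7, R)
  ds2 <- ragged_dataset(list(q %*% m1))
  p2 <- update_projections(ds2, A[1, , drop = FALSE], B, C)
  expect_equal(p2[[1]], q, tolerance = 1e-8)
  expect_equal(crossprod(p2[[1]]), diag(R), tolerance = 1e-8)
})

test_that("Procrustes solution beats 1,000 random orthonormal candidates", {
  set.seed(13)
  R <- 2; J <- 6; K <- 4
  B <- matrix(rnorm(R * R), R, R)
  C <- rand_orthonormal(K, R)
  A <- matrix(runif(R, 0.5, 1.5), 1, R)
  X <- matrix(rnorm(J * K), J, K)
  ds <- ragged_dataset(list(X))
  m <- B %*% (t(C) * A[1, ])
  p <- update_projections(ds, A, B, C)[[1]]
  err_opt <- sum((X - p %*% m)^2)
  errs <- replicate(1000, {
    q <- rand_orthonormal(J, R)
    sum((X - q %*% m)^2)
  })
  expect_true(all(err_opt <= errs + 1e-10))
})

test_that("projection of the data onto the frame matches direct products", {
  set.seed(14)
  X <- matrix(rnorm(5 * 3), 5, 3)
  p <- rand_orthonormal(5, 2)
  ds <- ragged_dataset(list(X))
  tt <- project_data(ds, list(p))
  expect_equal(drop(tt[1, , ]), crossprod(p, X), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identity projection (J = R) returns the slice unchanged
  ds2 <- ragged_dataset(list(X[1:3, ]))
  t2 <- project_data(ds2, list(diag(3)))
  expect_equal(drop(t2[1, , ]), X[1:3, ], tolerance = 1e-12, ignore_attr = TRUE)
  # X = P M implies slice = M
  m <- matrix(rnorm(2 * 3), 2, 3)
  ds3 <- ragged_dataset(list(p %*% m))
  t3 <- project_data(ds3, list(p))
  expect_equal(drop(t3[1, , ]), m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(project_data(ds, list(rand_orthonormal(4, 2))), "shapes")
})

test_that("noiseless planted structure is fit essentially exactly", {
  sim <- pf2_sim(6, c(15, 25), 20, 3, noise_sd = 0, seed = 5)
  fit <- pf2(sim$dataset, 3, seed = 5, tol = 1e-15, max_iter = 500)
  expect_gte(fit$r2x, 0.999)
  xh <- reconstruct(fit)
  for (i in seq_along(xh)) {
    expect_lt(max(abs(xh[[i]] - sim$dataset$matrices[[i]])), 1e-6)
  }
})

test_that("a single condition at rank 1 reduces to the truncated SVD", {
  set.seed(15)
  X <- matrix(rnorm(30 * 12), 30, 12)
  fit <- pf2(ragged_dataset(list(X)), 1, seed = 1, tol = 1e-10,
             max_iter = 500)
  d <- svd(X)$d
  expect_equal(fit$r2x, d[1]^2 / sum(d^2), tolerance = 1e-6)
})

test_that("unaccelerated fitting increases R2X monotonically", {
  for (s in 1:5) {
    sim <- pf2_sim(4, c(8, 14), 10, 2, noise_sd = 0.3, seed = 40 + s)
    fit <- pf2(sim$dataset, 2, seed = s, accelerate = FALSE, max_iter = 60)
    expect_true(all(diff(fit$r2x_trace) >= -1e-10))
  }
})

test_that("fits are bit-reproducible with the exact SVD", {
  sim <- pf2_sim(4, c(8, 12), 10, 2, noise_sd = 0.2, seed = 6)
  f1 <- pf2(sim$dataset, 2, seed = 3)
  f2 <- pf2(sim$dataset, 2, seed = 3)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$C, f2$C)
  expect_identical(f1$projections, f2$projections)
})

test_that("rank preconditions and degenerate data are rejected", {
  ds <- toy_noise_ds(I = 2, js = c(4, 9), K = 6, seed = 3)
  expect_error(pf2(ds, 5), "rank exceeds")
  zeros <- ragged_dataset(list(matrix(0, 4, 3)))
  expect_error(pf2(zeros, 1), "all-zero")
})

test_that("R2X follows its closed-form contract", {
  # exact reconstruction gives 1
  set.seed(16)
  p <- rand_orthonormal(6, 2)
  B <- diag(2); A <- matrix(c(2, 1), 1, 2); C <- rand_orthonormal(5, 2)
  X <- p %*% B %*% (t(C) * A[1, ])
  dec <- manual_pf2(A, B, C, list(p))
  ds <- ragged_dataset(list(X))
  expect_equal(r2x(ds, dec), 1)
  # zero reconstruction gives 0
  dec0 <- manual_pf2(A * 0, B, C, list(p))
  expect_equal(r2x(ds, dec0), 0)
  # hand-computed toy: X = [[2,0],[0,0]], Xhat = [[1,0],[0,0]] -> 0.75
  ds_toy <- ragged_dataset(list(matrix(c(2, 0, 0, 0), 2, 2)))
  dec_toy <- manual_pf2(A = matrix(c(1, 0), 1, 2), B = diag(2),
                        C = diag(2), projections = list(diag(2)))
  expect_equal(r2x(ds_toy, dec_toy), 0.75)
  expect_error(r2x(ragged_dataset(list(matrix(0, 2, 2))), dec_toy),
               "all-zero")
})

test_that("standardization and zero weights behave under reconstruction", {
  sim <- pf2_sim(4, c(8, 12), 10, 2, noise_sd = 0.1, seed = 17)
  fit <- pf2(sim$dataset, 2, seed = 1, standardize = FALSE)
  std <- pf2_standardize(fit)
  xh1 <- reconstruct(fit); xh2 <- reconstruct(std)
  for (i in seq_along(xh1)) expect_equal(xh1[[i]], xh2[[i]], tolerance = 1e-10)
  zero <- fit; zero$weights <- rep(0, 2)
  expect_true(all(vapply(reconstruct(zero), function(m) all(m == 0),
                         logical(1))))
})

test_that("prediction projects held-out cells onto the fitted frame", {
  sim <- pf2_sim(5, c(20, 30), 15, 2, noise_sd = 0, seed = 19)
  fit <- pf2(sim$dataset, 2, seed = 1)
  x_new <- sim$dataset$matrices[[2]]
  pr <- predict(fit, x_new)
  expect_equal(crossprod(pr$projection), diag(2), tolerance = 1e-8)
  # reconstruction from the predicted pieces explains the held-in condition
  xh <- pr$projection %*% fit$B %*% (t(fit$C) * (fit$weights * pr$condition_weights))
  expect_gt(1 - sum((x_new - xh)^2) / sum(x_new^2), 0.999)
})
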