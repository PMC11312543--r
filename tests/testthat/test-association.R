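make_factor_problem <- function(I = 40, R = 5, margin = 1, seed = 3) {
  set.seed(seed)
  A <- matrix(rnorm(I * R), I, R)
  labels <- as.integer(A[, 1] > 0)
  A[, 1] <- A[, 1] + ifelse(labels == 1, margin, -margin)
  list(A = A, labels = labels,
       batches = rep(paste0("b", 1:4), length.out = I))
}

test_that("the rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(50)
  for (rep in 1:5) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y
    got <- parafac2sc:::roc_auc(y, s)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("linearly separable factors give perfect pooled AUC", {
  prb <- make_factor_problem()
  res <- suppressWarnings(
    classify_conditions(prb$A, prb$labels, prb$batches))
  expect_equal(res$pooled_auc, 1)
  expect_gte(res$pooled_accuracy, 0.95)
  # L1 keeps the signal component and drops the noise ones
  expect_gt(abs(res$coefficients[1]), 0)
  expect_equal(nrow(res$fold_metrics), 4)
})

test_that("permuted labels give chance-level AUC on average", {
  prb <- make_factor_problem()
  aucs <- vapply(1:20, function(k) {
    set.seed(1000 + k)
    suppressWarnings(
      classify_conditions(prb$A, sample(prb$labels), prb$batches))$pooled_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("pure-noise components do not break a separable signal", {
  prb <- make_factor_problem(R = 2)
  set.seed(51)
  A_wide <- cbind(prb$A, matrix(rnorm(40 * 8), 40, 8))
  res <- suppressWarnings(
    classify_conditions(A_wide, prb$labels, prb$batches))
  expect_gte(res$pooled_auc, 0.95)
})

test_that("identical batches yield identical fold accuracies", {
  prb <- make_factor_problem(I = 20, seed = 7)
  A2 <- rbind(prb$A, prb$A)
  labels2 <- c(prb$labels, prb$labels)
  batches2 <- rep(c("x", "y"), each = 20)
  res <- suppressWarnings(classify_conditions(A2, labels2, batches2))
  expect_equal(res$fold_metrics$accuracy[1], res$fold_metrics$accuracy[2])
})

test_that("single-class training folds are skipped with a warning", {
  prb <- make_factor_problem(I = 30, seed = 9)
  batches <- c(rep("solo", 5), rep(c("b1", "b2"), length.out = 25))
  labels <- prb$labels
  labels[1:5] <- 1                       # batch 'solo' has one class
  w <- capture_warnings(classify_conditions(prb$A, labels, batches))
  expect_true(any(grepl("only one class", w)))
})

test_that("the pairwise component scan is symmetric with single-component diagonal", {
  prb <- make_factor_problem(R = 3)
  acc <- pairwise_component_scan(prb$A, prb$labels, prb$batches)
  expect_equal(acc, t(acc))
  expect_equal(dim(acc), c(3, 3))
  # the signal component dominates the matrix maximum
  expect_equal(which.max(apply(acc, 1, max)), 1, ignore_attr = TRUE)
  expect_true(all(acc[1, ] >= 0.9))
})

test_that("the rank-selection curve plateaus once the signal is spanned", {
  # conditions differ along 2 planted components; label = sign of comp 1
  sim <- pf2_sim(24, c(10, 15), 12, 2, noise_sd = 0.05,
                 condition_law = "block", seed = 52)
  a_true <- sim$truth$A
  labels <- as.integer(a_true[, 1] > median(a_true[, 1]))
  batches <- rep(paste0("b", 1:3), each = 8)
  curve <- suppressWarnings(
    rank_selection_curve(sim$dataset, labels, batches, ranks = c(1, 2, 3),
                         seed = 1))
  expect_equal(nrow(curve), 3)
  expect_gte(max(curve$pooled_auc[curve$rank >= 2]),
             max(curve$pooled_auc) - 0.02)
  one <- suppressWarnings(
    rank_selection_curve(sim$dataset, labels, batches, ranks = 2, seed = 1))
  expect_equal(nrow(one), 1)
})
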