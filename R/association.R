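# Condition-factor association workflow: leave-one-batch-out L1 logistic
# regression on the rows of A, pairwise component scans, and the
# AUC-vs-rank curve used to choose the number of components.

# rank-statistic ROC-AUC (equivalent to the Wilcoxon/Mann-Whitney estimate)
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# leave-one-batch-out folds: each batch serves once as the TRAINING set and
# all remaining batches, pooled, as the test set
lobo_folds <- function(batches) {
  ub <- unique(batches)
  if (length(ub) < 2) {
    stop("need at least two batches for leave-one-batch-out CV", call. = FALSE)
  }
  lapply(ub, function(b) list(batch = b,
                              train = which(batches == b),
                              test = which(batches != b)))
}

#' Associate condition factors with a binary condition label
#'
#' Trains L1-penalized logistic regression on the rows of the condition
#' factor matrix `A` under the leave-one-batch-out scheme: the model is
#' trained on each processing batch in turn and predicts the pooled
#' remaining batches. The regularization strength is chosen by grid search
#' under the same cross-validation, maximizing pooled held-out ROC-AUC.
#' Training folds lacking either class are skipped with a warning.
#'
#' @param A condition factor matrix (conditions x components), e.g.
#'   `coef(fit, "conditions")`.
#' @param labels binary (0/1 or logical/two-level factor) outcome per
#'   condition.
#' @param batches processing-batch assignment per condition (>= 2 batches).
#' @param penalty_grid regularization strengths (glmnet `lambda`) searched;
#'   default 10 log-spaced values over `[1e-3, 1e2]`.
#' @param scale_factors z-score each component column before fitting
#'   (default TRUE; penalized coefficients are scale-sensitive).
#' @param tol optimizer convergence threshold (default 1e-4).
#' @param max_iter optimizer iteration cap (default 1e4).
#' @return list of class `"pf2_classification"`: `pooled_auc`,
#'   `pooled_accuracy`, `fold_metrics` (data.frame with one row per usable
#'   fold), `best_lambda`, `coefficients` (per-component, fitted on all
#'   conditions at the chosen strength), `grid` (lambda vs pooled AUC).
#' @export
classify_conditions <- function(A, labels, batches,
                                penalty_grid = 10^seq(-3, 2, length.out = 10),
                                scale_factors = TRUE, tol = 1e-4,
                                max_iter = 1e4) {
  A <- as.matrix(A)
  y <- normalize_labels(labels)
  batches <- as.character(batches)
  stopifnot(nrow(A) == length(y), length(batches) == length(y))
  if (is.null(colnames(A))) colnames(A) <- paste0("comp", seq_len(ncol(A)))
  single_col <- ncol(A) == 1
  if (single_col) A <- cbind(A, `.pad` = 0)  # the optimizer needs >= 2 columns
  if (scale_factors) A <- scale_cols(A)
  folds <- lobo_folds(batches)
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)
  nl <- length(penalty_grid)

  # one path fit per fold; preds[test, lambda] pooled over folds
  preds <- matrix(NA_real_, length(y), nl)
  used <- logical(length(folds))
  fold_fits <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    if (length(unique(y[f$train])) < 2) {
      warning("skipping training batch '", f$batch,
              "': only one class present", call. = FALSE)
      next
    }
    fit <- tryCatch(
      glmnet::glmnet(A[f$train, , drop = FALSE], y[f$train],
                     family = "binomial", alpha = 1,
                     lambda = penalty_grid, thresh = tol,
                     maxit = max_iter),
      error = function(e) {
        warning("skipping training batch '", f$batch, "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    p <- stats::predict(fit, A[f$test, , drop = FALSE],
                        s = penalty_grid, type = "response")
    preds[f$test, ] <- as.matrix(p)
    used[fi] <- TRUE
    fold_fits[[fi]] <- fit
  }
  if (!any(used)) {
    stop("all cross-validation folds were skipped (validation error)",
         call. = FALSE)
  }
  keep <- !is.na(preds[, 1])
  grid_auc <- apply(preds[keep, , drop = FALSE], 2,
                    function(p) roc_auc(y[keep], p))
  grid_acc <- apply(preds[keep, , drop = FALSE], 2,
                    function(p) mean((p > 0.5) == (y[keep] == 1)))
  # best held-out AUC; ties broken by held-out accuracy, then sparsity
  best <- which(grid_auc == max(grid_auc, na.rm = TRUE))
  best <- best[which.max(grid_acc[best])]
  best_lambda <- penalty_grid[best]
  pooled_auc <- grid_auc[best]
  pooled_acc <- grid_acc[best]
  fold_metrics <- do.call(rbind, lapply(which(used), function(fi) {
    f <- folds[[fi]]
    p <- drop(as.matrix(stats::predict(fold_fits[[fi]],
                                       A[f$test, , drop = FALSE],
                                       s = best_lambda, type = "response")))
    data.frame(train_batch = f$batch,
               n_test = length(f$test),
               accuracy = mean((p > 0.5) == (y[f$test] == 1)),
               auc = roc_auc(y[f$test], p))
  }))
  full <- glmnet::glmnet(A, y, family = "binomial", alpha = 1,
                         lambda = penalty_grid, thresh = tol, maxit = max_iter)
  coefs <- drop(as.matrix(stats::coef(full, s = best_lambda)))[-1]
  names(coefs) <- colnames(A)
  if (single_col) coefs <- coefs[1]
  structure(list(pooled_auc = pooled_auc, pooled_accuracy = pooled_acc,
                 fold_metrics = fold_metrics, best_lambda = best_lambda,
                 coefficients = coefs,
                 grid = data.frame(lambda = penalty_grid, auc = grid_auc)),
            class = "pf2_classification")
}

#' @export
print.pf2_classification <- function(x, ...) {
  cat(sprintf("leave-one-batch-out classification: pooled AUC %.3f, accuracy %.3f\n",
              x$pooled_auc, x$pooled_accuracy))
  cat(sprintf("  chosen L1 strength: %g; nonzero coefficients: %d/%d\n",
              x$best_lambda, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' Classification accuracy over all component pairs
#'
#' For every unordered pair of components, fits an unpenalized logistic
#' model on those two condition-factor columns under the same
#' leave-one-batch-out scheme and records pooled held-out accuracy; the
#' diagonal holds single-component accuracies.
#'
#' @inheritParams classify_conditions
#' @return symmetric R x R accuracy matrix.
#' @export
pairwise_component_scan <- function(A, labels, batches,
                                    scale_factors = TRUE) {
  A <- as.matrix(A)
  y <- normalize_labels(labels)
  batches <- as.character(batches)
  if (scale_factors) A <- scale_cols(A)
  folds <- lobo_folds(batches)
  r <- ncol(A)

  cv_acc <- function(cols) {
    preds <- rep(NA_real_, length(y))
    for (f in folds) {
      if (length(unique(y[f$train])) < 2) next
      df <- data.frame(y = y[f$train], A[f$train, cols, drop = FALSE])
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      nd <- data.frame(A[f$test, cols, drop = FALSE])
      names(nd) <- names(df)[-1]
      preds[f$test] <- suppressWarnings(
        stats::predict(fit, newdata = nd, type = "response"))
    }
    keep <- !is.na(preds)
    if (!any(keep)) {
      stop("all cross-validation folds were skipped (validation error)",
           call. = FALSE)
    }
    mean((preds[keep] > 0.5) == (y[keep] == 1))
  }

  acc <- matrix(NA_real_, r, r)
  for (i in seq_len(r)) {
    acc[i, i] <- cv_acc(i)
    for (j in seq_len(r)) {
      if (j > i) acc[i, j] <- acc[j, i] <- cv_acc(c(i, j))
    }
  }
  dimnames(acc) <- list(paste0("comp", seq_len(r)), paste0("comp", seq_len(r)))
  acc
}

#' Classification performance as a function of rank
#'
#' Fits the Pf2 decomposition at each requested rank, runs
#' [classify_conditions()] on the resulting condition factors, and returns
#' the pooled held-out AUC per rank — the curve used to choose the number
#' of components.
#'
#' @param ds a preprocessed [ragged_dataset].
#' @param labels,batches per-condition outcome and batch (as in
#'   [classify_conditions()]).
#' @param ranks integer vector of ranks to evaluate.
#' @param seed seed passed to every fit.
#' @param ... further arguments to [pf2()].
#' @return data.frame with columns `rank` and `pooled_auc`.
#' @export
rank_selection_curve <- function(ds, labels, batches, ranks, seed = 0L, ...) {
  stopifnot(inherits(ds, "ragged_dataset"), length(ranks) >= 1)
  rows <- lapply(ranks, function(rk) {
    fit <- pf2(ds, rk, seed = seed, ...)
    res <- classify_conditions(fit$A, labels, batches)
    data.frame(rank = rk, pooled_auc = res$pooled_auc)
  })
  do.call(rbind, rows)
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) != 2) stop("labels must be binary", call. = FALSE)
    return(as.integer(labels == lv[2]))
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% 0:1)) stop("labels must be binary", call. = FALSE)
  as.integer(labels)
}

scale_cols <- function(m) {
  s <- apply(m, 2, stats::sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2, colMeans(m), `-`), 2, s, `/`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
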