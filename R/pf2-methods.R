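#' @export
print.pf2 <- function(x, ...) {
  js <- vapply(x$projections, nrow, integer(1))
  cat(sprintf("Pf2 decomposition: rank %d, %d conditions, %d cells, %d genes\n",
              x$rank, length(x$condition_ids), sum(js), length(x$gene_ids)))
  cat(sprintf("  R2X = %.5f after %d iterations (%s)\n", x$r2x,
              x$n_iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  cat(sprintf("  standardized: %s\n", x$standardized))
  if (isTRUE(x$standardized)) {
    cat("  component weights:",
        paste(formatC(utils::head(x$weights, 8), digits = 4, format = "g"),
              collapse = ", "),
        if (x$rank > 8) ", ..." else "", "\n", sep = " ")
  }
  invisible(x)
}

#' @export
summary.pf2 <- function(object, n_top_genes = 5, ...) {
  x <- if (isTRUE(object$standardized)) object else pf2_standardize(object)
  g <- apply(x$A, 2, gini)
  top <- vapply(seq_len(x$rank), function(r) {
    o <- order(abs(x$C[, r]), decreasing = TRUE)[seq_len(min(n_top_genes, nrow(x$C)))]
    paste(x$gene_ids[o], collapse = ", ")
  }, character(1))
  out <- list(rank = x$rank, r2x = x$r2x, n_iterations = x$n_iterations,
              converged = x$converged,
              components = data.frame(component = seq_len(x$rank),
                                      weight = x$weights,
                                      gini_conditions = g,
                                      top_genes = top))
  class(out) <- "summary.pf2"
  out
}

#' @export
print.summary.pf2 <- function(x, ...) {
  cat(sprintf("Pf2 decomposition, rank %d\n", x$rank))
  cat(sprintf("R2X: %.5f (%d iterations, %s)\n", x$r2x, x$n_iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  cat("Components (ordered by Gini coefficient of condition association):\n")
  df <- x$components
  df$weight <- formatC(df$weight, digits = 4, format = "g")
  df$gini_conditions <- formatC(df$gini_conditions, digits = 3, format = "f")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract factor matrices from a Pf2 fit
#'
#' @param object a fitted [pf2] object.
#' @param which which factor matrix to return: condition factors A,
#'   eigen-state factors B, gene factors C, or the component weights.
#' @param ... unused.
#' @return the requested matrix with informative dimnames (or the weight
#'   vector).
#' @export
coef.pf2 <- function(object,
                     which = c("conditions", "eigenstates", "genes", "weights"),
                     ...) {
  which <- match.arg(which)
  comp <- paste0("comp", seq_len(object$rank))
  switch(which,
    conditions = {
      m <- object$A; dimnames(m) <- list(object$condition_ids, comp); m
    },
    eigenstates = {
      m <- object$B; dimnames(m) <- list(paste0("state", seq_len(nrow(m))), comp); m
    },
    genes = {
      m <- object$C; dimnames(m) <- list(object$gene_ids, comp); m
    },
    weights = stats::setNames(object$weights, comp)
  )
}

#' @export
fitted.pf2 <- function(object, ...) {
  reconstruct(object)
}

#' Residuals of a Pf2 fit
#'
#' @param object a fitted [pf2] object.
#' @param ds the [ragged_dataset] the model was fitted to.
#' @param ... unused.
#' @return list of `J_i x K` residual matrices `X_i - X_hat_i`.
#' @export
residuals.pf2 <- function(object, ds, ...) {
  stopifnot(inherits(ds, "ragged_dataset"))
  xh <- reconstruct(object)
  stopifnot(length(xh) == n_conditions(ds))
  lapply(seq_along(xh), function(i) as_dense(ds$matrices[[i]]) - xh[[i]])
}

#' Project new cells onto a fitted eigen-state frame
#'
#' Given a new cell-by-gene matrix over the same genes (e.g. an unseen
#' condition), alternates a least-squares estimate of the new condition's
#' component weights with an orthogonal-Procrustes projection update, then
#' returns the projection, the weights and the per-cell component scores
#' `P_new %*% B`.
#'
#' @param object a fitted [pf2] object.
#' @param newdata numeric matrix, cells x genes, genes matching the fit.
#' @param n_iter number of alternations (default 20).
#' @param ... unused.
#' @return list with `projection` (cells x R, orthonormal columns),
#'   `condition_weights` (length R) and `scores` (cells x R).
#' @export
predict.pf2 <- function(object, newdata, n_iter = 20, ...) {
  x <- as_dense(newdata)
  stopifnot(ncol(x) == length(object$gene_ids), nrow(x) >= object$rank)
  b <- object$B
  cc <- object$C
  w <- object$weights
  # effective gene-side basis per component, weights folded in
  bc_gram <- crossprod(b) * crossprod(cc)        # (b_r'b_s)(c_r'c_s)
  a_new <- rep(1, object$rank)
  p <- NULL
  for (it in seq_len(n_iter)) {
    m <- b %*% (t(cc) * (w * a_new))
    s <- m %*% t(x)
    sv <- svd(s)
    p <- sv$v %*% t(sv$u)
    # least squares for a_new given p: since P has orthonormal columns,
    # N_rs = w_r w_s (b_r'b_s)(c_r'c_s) and rhs_r = w_r b_r' (P'X) c_r
    px <- crossprod(p, x)                        # R x K
    rhs <- w * vapply(seq_len(object$rank), function(r) {
      sum(b[, r] * (px %*% cc[, r]))
    }, numeric(1))
    a_new <- drop(MASS::ginv(outer(w, w) * bc_gram) %*% rhs)
  }
  list(projection = p, condition_weights = a_new, scores = p %*% b)
}

#' Plot a Pf2 decomposition
#'
#' Base-graphics displays of a fitted decomposition: a heatmap of the
#' condition factors, a heatmap of the leading gene factors, or the
#' R2X convergence trace.
#'
#' @param x a fitted [pf2] object.
#' @param type `"conditions"`, `"genes"` or `"trace"`.
#' @param n_genes number of top-loading genes to show for `type = "genes"`.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.pf2 <- function(x, type = c("conditions", "genes", "trace"),
                     n_genes = 20, ...) {
  type <- match.arg(type)
  comp <- paste0("comp", seq_len(x$rank))
  if (type == "trace") {
    if (is.null(x$r2x_trace) || !length(x$r2x_trace)) {
      stop("no R2X trace stored on this object", call. = FALSE)
    }
    graphics::plot(seq_along(x$r2x_trace), x$r2x_trace, type = "b",
                   xlab = "iteration", ylab = "R2X", ...)
    return(invisible(x))
  }
  m <- if (type == "conditions") {
    mm <- x$A; rownames(mm) <- x$condition_ids; mm
  } else {
    sel <- order(apply(abs(x$C), 1, max), decreasing = TRUE)
    sel <- sort(utils::head(sel, n_genes))
    mm <- x$C[sel, , drop = FALSE]; rownames(mm) <- x$gene_ids[sel]; mm
  }
  colnames(m) <- comp
  lim <- max(abs(m))
  pal <- grDevices::hcl.colors(101, "Blue-Red 3")
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "component", ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
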