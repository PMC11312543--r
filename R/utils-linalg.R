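# Internal numerical helpers shared across the fitting code.

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

#' Truncated singular value decomposition
#'
#' Computes the leading `k` singular triplets of a matrix, either exactly
#' (LAPACK through [base::svd()]) or by a seeded randomized range finder with
#' oversampling 10 and two power iterations.
#'
#' @param x numeric matrix.
#' @param k number of singular triplets to return.
#' @param method `"exact"` or `"randomized"`.
#' @param seed integer seed used by the randomized method.
#' @return list with components `u`, `d`, `v` (as from [base::svd()], truncated
#'   to `k` columns).
#' @keywords internal
truncated_svd <- function(x, k, method = c("exact", "randomized"), seed = 0L) {
  method <- match.arg(method)
  x <- as_dense(x)
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= min(dim(x)))
  if (method == "exact") {
    s <- svd(x, nu = k, nv = k)
    return(list(u = s$u, d = s$d[seq_len(k)], v = s$v))
  }
  # randomized range finder: oversampling 10, 2 power iterations
  p <- min(ncol(x), k + 10L)
  omega <- with_seed(seed, matrix(stats::rnorm(ncol(x) * p), ncol(x), p))
  y <- x %*% omega
  for (it in 1:2) {
    y <- qr.Q(qr(y))
    y <- x %*% crossprod(x, y)
  }
  q <- qr.Q(qr(y))
  b <- crossprod(q, x)                       # p x ncol
  s <- svd(b, nu = k, nv = k)
  list(u = q %*% s$u, d = s$d[seq_len(k)], v = s$v)
}

# Column-wise Khatri-Rao product; row (i-1)*nrow(y)+j holds x[i,]*y[j,]
# (second argument's index varies fastest).
khatri_rao <- function(x, y) {
  stopifnot(ncol(x) == ncol(y))
  out <- matrix(0, nrow(x) * nrow(y), ncol(x))
  for (r in seq_len(ncol(x))) out[, r] <- kronecker(x[, r], y[, r])
  out
}

# Solve G t(B) = t(M) for B = M G^+ robustly: plain solve, pseudoinverse on
# rank deficiency. Returns list(coef, pinv_used).
solve_gram <- function(m, gram) {
  out <- tryCatch(
    list(coef = t(solve(gram, t(m))), pinv_used = FALSE),
    error = function(e) NULL
  )
  if (is.null(out) || !all(is.finite(out$coef))) {
    out <- list(coef = m %*% MASS::ginv(gram), pinv_used = TRUE)
  }
  out
}

# Nearest column-orthonormal matrix (polar factor) of x (n x k, n >= k).
polar_orthonormal <- function(x) {
  s <- svd(x)
  s$u %*% t(s$v)
}

# Random matrix with orthonormal columns, n x k.
random_orthonormal <- function(n, k) {
  polar_orthonormal(matrix(stats::rnorm(n * k), n, k))
}

#' Hungarian linear sum assignment
#'
#' Solves the linear sum assignment problem for a square cost matrix by the
#' shortest-augmenting-path (Jonker-Volgenant style) algorithm in O(n^3).
#'
#' @param cost square numeric cost matrix; entry `[i, j]` is the cost of
#'   assigning row `i` to column `j`.
#' @param maximize if `TRUE`, maximize total score instead of minimizing cost.
#' @return integer vector `perm` with `perm[i]` the column assigned to row `i`.
#' @examples
#' cost <- matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3)
#' solve_lsap(cost)
#' @export
solve_lsap <- function(cost, maximize = FALSE) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  if (maximize) cost <- -cost
  n <- nrow(cost)
  # columns indexed 0..n (0 = dummy), stored at position j + 1
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1]] <- j
  perm
}
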