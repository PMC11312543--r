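#' Simulate a ragged dataset with planted Pf2 structure
#'
#' Generates `X_i = P_i B diag(a_i) C' + noise_sd * E_i` with known ground
#' truth: condition factors `A` drawn from `condition_law`, a
#' well-conditioned near-identity eigen-state matrix `B` (or a dense random
#' one with `hard = TRUE`), gene factors `C` with orthonormalized random
#' columns, and per-condition random column-orthonormal projections `P_i`
#' with cell counts drawn uniformly from `cells`. Optional labeled cell
#' blocks receive elevated projection loadings on a chosen component,
#' emulating a cell type that drives that component; block membership is
#' recorded in the dataset's cell labels (remaining cells are labeled
#' `"other"`).
#'
#' The generator emulates the model class the decomposition targets, not
#' sequencing noise: entries are Gaussian around the low-rank signal, with
#' no counts, dropout or library-size structure.
#'
#' @param n_conditions number of conditions I.
#' @param cells length-2 integer range `c(J_min, J_max)` of cells per
#'   condition (a single number fixes the count).
#' @param n_genes number of genes K.
#' @param rank number of planted components.
#' @param noise_sd standard deviation of the i.i.d. additive Gaussian noise;
#'   the planted signal is scaled to unit per-entry root-mean-square, so
#'   `noise_sd = 1` puts about half the variance in noise.
#' @param condition_law distribution of the condition factor entries:
#'   `"uniform"` (U(0,1)), `"lognormal"`, or `"block"` (each component
#'   elevated in a random half of the conditions).
#' @param labeled_blocks optional list of `list(label =, component =,
#'   fraction =)` triples: in every condition, `fraction` of the cells are
#'   given `label` and an elevated loading on `component`.
#' @param block_boost loading boost added to labeled cells before
#'   orthonormalization (default 3).
#' @param hard use a dense random `B` instead of near-identity.
#' @param seed integer seed; the same seed reproduces the dataset bit for
#'   bit.
#' @return list with `dataset` (a [ragged_dataset]), `truth` (a standardized
#'   [pf2] object holding the planted factors; its `r2x` is the planted
#'   signal's share of the generated data's squared norm) and, when blocks
#'   were planted, `blocks` (data.frame mapping each block label to its
#'   component index in the standardized truth).
#' @export
pf2_sim <- function(n_conditions, cells, n_genes, rank, noise_sd = 0.1,
                    condition_law = c("uniform", "lognormal", "block"),
                    labeled_blocks = NULL, block_boost = 3, hard = FALSE,
                    seed = 0L) {
  condition_law <- match.arg(condition_law)
  stopifnot(n_conditions >= 1, n_genes >= rank, rank >= 1, noise_sd >= 0)
  if (length(cells) == 1) cells <- c(cells, cells)
  stopifnot(length(cells) == 2, cells[1] >= rank, cells[2] >= cells[1])
  if (!is.null(labeled_blocks)) {
    for (blk in labeled_blocks) {
      stopifnot(is.list(blk), !is.null(blk$label), !is.null(blk$component),
                !is.null(blk$fraction),
                blk$component >= 1, blk$component <= rank,
                blk$fraction > 0, blk$fraction <= 1)
    }
  }
  out <- with_seed(seed, {
    i_n <- n_conditions
    js <- sample(cells[1]:cells[2], i_n, replace = TRUE)
    a <- switch(condition_law,
      uniform = matrix(stats::runif(i_n * rank), i_n, rank),
      lognormal = matrix(stats::rlnorm(i_n * rank, sdlog = 0.5), i_n, rank),
      block = {
        m <- matrix(stats::runif(i_n * rank, 0.05, 0.3), i_n, rank)
        for (r in seq_len(rank)) {
          on <- sample.int(i_n, max(1, floor(i_n / 2)))
          m[on, r] <- stats::runif(length(on), 0.7, 1)
        }
        m
      })
    b <- if (hard) {
      matrix(stats::rnorm(rank * rank), rank, rank)
    } else {
      diag(rank) + matrix(stats::rnorm(rank * rank, sd = 0.1), rank, rank)
    }
    cc <- random_orthonormal(n_genes, rank)
    projections <- vector("list", i_n)
    labels <- vector("list", i_n)
    for (i in seq_len(i_n)) {
      g <- matrix(stats::rnorm(js[i] * rank), js[i], rank)
      lab <- rep("other", js[i])
      if (!is.null(labeled_blocks)) {
        free <- seq_len(js[i])
        for (blk in labeled_blocks) {
          n_blk <- max(1, round(blk$fraction * js[i]))
          pick <- sample(free, min(n_blk, length(free)))
          free <- setdiff(free, pick)
          lab[pick] <- blk$label
          # the block's component is a cell-type program: block cells carry
          # it strongly, other cells barely express it
          g[, blk$component] <- 0.2 * g[, blk$component]
          g[pick, blk$component] <- g[pick, blk$component] + block_boost
        }
      }
      projections[[i]] <- polar_orthonormal(g)
      labels[[i]] <- lab
    }
    xs <- lapply(seq_len(i_n), function(i) {
      projections[[i]] %*% b %*% (t(cc) * a[i, ])
    })
    # scale the planted signal to unit per-entry root-mean-square, so
    # noise_sd reads directly as a noise-to-signal amplitude ratio
    n_entries <- sum(js) * n_genes
    signal2 <- sum(vapply(xs, function(m) sum(m^2), numeric(1)))
    sc <- sqrt(n_entries / signal2)
    xs <- lapply(xs, `*`, sc)
    a <- a * sc
    signal2 <- n_entries
    if (noise_sd > 0) {
      xs <- lapply(xs, function(m) {
        m + noise_sd * matrix(stats::rnorm(length(m)), nrow(m), ncol(m))
      })
    }
    total2 <- sum(vapply(xs, function(m) sum(m^2), numeric(1)))
    list(js = js, a = a, b = b, cc = cc, projections = projections,
         labels = labels, xs = xs, signal_share = signal2 / total2)
  })
  cond_ids <- sprintf("cond%02d", seq_len(n_conditions))
  ds <- ragged_dataset(out$xs, cond_ids,
                       sprintf("gene%03d", seq_len(n_genes)),
                       cell_labels = if (is.null(labeled_blocks)) NULL
                                     else out$labels)
  truth <- new_pf2(A = out$a, B = out$b, C = out$cc,
                   projections = out$projections,
                   weights = rep(1, rank), rank = rank,
                   condition_ids = cond_ids, gene_ids = ds$gene_ids,
                   r2x = out$signal_share, n_iterations = 0L,
                   converged = TRUE, standardized = FALSE)
  truth_std <- pf2_standardize(truth)
  res <- list(dataset = ds, truth = truth_std)
  if (!is.null(labeled_blocks)) {
    # standardization reorders components; recover each block's new index
    res$blocks <- do.call(rbind, lapply(labeled_blocks, function(blk) {
      data.frame(label = blk$label,
                 planted_component = blk$component,
                 truth_component = which.max(
                   abs(crossprod(truth_std$C, out$cc[, blk$component]))))
    }))
  }
  res
}

#' Pure-noise ragged dataset
#'
#' Standard-normal entries with no planted structure; used to calibrate the
#' null scale of the factor match score and of rank-selection behavior.
#'
#' @param n_conditions number of conditions.
#' @param cells cells per condition (single number or range, as in
#'   [pf2_sim()]).
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return a [ragged_dataset].
#' @export
null_dataset <- function(n_conditions, cells, n_genes, seed = 0L) {
  stopifnot(n_conditions >= 1, n_genes >= 1)
  if (length(cells) == 1) cells <- c(cells, cells)
  out <- with_seed(seed, {
    js <- sample(cells[1]:cells[2], n_conditions, replace = TRUE)
    lapply(js, function(j) matrix(stats::rnorm(j * n_genes), j, n_genes))
  })
  ragged_dataset(out, sprintf("cond%02d", seq_len(n_conditions)),
                 sprintf("gene%03d", seq_len(n_genes)))
}
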