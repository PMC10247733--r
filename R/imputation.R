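## Markov-affinity graph diffusion imputation: a kNN graph over cells in PCA
## space with adaptive Gaussian kernels is symmetrized, row-normalized and
## powered to smooth expression before correlation-based analyses.

#' Library-size normalize and log-transform a count matrix
#'
#' Scales every cell's counts to the median per-cell total, then applies
#' log1p. The per-cell scale factors are returned so imputed values can be
#' mapped back to the absolute scale (see [descale_imputed()]); the
#' dosage-ratio analyses require absolute-scale values because per-cell
#' normalization would erase the global 2:1 structure.
#'
#' @param counts A [count_matrix()] or a cells x genes numeric matrix.
#' @return List: `norm` (dense cells x genes log1p matrix), `scale_factors`
#'   (per-cell totals / median total), `target_total`.
#' @export
normalize_cells <- function(counts) {
  m <- if (inherits(counts, "CountMatrix")) counts$counts else counts
  totals <- Matrix::rowSums(m)
  if (any(totals <= 0)) stop("cells with zero total counts; filter first")
  target <- median(totals)
  sf <- totals / target
  norm <- log1p(as.matrix(m) / sf)
  list(norm = norm, scale_factors = sf, target_total = target)
}

#' Map imputed log-scale expression back to the absolute count scale
#'
#' Inverts the per-cell scaling applied by [normalize_cells()]:
#' `expm1(imputed) * scale_factor`. Dosage-ratio analyses run on this scale.
#'
#' @param imputed Cells x genes imputed matrix on the log1p scale.
#' @param scale_factors Per-cell factors from [normalize_cells()].
#' @return Cells x genes matrix on the absolute scale.
#' @export
descale_imputed <- function(imputed, scale_factors) {
  expm1(imputed) * scale_factors
}

# PCA scores via eigen-decomposition of the smaller of the covariance or
# Gram matrix; avoids a full SVD on wide single-cell matrices
.pca_scores <- function(x, n_pc) {
  x <- sweep(x, 2, colMeans(x))
  n <- nrow(x); p <- ncol(x)
  k <- min(n_pc, n - 1L, p)
  if (p <= n) {
    ev <- eigen(crossprod(x) / (n - 1), symmetric = TRUE)
    x %*% ev$vectors[, seq_len(k), drop = FALSE]
  } else {
    ev <- eigen(tcrossprod(x) / (n - 1), symmetric = TRUE)
    ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(k)], 0) * (n - 1)), k)
  }
}

#' Build a Markov affinity matrix over cells
#'
#' kNN graph on cells using Euclidean distances in top-principal-component
#' space, Gaussian kernel with per-cell adaptive bandwidth equal to the
#' distance to the `ka`-th neighbour, symmetrization (A + t(A))/2, and row
#' normalization to a stochastic matrix.
#'
#' @param norm Cells x genes normalized (log1p) matrix, e.g.
#'   `normalize_cells()$norm`.
#' @param k_neighbors Neighbours per cell (default 30).
#' @param ka_adaptive Neighbour index setting the kernel bandwidth
#'   (default 10); must be <= `k_neighbors`.
#' @param n_pc Number of principal components for the distance space
#'   (default 20).
#' @return Dense row-stochastic cells x cells matrix.
#' @export
build_markov <- function(norm, k_neighbors = 30, ka_adaptive = 10,
                         n_pc = 20) {
  n <- nrow(norm)
  if (n < k_neighbors + 1L)
    stop("parameter error: need at least k_neighbors + 1 = ",
         k_neighbors + 1L, " cells, got ", n)
  if (ka_adaptive > k_neighbors)
    stop("parameter error: ka_adaptive must be <= k_neighbors")
  pcs <- .pca_scores(norm, n_pc)
  d <- as.matrix(dist(pcs))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    nb <- ord[ord != i][seq_len(k_neighbors)]
    sigma <- d[i, nb[ka_adaptive]]
    if (sigma <= 0) sigma <- .Machine$double.eps
    A[i, nb] <- exp(-(d[i, nb] / sigma)^2)
    A[i, i] <- 1
  }
  A <- (A + t(A)) / 2
  A / rowSums(A)
}

#' Diffuse expression over the cell graph
#'
#' Returns `M^t %*% X`: `t_steps` applications of the row-stochastic Markov
#' matrix to the expression matrix. `t_steps = 0` returns the input
#' unchanged.
#'
#' @param norm Cells x genes matrix (same cell order as `markov`).
#' @param markov Row-stochastic matrix from [build_markov()].
#' @param t_steps Non-negative integer diffusion time (typical defaults: 3
#'   for a KBM7-style dataset, 7 for a PDX-style dataset).
#' @return Cells x genes imputed matrix (non-negative for non-negative
#'   input).
#' @export
impute_expression <- function(norm, markov, t_steps = 3) {
  if (t_steps < 0 || t_steps != round(t_steps))
    stop("parameter error: t_steps must be a non-negative integer")
  rs <- rowSums(markov)
  if (any(abs(rs - 1) > 1e-8) || any(markov < -1e-12))
    stop("contract error: markov matrix is not row-stochastic")
  x <- as.matrix(norm)
  for (i in seq_len(t_steps)) x <- markov %*% x
  dimnames(x) <- dimnames(norm)
  x
}

#' Drop genes with zero variance across cells
#'
#' Removes genes whose expression is constant across cells (including
#' all-zero genes), as required before correlation and signature analyses.
#'
#' @param m Cells x genes matrix.
#' @return The matrix restricted to varying genes.
#' @export
drop_constant_genes <- function(m) {
  v <- apply(m, 2, function(col) max(col) - min(col))
  m[, v > 0, drop = FALSE]
}
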