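# Shared fixtures and independent brute-force oracles used across tests.

# small clean simulation: high amplitude, Poisson limit, no dropout
clean_sim_config <- function(n_cells = 300, n_genes = 400, seed = 7, ...) {
  sim_config(n_cells_per_group = n_cells, n_genes = n_genes,
             program_amplitude = 10, nb_dispersion = 1e-10,
             dropout_rate = 0, seed = seed, ...)
}

truth_signatures <- function(sim) {
  gt <- sim$truth$genes
  lapply(setNames(cc_phases(), cc_phases()),
         function(p) gt$gene_id[gt$phase == p])
}

# independent step-up BH: literal definition, quadratic scan
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# exhaustive two-sided rank-sum p over all C(n+m, n) group assignments
wilcox_permutation_oracle <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n)])
  e <- n * (N + 1) / 2
  combs <- utils::combn(N, n)
  sums <- colSums(matrix(r[combs], nrow = n))
  mean(abs(sums - e) >= abs(obs - e) - 1e-9)
}

# exhaustive hypergeometric upper tail by enumerating all draws of |B|
overlap_enumeration_oracle <- function(set_a, set_b, universe) {
  k_obs <- length(intersect(set_a, set_b))
  draws <- utils::combn(length(universe), length(set_b))
  hits <- apply(draws, 2, function(idx)
    length(intersect(universe[idx], set_a)))
  mean(hits >= k_obs)
}

# brute-force rolling window means: explicit distance filter per anchor
rolling_oracle <- function(scores2d, expression, ellipse, radius,
                           n_anchors) {
  tg <- seq(0, 2 * pi, length.out = n_anchors + 1)[-(n_anchors + 1)]
  anchors <- ellipse_points(ellipse, tg)
  res <- matrix(NA_real_, n_anchors, ncol(expression))
  nn <- integer(n_anchors)
  for (k in seq_len(n_anchors)) {
    keep <- logical(nrow(scores2d))
    for (i in seq_len(nrow(scores2d)))
      keep[i] <- sqrt(sum((scores2d[i, ] - anchors[k, ])^2)) <= radius
    nn[k] <- sum(keep)
    if (any(keep))
      res[k, ] <- colMeans(expression[keep, , drop = FALSE])
  }
  list(mean = res, n = nn, angles = tg)
}

# all-pairs colocalization per cell
coloc_oracle <- function(foci_a, foci_b, radius) {
  ids <- union(foci_a$cell_id, foci_b$cell_id)
  fa <- fb <- c(); na <- nb <- 0
  for (id in ids) {
    A <- foci_a[foci_a$cell_id == id, ]
    B <- foci_b[foci_b$cell_id == id, ]
    if (nrow(A)) {
      occ <- vapply(seq_len(nrow(A)), function(i) {
        if (!nrow(B)) return(FALSE)
        any(sqrt((B$x - A$x[i])^2 + (B$y - A$y[i])^2) <= radius)
      }, logical(1))
      fa <- c(fa, mean(occ)); na <- na + 1
    }
    if (nrow(B)) {
      occ <- vapply(seq_len(nrow(B)), function(i) {
        if (!nrow(A)) return(FALSE)
        any(sqrt((A$x - B$x[i])^2 + (A$y - B$y[i])^2) <= radius)
      }, logical(1))
      fb <- c(fb, mean(occ)); nb <- nb + 1
    }
  }
  list(frac_a = mean(fa), frac_b = mean(fb))
}

# points on an ellipse with given geometric parameters
ellipse_truth_points <- function(n, cx, cy, a, b, phi, noise_sd = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- cx + a * cos(t) * cos(phi) - b * sin(t) * sin(phi)
  y <- cy + a * cos(t) * sin(phi) + b * sin(t) * cos(phi)
  if (noise_sd > 0) {
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
  }
  cbind(x, y)
}
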