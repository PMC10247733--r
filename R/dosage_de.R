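## ERCC spike-in normalization, stage-specific diploid:haploid dosage
## ratios with Wilcoxon/BH testing, and the cutoff census of
## dosage-deviating genes.

#' Normalize a bulk count table to top-5 ERCC spike-ins
#'
#' Selects the five ERCC spike-in transcripts with the highest mean count
#' across all samples, then divides every gene's count in each sample by the
#' mean of those five ERCC counts in that sample. Because spike-ins are
#' added at fixed amounts per sample, this puts samples on an absolute
#' scale and removes depth differences exactly.
#'
#' @param bulk Numeric matrix (rows = genes + ERCC spike-ins, columns =
#'   samples); ERCC rows identified by rownames starting with "ERCC".
#' @param n_top Number of top spike-ins to average (default 5).
#' @return The normalized matrix (ERCC rows retained, also normalized),
#'   with the per-sample factors in `attr(, "ercc_factors")`.
#' @export
ercc_normalize <- function(bulk, n_top = 5) {
  bulk <- as.matrix(bulk)
  is_ercc <- grepl("^ERCC", rownames(bulk))
  if (sum(is_ercc) < n_top)
    stop("normalization error: need at least ", n_top, " ERCC rows, found ",
         sum(is_ercc))
  ercc <- bulk[is_ercc, , drop = FALSE]
  top <- order(rowMeans(ercc), decreasing = TRUE)[seq_len(n_top)]
  factors <- colMeans(ercc[top, , drop = FALSE])
  if (any(factors <= 0))
    stop("normalization error: zero top-ERCC mean in sample(s) ",
         paste(colnames(bulk)[factors <= 0], collapse = ", "))
  out <- sweep(bulk, 2, factors, "/")
  attr(out, "ercc_factors") <- factors
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the permutation distribution of the rank sum
#' (tie-aware, via dynamic programming over the tied rank multiset) when
#' both groups have at most `exact_max` observations; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-group size for the exact branch (default 25).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y); N <- n + m
  if (n == 0 || m == 0) stop("empty sample")
  r <- rank(c(x, y))
  if (n <= exact_max && m <= exact_max) {
    return(.wilcox_exact_two_sided(round(2 * r), n))
  }
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  tie_tab <- table(r)
  sigma2 <- n * m / 12 *
    ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - n * m / 2
  z <- z - sign(z) * 0.5
  min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
}

# exact two-sided rank-sum p over the permutation distribution of the
# observed (possibly tied) rank multiset; r2 = doubled ranks (integers)
.wilcox_exact_two_sided <- function(r2, n) {
  N <- length(r2)
  S <- sum(r2)
  f <- matrix(0, nrow = n + 1, ncol = S + 1)
  f[1, 1] <- 1
  for (r in r2) {
    kmax <- n
    for (k in seq(kmax, 1)) {
      idx <- (r + 1):(S + 1)
      f[k + 1, idx] <- f[k + 1, idx] + f[k, seq_len(S - r + 1)]
    }
  }
  counts <- f[n + 1, ]
  sums <- 0:S
  E <- n * (N + 1)                       # mean of the doubled rank sum
  obs <- sum(r2[seq_len(n)])
  dev <- abs(obs - E)
  p <- sum(counts[abs(sums - E) >= dev - 1e-9]) / choose(N, n)
  min(1, p)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Numeric vector of p-values.
#' @return q-values: `q_i = min_{j >= i} ( p_(j) * n / j )`, capped at 1,
#'   in the original order.
#' @export
bh_correct <- function(p) {
  n <- length(p)
  if (!n) return(numeric())
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

#' Per-stage diploid:haploid dosage ratios with differential testing
#'
#' Restricts both groups to cells assigned to one cell-cycle stage. Per
#' gene it reports two complementary views:
#' \itemize{
#'   \item the absolute-scale group means and their log2 diploid/haploid
#'     ratio (finite only when both means are positive) — this is the
#'     quantity whose null expectation under pure genome doubling is 2:1
#'     (log2 = 1);
#'   \item a two-sided Wilcoxon rank-sum p-value computed on per-cell
#'     library-normalized expression (each cell divided by its total over
#'     the supplied matrix), with BH q-values across genes within the
#'     stage. Normalizing removes the global dosage, so the test is
#'     sensitive to stage-specific deviations from the 2:1 expectation
#'     rather than to the expectation itself.
#' }
#' A gene is flagged `is_de` when q < `q_max` and its normalized fold
#' change exceeds `fc_min` in either direction.
#'
#' @param expr_haploid,expr_diploid Cells x genes absolute-scale matrices
#'   (same gene columns): de-scaled imputed expression or raw counts.
#' @param phases_haploid,phases_diploid Per-cell assigned phases.
#' @param stage One of [cc_phases()].
#' @param min_cells Minimum cells per group in the stage (default 20).
#' @param fc_min,q_max DE thresholds (defaults 1.25 and 0.01).
#' @return Data.frame: gene, stage, mean_diploid, mean_haploid, log2_ratio,
#'   norm_log2fc, p_value, q_value, is_de, n_diploid, n_haploid.
#' @export
stage_ratios <- function(expr_haploid, expr_diploid, phases_haploid,
                         phases_diploid, stage, min_cells = 20,
                         fc_min = 1.25, q_max = 0.01) {
  stopifnot(identical(colnames(expr_haploid), colnames(expr_diploid)))
  h <- which(phases_haploid == stage)
  d <- which(phases_diploid == stage)
  if (length(h) < min_cells || length(d) < min_cells)
    stop(sprintf(
      "stage error: stage '%s' has %d haploid / %d diploid cells (need >= %d)",
      stage, length(h), length(d), min_cells))
  xh <- expr_haploid[h, , drop = FALSE]
  xd <- expr_diploid[d, , drop = FALSE]
  nh <- xh / rowSums(xh)
  nd <- xd / rowSums(xd)
  mh <- colMeans(xh); md <- colMeans(xd)
  mnh <- colMeans(nh); mnd <- colMeans(nd)
  pv <- vapply(seq_len(ncol(xh)), function(j)
    wilcoxon_rank_sum(nd[, j], nh[, j]), numeric(1))
  qv <- bh_correct(pv)
  lr <- ifelse(mh > 0 & md > 0, log2(md / mh), NA_real_)
  nfc <- ifelse(mnh > 0 & mnd > 0, log2(mnd / mnh), NA_real_)
  data.frame(gene = colnames(xh), stage = stage,
             mean_diploid = md, mean_haploid = mh, log2_ratio = lr,
             norm_log2fc = nfc, p_value = pv, q_value = qv,
             is_de = !is.na(nfc) & qv < q_max & abs(nfc) > log2(fc_min),
             n_diploid = length(d), n_haploid = length(h),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dosage ratios across all populated stages
#'
#' Runs [stage_ratios()] for every stage where both groups reach
#' `min_cells`, skipping (with a message) the rest.
#'
#' @inheritParams stage_ratios
#' @return Row-bound data.frame over stages.
#' @export
all_stage_ratios <- function(expr_haploid, expr_diploid, phases_haploid,
                             phases_diploid, min_cells = 20) {
  res <- list()
  for (st in cc_phases()) {
    if (sum(phases_haploid == st) >= min_cells &&
        sum(phases_diploid == st) >= min_cells) {
      res[[st]] <- stage_ratios(expr_haploid, expr_diploid, phases_haploid,
                                phases_diploid, st, min_cells)
    } else {
      message("skipping stage '", st, "': too few cells")
    }
  }
  do.call(rbind, res)
}

#' Census of genes below a log2 dosage-ratio cutoff, per stage
#'
#' Counts, per cell-cycle stage, genes whose log2 diploid:haploid ratio
#' falls below the cutoff (default 0.5, i.e. ~1.4-fold in linear space
#' against the 2-fold dosage expectation). Genes with a zero mean in either
#' group are excluded from ratios and counted separately. ECDF coordinates
#' of the per-stage ratio distributions are returned for plotting.
#'
#' @param ratio_table Output of [stage_ratios()] / [all_stage_ratios()].
#' @param ratio_cutoff_log2 Log2-space cutoff (default 0.5).
#' @return List: `counts` (stage, n_below, n_with_ratio, n_excluded_zero),
#'   `linear_cutoff` (2^cutoff), `linear_cutoff_rounded` (1 decimal),
#'   `ecdf` (per-stage sorted log2 ratios).
#' @export
cutoff_census <- function(ratio_table, ratio_cutoff_log2 = 0.5) {
  stages <- unique(ratio_table$stage)
  counts <- do.call(rbind, lapply(stages, function(st) {
    sub <- ratio_table[ratio_table$stage == st, ]
    ok <- !is.na(sub$log2_ratio)
    data.frame(stage = st,
               n_below = sum(sub$log2_ratio[ok] < ratio_cutoff_log2),
               n_with_ratio = sum(ok),
               n_excluded_zero = sum(!ok))
  }))
  ecdfs <- lapply(stages, function(st)
    sort(ratio_table$log2_ratio[ratio_table$stage == st]))
  names(ecdfs) <- stages
  list(counts = counts,
       linear_cutoff = 2^ratio_cutoff_log2,
       linear_cutoff_rounded = round(2^ratio_cutoff_log2, 1),
       ecdf = ecdfs)
}
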