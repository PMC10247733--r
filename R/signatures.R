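## Anchor-gene co-expression signatures, per-cell signature scores, and
## hypergeometric gene-set overlap tests.

#' Co-expression signature around an anchor gene
#'
#' Computes the Pearson correlation of the anchor gene with every other
#' nonzero-variance gene across cells (on imputed expression) and returns
#' the genes with r >= `r_min`, always including the anchor itself.
#'
#' @param imputed Cells x genes imputed matrix.
#' @param anchor_gene Gene id present in the matrix.
#' @param r_min Pearson inclusion threshold (default 0.5).
#' @return Character vector of member genes, with the correlation values in
#'   `attr(, "r")`.
#' @export
coexpression_signature <- function(imputed, anchor_gene, r_min = 0.5) {
  if (!anchor_gene %in% colnames(imputed))
    stop("signature error: anchor gene '", anchor_gene, "' not in matrix")
  a <- imputed[, anchor_gene]
  if (sd(a) == 0)
    stop("signature error: anchor gene '", anchor_gene,
         "' has zero variance")
  v <- apply(imputed, 2, sd)
  candidates <- colnames(imputed)[v > 0]
  r <- as.vector(cor(imputed[, candidates, drop = FALSE], a))
  names(r) <- candidates
  members <- union(anchor_gene, candidates[r >= r_min])
  structure(members, r = r[members])
}

#' Per-cell signature score
#'
#' Mean imputed expression of the member genes per cell (raw-mean default;
#' `standardize = TRUE` averages z-scored expression instead).
#'
#' @param imputed Cells x genes imputed matrix.
#' @param gene_set Character vector of member genes.
#' @param standardize Z-score genes before averaging (default FALSE).
#' @return Named numeric vector (one score per cell).
#' @export
signature_score <- function(imputed, gene_set, standardize = FALSE) {
  memb <- intersect(gene_set, colnames(imputed))
  if (!length(memb)) stop("signature error: no member genes in matrix")
  x <- imputed[, memb, drop = FALSE]
  if (standardize) {
    s <- apply(x, 2, sd); s[s == 0] <- 1
    x <- sweep(sweep(x, 2, colMeans(x)), 2, s, "/")
  }
  setNames(rowMeans(x), rownames(imputed))
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability of observing at least the actual overlap when
#' |B| genes are drawn from the universe containing |A| successes.
#'
#' @param set_a,set_b Character vectors; both must be subsets of `universe`.
#' @param universe Character vector of background genes.
#' @return List: `overlap`, `expected`, `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("domain error: sets must be subsets of the universe")
  k <- length(intersect(set_a, set_b))
  nU <- length(universe); nA <- length(set_a); nB <- length(set_b)
  p <- phyper(k - 1, nA, nU - nA, nB, lower.tail = FALSE)
  list(overlap = k, expected = nA * nB / nU, p_value = p)
}

#' Compare signature scores between two groups (per stratum)
#'
#' Two-sided Wilcoxon rank-sum test of the score distributions between the
#' two levels of `groups`, optionally within strata (e.g. compartment or
#' ploidy).
#'
#' @param scores Numeric per-cell scores.
#' @param groups Two-level per-cell factor (e.g. treated / vehicle).
#' @param strata Optional per-cell stratum labels.
#' @return Data.frame: stratum, group levels, n per group, p_value.
#' @export
group_score_compare <- function(scores, groups, strata = NULL) {
  lv <- unique(as.character(groups))
  if (length(lv) != 2L) stop("groups must have exactly two levels")
  if (is.null(strata)) strata <- rep("all", length(scores))
  out <- do.call(rbind, lapply(unique(strata), function(st) {
    sel <- strata == st
    x <- scores[sel & groups == lv[1]]
    y <- scores[sel & groups == lv[2]]
    data.frame(stratum = st, group1 = lv[1], group2 = lv[2],
               n1 = length(x), n2 = length(y),
               p_value = if (length(x) && length(y))
                 wilcoxon_rank_sum(x, y) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
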