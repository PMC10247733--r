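## Phase signature filtering and per-cell cell-cycle phase assignment from
## five metagene scores (G1S, S, G2, G2M, MG1).

#' Filter a phase signature against a dataset
#'
#' Keeps signature genes that are (i) detected (raw UMI > 0) in at least
#' `min_expressing_fraction` of cells and (ii) Pearson-correlated at
#' r >= `r_min` with the mean imputed expression of all genes passing (i)
#' (the mean is computed once over the (i)-passing set). When `groups` is
#' supplied the filter runs within each group separately and a gene is kept
#' if it passes in either group.
#'
#' @param counts A [count_matrix()] or raw cells x genes matrix.
#' @param imputed Imputed cells x genes matrix (same cells).
#' @param signature Character vector of member gene ids.
#' @param min_expressing_fraction Detection threshold (default 0.05).
#' @param r_min Pearson threshold (default 0.5).
#' @param groups Optional per-cell group labels.
#' @param name Signature name used in error messages.
#' @return Character vector: the retained members.
#' @export
filter_signature <- function(counts, imputed, signature,
                             min_expressing_fraction = 0.05, r_min = 0.5,
                             groups = NULL, name = "signature") {
  raw <- if (inherits(counts, "CountMatrix")) counts$counts else counts
  sig <- intersect(signature, colnames(imputed))
  if (!length(sig))
    stop("signature error: no members of '", name, "' in the matrix")
  one_group <- function(rows) {
    det <- Matrix::colSums(raw[rows, sig, drop = FALSE] > 0) / length(rows)
    eligible <- sig[det >= min_expressing_fraction]
    if (!length(eligible)) return(character())
    ref <- rowMeans(imputed[rows, eligible, drop = FALSE])
    if (sd(ref) == 0) return(character())
    r <- suppressWarnings(
      cor(imputed[rows, eligible, drop = FALSE], ref))[, 1]
    eligible[!is.na(r) & r >= r_min]
  }
  kept <- if (is.null(groups)) {
    one_group(seq_len(nrow(imputed)))
  } else {
    unique(unlist(lapply(unique(groups),
                         function(g) one_group(which(groups == g)))))
  }
  if (!length(kept))
    stop("signature error: no genes of '", name, "' survive filtering")
  sig[sig %in% kept]
}

#' Score cells for the five phase signatures and assign a phase
#'
#' Each gene is standardized (z-score across cells); a phase's score for a
#' cell is the mean z-scored expression over that phase's filtered signature
#' genes. The assigned phase is the arg-max score; exact ties give
#' "unassigned". Raw-mean (non-standardized) scoring is available via
#' `standardize = FALSE`.
#'
#' @param imputed Imputed cells x genes matrix.
#' @param signatures Named list of five filtered signatures (names must be
#'   [cc_phases()]).
#' @param standardize Z-score genes before averaging (default TRUE).
#' @return Data.frame: cell_id, one score column per phase, `phase`.
#' @export
score_phases <- function(imputed, signatures, standardize = TRUE) {
  if (!setequal(names(signatures), cc_phases()))
    stop("signatures must be named by the five phases")
  if (any(!lengths(signatures)))
    stop("signature error: empty signature")
  x <- imputed
  if (standardize) {
    mu <- colMeans(x)
    s <- apply(x, 2, sd)
    s[s == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, s, "/")
  }
  scores <- vapply(cc_phases(), function(p) {
    memb <- intersect(signatures[[p]], colnames(x))
    if (!length(memb))
      stop("signature error: no genes of '", p, "' in the matrix")
    rowMeans(x[, memb, drop = FALSE])
  }, numeric(nrow(x)))
  best <- max.col(scores, ties.method = "first")
  top <- scores[cbind(seq_len(nrow(scores)), best)]
  n_at_top <- rowSums(scores == top)
  phase <- ifelse(n_at_top > 1L, "unassigned", cc_phases()[best])
  out <- data.frame(cell_id = rownames(imputed), scores, phase = phase,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-group cell-cycle phase proportions
#'
#' Fractions of assigned cells in each phase, per group; unassigned cells
#' are reported separately and excluded from the denominators.
#'
#' @param scores Output of [score_phases()].
#' @param groups Per-cell group labels (same order as `scores`).
#' @return Data.frame: group, phase, n, fraction (summing to 1 per group
#'   over the five phases), plus one `unassigned` row per group with the
#'   unassigned count and its fraction of all cells.
#' @export
phase_proportions <- function(scores, groups) {
  stopifnot(length(groups) == nrow(scores))
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    ph <- scores$phase[groups == g]
    assigned <- ph[ph != "unassigned"]
    n <- vapply(cc_phases(), function(p) sum(assigned == p), 0L)
    rbind(data.frame(group = g, phase = cc_phases(), n = n,
                     fraction = if (length(assigned)) n / length(assigned)
                                else NA_real_),
          data.frame(group = g, phase = "unassigned",
                     n = sum(ph == "unassigned"),
                     fraction = sum(ph == "unassigned") / length(ph)))
  }))
  rownames(out) <- NULL
  out
}
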