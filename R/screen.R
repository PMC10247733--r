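## CRISPR knockout screen depletion scoring and the multi-screen
## intersection that nominates ploidy-specific essential genes.

#' Per-guide log2 fold change between screen samples
#'
#' Counts are scaled to equal sample totals (counts per million), a
#' pseudocount is added, and log2(endpoint / input) is taken per guide.
#' Scaling to a fixed total makes the result invariant to uniform depth
#' rescaling of either sample.
#'
#' @param table Data.frame with columns `guide`, `gene` and one count
#'   column per sample.
#' @param endpoint,input Names of the endpoint and input count columns.
#' @param pseudocount Added after depth scaling (default 1).
#' @return Data.frame: guide, gene, log2fc.
#' @export
guide_log2fc <- function(table, endpoint, input, pseudocount = 1) {
  e <- table[[endpoint]]; i <- table[[input]]
  if (is.null(e) || is.null(i)) stop("unknown sample column")
  if (any(e < 0) || any(i < 0)) stop("negative counts")
  e_s <- e / sum(e) * 1e6
  i_s <- i / sum(i) * 1e6
  data.frame(guide = table$guide, gene = table$gene,
             log2fc = log2((e_s + pseudocount) / (i_s + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Call essential genes from guide-level depletion
#'
#' Gene score = median log2FC of the gene's guides. A gene is called
#' essential iff its score is strictly below the threshold AND at least
#' `min_depleted_guides` of its guides are individually below it. The
#' threshold defaults to a quantile of the non-targeting control guides'
#' log2FCs (strict inequality, so a flat screen yields no calls).
#'
#' @param log2fc Data.frame from [guide_log2fc()]; control guides carry
#'   gene == `control_label`.
#' @param score_threshold Explicit threshold; if NULL (default), uses the
#'   `control_quantile` of control-guide log2FCs.
#' @param control_quantile Quantile for the control-derived threshold
#'   (default 0.05).
#' @param min_depleted_guides Minimum individually depleted guides
#'   (default 2).
#' @param control_label Gene label marking non-targeting controls.
#' @return Data.frame: gene, gene_score, n_guides, depleted_guides,
#'   is_essential, rank_percentile; threshold in `attr(, "threshold")`.
#' @export
call_essentials <- function(log2fc, score_threshold = NULL,
                            control_quantile = 0.05,
                            min_depleted_guides = 2,
                            control_label = "control") {
  ctrl <- log2fc$log2fc[log2fc$gene == control_label]
  if (is.null(score_threshold)) {
    if (!length(ctrl))
      stop("no control guides to derive the threshold from")
    score_threshold <- unname(quantile(ctrl, control_quantile))
  }
  tg <- log2fc[log2fc$gene != control_label, ]
  empty <- setdiff(unique(log2fc$gene), unique(c(tg$gene, control_label)))
  if (length(empty)) warning("genes with zero guides excluded: ",
                             paste(empty, collapse = ", "))
  sp <- split(tg$log2fc, tg$gene)
  gene_score <- vapply(sp, median, numeric(1))
  n_guides <- lengths(sp)
  depleted <- vapply(sp, function(v) sum(v < score_threshold), 0L)
  out <- data.frame(gene = names(sp), gene_score = unname(gene_score),
                    n_guides = unname(n_guides),
                    depleted_guides = unname(depleted),
                    is_essential = unname(gene_score < score_threshold &
                                            depleted >= min_depleted_guides),
                    stringsAsFactors = FALSE)
  out$rank_percentile <- rank(out$gene_score) / nrow(out) * 100
  rownames(out) <- NULL
  attr(out, "threshold") <- score_threshold
  out
}

#' Ploidy-specific essential-gene intersection
#'
#' Nominates genes essential in EVERY haploid screen, essential in NO
#' diploid screen, absent from the panel-wide common-essential list, and
#' present in the stage-overexpressed set, with full provenance of which
#' criterion removed each candidate.
#'
#' @param haploid_calls List of [call_essentials()] tables (haploid arms).
#' @param diploid_calls List of call tables (diploid arms).
#' @param panel_common_essentials Character vector of pan-lineage common
#'   essential genes (exclusion list).
#' @param stage_overexpressed Character vector of genes with higher
#'   stage-specific expression in the haploid cells (inclusion filter).
#' @return List: `genes` (the nominated set) and `provenance` (data.frame
#'   per candidate: which criteria passed).
#' @export
ploidy_specific_intersection <- function(haploid_calls, diploid_calls,
                                         panel_common_essentials,
                                         stage_overexpressed) {
  ess <- function(calls) lapply(calls, function(x) x$gene[x$is_essential])
  hap <- ess(haploid_calls); dip <- ess(diploid_calls)
  candidates <- Reduce(intersect, hap)
  in_dip <- if (length(dip)) Reduce(union, dip) else character()
  prov <- data.frame(
    gene = candidates,
    in_all_haploid = TRUE,
    in_any_diploid = candidates %in% in_dip,
    in_panel_common = candidates %in% panel_common_essentials,
    stage_overexpressed = candidates %in% stage_overexpressed,
    stringsAsFactors = FALSE)
  prov$selected <- !prov$in_any_diploid & !prov$in_panel_common &
    prov$stage_overexpressed
  prov$removed_by <- ifelse(prov$selected, "",
    ifelse(prov$in_any_diploid, "essential_in_diploid",
      ifelse(prov$in_panel_common, "panel_common_essential",
             "not_stage_overexpressed")))
  list(genes = sort(prov$gene[prov$selected]), provenance = prov)
}
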