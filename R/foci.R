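## DNA-damage focus quantification: DAPI-based cell-cycle binning, foci
## count ratios against the genome-dosage expectation, and centroid-based
## colocalization metrics.

.foci_counts <- function(tab, channel) {
  f <- tab$foci[tab$foci$channel == channel, ]
  n <- table(factor(f$cell_id, levels = tab$cells$cell_id))
  as.integer(n)
}

#' Bin cells by nuclear DAPI intensity
#'
#' Within-group quantile cuts of integrated DAPI signal produce low, medium
#' and high DNA-content bins, mapped to cell-cycle stages G1/S, S and G2/M
#' respectively.
#'
#' @param cells Data.frame with columns `cell_id`, `group`,
#'   `dapi_intensity` (e.g. `simulate_foci()$cells`).
#' @param quantiles Two cut fractions with 0 < q1 < q2 < 1
#'   (default c(0.3, 0.7)).
#' @return `cells` with a `dapi_bin` column (low/medium/high); the
#'   bin-to-stage mapping is in `attr(, "bin_stage")`.
#' @export
dapi_bin <- function(cells, quantiles = c(0.3, 0.7)) {
  if (length(quantiles) != 2 || quantiles[1] <= 0 || quantiles[2] >= 1 ||
      quantiles[1] >= quantiles[2])
    stop("quantile cuts must satisfy 0 < q1 < q2 < 1")
  cells$dapi_bin <- NA_character_
  for (g in unique(cells$group)) {
    sel <- cells$group == g
    v <- cells$dapi_intensity[sel]
    qs <- quantile(v, quantiles)
    if (qs[1] >= qs[2] || length(unique(v)) < 3)
      stop("degenerate DAPI quantiles in group '", g, "'")
    cells$dapi_bin[sel] <- as.character(cut(v, c(-Inf, qs, Inf),
                                            labels = c("low", "medium",
                                                       "high")))
  }
  attr(cells, "bin_stage") <- c(low = "G1/S", medium = "S", high = "G2/M")
  cells
}

#' Ratio of mean foci counts between two groups, tested across replicates
#'
#' Computes one ratio per replicate (mean focus count in the numerator
#' table over mean count in the denominator table) and a two-sided
#' one-sample Student's t-test of the replicate ratios against the expected
#' value (2 under the pure genome-dosage model).
#'
#' @param table_num,table_den `FociTable` objects (lists with `cells`,
#'   `foci`); replicates are matched by the `replicate` column.
#' @param channel Focus channel to count (default "gH2AX").
#' @param expected_ratio Null ratio for the t-test (default 2).
#' @return List: `replicate_ratios`, `mean_ratio`, `t_statistic`,
#'   `p_value` (NA with a note if the replicate ratios have zero variance).
#' @export
foci_ratio <- function(table_num, table_den, channel = "gH2AX",
                       expected_ratio = 2) {
  reps <- sort(intersect(unique(table_num$cells$replicate),
                         unique(table_den$cells$replicate)))
  if (length(reps) < 2)
    stop("need >= 2 common replicates for the one-sample test")
  per_cell <- function(tab) {
    data.frame(replicate = tab$cells$replicate,
               count = .foci_counts(tab, channel))
  }
  num <- per_cell(table_num); den <- per_cell(table_den)
  ratios <- vapply(reps, function(r) {
    dn <- mean(den$count[den$replicate == r])
    if (dn == 0) stop("ratio error: zero mean focus count in denominator, ",
                      "replicate ", r)
    mean(num$count[num$replicate == r]) / dn
  }, numeric(1))
  if (sd(ratios) == 0) {
    return(list(replicate_ratios = ratios, mean_ratio = mean(ratios),
                t_statistic = NA_real_, p_value = NA_real_,
                note = "zero variance across replicates; test undefined"))
  }
  tt <- t.test(ratios, mu = expected_ratio)
  list(replicate_ratios = ratios, mean_ratio = mean(ratios),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Colocalization of two focus channels by centroid distance
#'
#' A focus in channel A is occupied iff some channel-B focus in the same
#' cell lies within `match_radius` (Euclidean). Occupancy fractions are
#' computed per cell and averaged over cells having at least one focus of
#' the relevant channel.
#'
#' @param foci_a,foci_b Data.frames with columns `cell_id`, `x`, `y`.
#' @param match_radius Matching distance in image units (default 0.5).
#' @return List: `frac_a_occupied`, `frac_b_occupied` (cell-averaged),
#'   `per_cell` data.frame, `n_cells_a`, `n_cells_b`.
#' @export
colocalize <- function(foci_a, foci_b, match_radius = 0.5) {
  if (match_radius <= 0) stop("match_radius must be > 0")
  ids <- union(unique(foci_a$cell_id), unique(foci_b$cell_id))
  per <- do.call(rbind, lapply(ids, function(id) {
    A <- as.matrix(foci_a[foci_a$cell_id == id, c("x", "y")])
    B <- as.matrix(foci_b[foci_b$cell_id == id, c("x", "y")])
    fa <- fb <- NA_real_
    if (nrow(A) && nrow(B)) {
      d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
      hit <- d2 <= match_radius^2
      fa <- mean(apply(hit, 1, any))
      fb <- mean(apply(hit, 2, any))
    } else {
      if (nrow(A)) fa <- 0
      if (nrow(B)) fb <- 0
    }
    data.frame(cell_id = id, n_a = nrow(A), n_b = nrow(B),
               frac_a = fa, frac_b = fb, stringsAsFactors = FALSE)
  }))
  fa_cells <- per$n_a > 0 & !is.na(per$frac_a)
  fb_cells <- per$n_b > 0 & !is.na(per$frac_b)
  list(frac_a_occupied = if (any(fa_cells)) mean(per$frac_a[fa_cells])
                         else NA_real_,
       frac_b_occupied = if (any(fb_cells)) mean(per$frac_b[fb_cells])
                         else NA_real_,
       per_cell = per,
       n_cells_a = sum(fa_cells), n_cells_b = sum(fb_cells))
}

.subset_foci <- function(tab, keep_ids) {
  out <- list(cells = tab$cells[tab$cells$cell_id %in% keep_ids, ],
              foci = tab$foci[tab$foci$cell_id %in% keep_ids, ])
  class(out) <- "FociTable"
  out
}

#' Stage-stratified foci report
#'
#' Composes DAPI binning, replicate foci-count ratios (with the one-sample
#' t-test against the dosage expectation) and gH2AX/RAD51 colocalization
#' per DNA-content bin, plus two-sample Student's t-tests between groups
#' on per-cell gH2AX counts within each bin. Empty bins are reported as
#' missing.
#'
#' @param table A `FociTable` with two groups ("haploid", "diploid").
#' @param quantiles DAPI bin cuts (default c(0.3, 0.7)).
#' @param match_radius Colocalization radius (default 0.5).
#' @param expected_ratio Null diploid:haploid ratio (default 2).
#' @return Data.frame with one row per bin: foci means per group, the
#'   replicate ratio and its one-sample p, colocalization fractions per
#'   group, and between-group two-sample p-values on per-cell gH2AX counts
#'   (`group_t_p`) and on per-cell gH2AX occupancy by RAD51 (`occ_t_p`).
#' @export
stage_stratified_report <- function(table, quantiles = c(0.3, 0.7),
                                    match_radius = 0.5,
                                    expected_ratio = 2) {
  cells <- dapi_bin(table$cells, quantiles)
  out <- do.call(rbind, lapply(c("low", "medium", "high"), function(b) {
    ids <- cells$cell_id[cells$dapi_bin == b]
    row <- data.frame(bin = b, n_cells = length(ids),
                      mean_gH2AX_haploid = NA_real_,
                      mean_gH2AX_diploid = NA_real_,
                      ratio = NA_real_, ratio_p = NA_real_,
                      frac_gH2AX_occ_haploid = NA_real_,
                      frac_gH2AX_occ_diploid = NA_real_,
                      group_t_p = NA_real_, occ_t_p = NA_real_)
    if (!length(ids)) return(row)
    sub <- .subset_foci(table, ids)
    by_group <- lapply(c("haploid", "diploid"), function(g)
      .subset_foci(sub, sub$cells$cell_id[sub$cells$group == g]))
    names(by_group) <- c("haploid", "diploid")
    ch <- .foci_counts(by_group$haploid, "gH2AX")
    cd <- .foci_counts(by_group$diploid, "gH2AX")
    row$mean_gH2AX_haploid <- mean(ch)
    row$mean_gH2AX_diploid <- mean(cd)
    fr <- tryCatch(foci_ratio(by_group$diploid, by_group$haploid,
                              expected_ratio = expected_ratio),
                   error = function(e) NULL)
    if (!is.null(fr)) {
      row$ratio <- fr$mean_ratio
      row$ratio_p <- fr$p_value
    }
    occ <- list()
    for (g in c("haploid", "diploid")) {
      tb <- by_group[[g]]
      co <- colocalize(tb$foci[tb$foci$channel == "gH2AX", ],
                       tb$foci[tb$foci$channel == "RAD51", ],
                       match_radius)
      row[[paste0("frac_gH2AX_occ_", g)]] <- co$frac_a_occupied
      occ[[g]] <- co$per_cell$frac_a[co$per_cell$n_a > 0]
    }
    if (length(ch) > 1 && length(cd) > 1 && (sd(ch) > 0 || sd(cd) > 0))
      row$group_t_p <- t.test(cd, ch, var.equal = TRUE)$p.value
    if (length(occ$haploid) > 1 && length(occ$diploid) > 1 &&
        (sd(occ$haploid) > 0 || sd(occ$diploid) > 0))
      row$occ_t_p <- t.test(occ$haploid, occ$diploid,
                            var.equal = TRUE)$p.value
    row
  }))
  rownames(out) <- NULL
  out
}
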