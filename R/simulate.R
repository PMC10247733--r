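## Synthetic-data generators. All inputs the pipeline consumes can be drawn
## here with known ground truth: two ploidy groups at a configurable per-cell
## transcript dosage, cyclic five-phase expression programs, NB + dropout
## counting noise, ERCC-bearing bulk tables, planted-essential screen counts,
## and DNA-damage focus fields with a set colocalization fraction.

# circle is partitioned into five fixed equal arcs, one per phase in cycle
# order; dwell fractions reweight arc sampling probability so the phase
# intervals are identical across groups while occupancy differs
.phase_arc <- function(phase_idx) {
  c(lo = (phase_idx - 1) * 2 * pi / 5, hi = phase_idx * 2 * pi / 5)
}

.phase_of_theta <- function(theta) {
  cc_phases()[pmin(5L, floor(theta / (2 * pi / 5)) + 1L)]
}

# cosine-power bump peaking at `peak` with value 1; mean over the circle
.bump01 <- function(theta, peak, width) {
  ((1 + cos(theta - peak)) / 2)^width
}

.bump_circle_mean <- function(width) {
  if (width == round(width)) {
    choose(2 * width, width) / 4^width
  } else {
    th <- seq(0, 2 * pi, length.out = 4097L)[-1L]
    mean(((1 + cos(th)) / 2)^width)
  }
}

# program factor normalized to unit mean over the circle, so total expression
# is independent of the dwell distribution in expectation and the global
# diploid:haploid ratio stays at dosage_factor
.program_factor <- function(theta, peak, amplitude, width) {
  (1 + (amplitude - 1) * .bump01(theta, peak, width)) /
    (1 + (amplitude - 1) * .bump_circle_mean(width))
}

#' Simulate a two-group single-cell UMI count matrix with cell-cycle structure
#'
#' Draws `n_cells_per_group` near-haploid and diploidized cells. Each cell
#' gets an angular cell-cycle position theta: a phase is sampled from the
#' group's dwell fractions and theta uniformly within that phase's fixed arc.
#' Per-gene means are baseline x cyclic program factor (cosine bump centred
#' on the gene's phase) x group dosage scale x any planted stage-specific
#' deviation; counts are negative-binomial (Poisson in the zero-dispersion
#' limit) and then thinned by independent dropout.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (a [count_matrix()] whose `cell_meta` carries
#'   group, true phase and theta) and `truth` (list: `cells`, `genes`,
#'   `deviations`) for recovery tests.
#' @export
simulate_cells <- function(config) {
  validate_sim_config(config)
  set.seed(.derive_seed(config$seed, "simulate_cells"))
  phases <- cc_phases()
  n <- config$n_cells_per_group
  groups <- rep(c("haploid", "diploid"), each = n)
  n_tot <- 2L * n

  ph_idx <- integer(n_tot)
  theta <- numeric(n_tot)
  for (g in c("haploid", "diploid")) {
    sel <- which(groups == g)
    dw <- config$dwell_fractions[[g]][phases]
    ph_idx[sel] <- sample.int(5L, length(sel), replace = TRUE, prob = dw)
    arc <- 2 * pi / 5
    theta[sel] <- (ph_idx[sel] - 1) * arc + runif(length(sel)) * arc
  }

  n_sig <- config$n_signature_genes_per_phase
  gene_phase <- c(rep(phases, each = n_sig),
                  rep("none", config$n_genes - 5L * n_sig))
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  peak <- ifelse(gene_phase == "none", NA_real_,
                 (match(gene_phase, phases) - 0.5) * 2 * pi / 5)
  # baselines of the cyclic genes are matched across the five phase
  # programs (one draw reused per phase rank): programs stay exchangeable,
  # so total expression is exactly dwell-independent in expectation and the
  # global diploid:haploid ratio equals dosage_factor
  sig_base <- rlnorm(n_sig, config$baseline_meanlog, config$baseline_sdlog)
  baseline <- c(rep(sig_base, 5L),
                rlnorm(config$n_genes - 5L * n_sig,
                       config$baseline_meanlog, config$baseline_sdlog))

  mu <- matrix(rep(baseline, each = n_tot), nrow = n_tot)
  cyc <- which(gene_phase != "none")
  for (j in cyc) {
    mu[, j] <- mu[, j] * .program_factor(theta, peak[j],
                                         config$program_amplitude,
                                         config$program_width)
  }
  dip <- groups == "diploid"
  mu[dip, ] <- mu[dip, ] * config$dosage_factor

  if (!is.null(config$deviations) && nrow(config$deviations)) {
    for (k in seq_len(nrow(config$deviations))) {
      dv <- config$deviations[k, ]
      j <- match(dv$gene, gene_ids)
      if (is.na(j)) stop("config error: unknown gene in deviations: ", dv$gene)
      rows <- dip & phases[ph_idx] == dv$stage
      mu[rows, j] <- mu[rows, j] * 2^dv$log2_offset
    }
  }

  if (config$nb_dispersion < 1e-8) {
    counts <- rpois(length(mu), mu)
  } else {
    counts <- rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu)
  }
  if (config$dropout_rate > 0) {
    counts <- rbinom(length(counts), counts, 1 - config$dropout_rate)
  }
  counts <- matrix(counts, nrow = n_tot,
                   dimnames = list(sprintf("cell%05d", seq_len(n_tot)),
                                   gene_ids))

  meta <- data.frame(cell_id = rownames(counts), group = groups,
                     true_phase = phases[ph_idx], theta = theta,
                     stringsAsFactors = FALSE)
  truth <- list(
    cells = meta,
    genes = data.frame(gene_id = gene_ids, phase = gene_phase,
                       baseline = baseline, peak_angle = peak,
                       stringsAsFactors = FALSE),
    deviations = config$deviations)
  list(matrix = count_matrix(counts, meta), truth = truth)
}

#' Simulate a bulk count table with ERCC spike-in rows
#'
#' Gene rows plus ERCC spike-in rows whose true abundance is identical across
#' samples; a per-sample depth factor multiplies every row, and an optional
#' per-sample biological scale multiplies gene rows only. Deterministic by
#' default (expected counts) so spike-in normalization can be checked in
#' closed form; set `poisson_noise = TRUE` for counting noise.
#'
#' @param config A [sim_config()]; `n_ercc` must be >= 1.
#' @param depth_factors Numeric vector of per-sample sequencing depths.
#' @param sample_scales Per-sample biological scale applied to gene rows only
#'   (e.g. `c(1, 2)` for a haploid/diploid pair); default all 1.
#' @param poisson_noise Draw Poisson counts around the expectations.
#' @return List: `table` (genes + ERCC rows x samples numeric matrix; ERCC
#'   row names start with "ERCC-"), `truth` (per-gene true abundances and the
#'   factors used).
#' @export
simulate_bulk <- function(config, depth_factors = c(1, 1),
                          sample_scales = rep(1, length(depth_factors)),
                          poisson_noise = FALSE) {
  validate_sim_config(config)
  if (config$n_ercc < 1) stop("config error: simulate_bulk needs n_ercc >= 1")
  if (length(sample_scales) != length(depth_factors))
    stop("config error: sample_scales and depth_factors lengths differ")
  set.seed(.derive_seed(config$seed, "simulate_bulk"))
  n_s <- length(depth_factors)
  gene_true <- rlnorm(config$n_genes, config$baseline_meanlog + log(100),
                      config$baseline_sdlog)
  ercc_true <- rlnorm(config$n_ercc, config$ercc_meanlog, 1)
  genes <- outer(gene_true, sample_scales) %*% diag(depth_factors, n_s)
  ercc <- outer(ercc_true, rep(1, n_s)) %*% diag(depth_factors, n_s)
  tab <- rbind(genes, ercc)
  if (poisson_noise) tab <- matrix(rpois(length(tab), tab), nrow = nrow(tab))
  dimnames(tab) <- list(c(sprintf("g%04d", seq_len(config$n_genes)),
                          sprintf("ERCC-%05d", seq_len(config$n_ercc))),
                        sprintf("sample%d", seq_len(n_s)))
  list(table = tab,
       truth = list(gene_true = gene_true, ercc_true = ercc_true,
                    depth_factors = depth_factors,
                    sample_scales = sample_scales))
}

#' Simulate a CRISPR knockout screen guide count table
#'
#' Genes x guides-per-gene plus non-targeting controls, with three samples:
#' `input`, `haploid_end`, `diploid_end`. Planted haploid-essential genes
#' have every guide's expected abundance multiplied by `2^-depletion_log2`
#' in the haploid endpoint only; counts are Poisson around per-guide
#' log-normal baselines scaled to the configured depth.
#'
#' @param config A [sim_config()]; see the `screen` field.
#' @return List: `table` (data.frame guide, gene, input, haploid_end,
#'   diploid_end; controls have gene == "control"), `essential_genes`
#'   (character, the planted set).
#' @export
simulate_screen <- function(config) {
  validate_sim_config(config)
  sc <- config$screen
  set.seed(.derive_seed(config$seed, "simulate_screen"))
  genes <- sprintf("sg_gene%04d", seq_len(sc$n_genes))
  essential <- sample(genes, sc$n_essential)
  gene_col <- c(rep(genes, each = sc$guides_per_gene),
                rep("control", sc$n_controls))
  n_guides <- length(gene_col)
  guide_id <- sprintf("guide%05d", seq_len(n_guides))
  base <- rlnorm(n_guides, 0, sc$guide_sdlog) * sc$depth
  mult <- ifelse(gene_col %in% essential, 2^(-sc$depletion_log2), 1)
  tab <- data.frame(
    guide = guide_id, gene = gene_col,
    input = rpois(n_guides, base),
    haploid_end = rpois(n_guides, base * mult),
    diploid_end = rpois(n_guides, base),
    stringsAsFactors = FALSE)
  list(table = tab, essential_genes = sort(essential))
}

#' Simulate DNA-damage focus fields for two ploidy groups
#'
#' Per-cell DAPI intensity is drawn from a two-mode (2N-like / 4N-like)
#' mixture scaled by ploidy (haploid DNA content 1 or 2, diploid 2 or 4).
#' gamma-H2AX focus counts are Poisson with mean damage_rate x DNA content;
#' a configured fraction of gamma-H2AX foci receive a RAD51 partner within
#' the matching radius, and background RAD51 foci fall uniformly in the
#' field.
#'
#' @param config A [sim_config()]; see the `foci` field.
#' @return List of class `FociTable`: `cells` (cell_id, group, replicate,
#'   dapi_intensity, true_content) and `foci` (cell_id, channel in
#'   {"gH2AX","RAD51"}, x, y).
#' @export
simulate_foci <- function(config) {
  validate_sim_config(config)
  fc <- config$foci
  set.seed(.derive_seed(config$seed, "simulate_foci"))
  cells <- expand.grid(i = seq_len(fc$n_cells),
                       group = c("haploid", "diploid"),
                       replicate = seq_len(fc$n_replicates),
                       stringsAsFactors = FALSE)
  n <- nrow(cells)
  cells$cell_id <- sprintf("fc%05d", seq_len(n))
  base_content <- ifelse(cells$group == "haploid", 1, 2)
  g2 <- runif(n) < fc$g2_fraction
  content <- base_content * ifelse(g2, 2, 1)
  cells$true_content <- content
  cells$dapi_intensity <- content * rlnorm(n, 0, fc$dapi_cv)

  # colocalization fraction: scalar, or named by group; an optional
  # `coloc_fraction_high` (named by group) overrides it in 4N-like cells,
  # modelling a G2/M-specific recruitment difference
  frac_of <- function(i) {
    f <- fc$coloc_fraction
    f <- if (length(f) > 1L) unname(f[cells$group[i]]) else f
    if (!is.null(fc$coloc_fraction_high) && g2[i]) {
      fh <- fc$coloc_fraction_high
      f <- if (length(fh) > 1L) unname(fh[cells$group[i]]) else fh
    }
    f
  }

  n_g <- rpois(n, fc$damage_rate * content)
  n_bg <- rpois(n, fc$rad51_background)
  foci <- vector("list", n)
  for (i in seq_len(n)) {
    gx <- runif(n_g[i], 0, fc$field_size)
    gy <- runif(n_g[i], 0, fc$field_size)
    paired <- runif(n_g[i]) < frac_of(i)
    ang <- runif(sum(paired), 0, 2 * pi)
    rad <- runif(sum(paired), 0, 0.8 * fc$match_radius)
    rx <- c(gx[paired] + rad * cos(ang), runif(n_bg[i], 0, fc$field_size))
    ry <- c(gy[paired] + rad * sin(ang), runif(n_bg[i], 0, fc$field_size))
    if (n_g[i] + length(rx) == 0L) next
    foci[[i]] <- data.frame(
      cell_id = cells$cell_id[i],
      channel = c(rep("gH2AX", n_g[i]), rep("RAD51", length(rx))),
      x = c(gx, rx), y = c(gy, ry), stringsAsFactors = FALSE)
  }
  out <- list(cells = cells[, c("cell_id", "group", "replicate",
                                "dapi_intensity", "true_content")],
              foci = do.call(rbind, foci))
  rownames(out$cells) <- NULL
  class(out) <- "FociTable"
  out
}
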