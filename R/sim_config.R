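#' Simulation configuration
#'
#' Builds the configuration object consumed by all `simulate_*` generators.
#' Defaults describe the study conditions the pipeline is designed for: two
#' populations (near-haploid and diploidized) at a 2:1 per-cell transcript
#' dosage, cyclic five-phase expression programs, negative-binomial counting
#' noise with dropout, and a longer G2/M dwell in the near-haploid group.
#'
#' @param n_cells_per_group Cells per group (default 2000).
#' @param n_genes Total genes (default 1000); the first
#'   `5 * n_signature_genes_per_phase` are cyclic phase-program genes.
#' @param n_signature_genes_per_phase Cyclic genes per phase (default 40).
#' @param dosage_factor Diploid per-cell transcript scale relative to haploid
#'   (default 2, the pure genome-doubling expectation).
#' @param dwell_fractions Named list with `haploid` and `diploid` numeric
#'   vectors over [cc_phases()], each summing to 1. Defaults give the haploid
#'   group a larger combined G2 + G2/M fraction.
#' @param program_amplitude Fold-elevation of a phase gene at its peak angle
#'   relative to its trough (default 3).
#' @param program_width Cosine-bump sharpness exponent (default 6, giving a
#'   program full-width at half maximum of about one phase arc); larger
#'   values concentrate a gene's program in its own phase arc.
#' @param nb_dispersion Negative-binomial dispersion (1/size); values below
#'   1e-8 switch to the Poisson limit. Default 0.5.
#' @param dropout_rate Independent Bernoulli thinning probability per count
#'   (default 0.1).
#' @param deviations Optional data.frame(`gene`, `stage`, `log2_offset`)
#'   of planted stage-specific dosage deviations, applied multiplicatively
#'   (2^offset) to the diploid group only, in the named stage. Default empty.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline mean expression (defaults log(2), 1: roughly 3000-7000 total
#'   UMIs per cell at the default gene count, typical of droplet scRNA-seq).
#' @param n_ercc,ercc_meanlog Bulk simulation: number of ERCC spike-in rows
#'   (default 20) and log-mean of their fixed abundances.
#' @param screen Named list of screen-simulation settings: `n_genes`,
#'   `guides_per_gene`, `n_controls`, `n_essential`, `depletion_log2` (the d
#'   in 2^-d applied to the haploid endpoint), `depth` (mean reads/guide),
#'   `guide_sdlog` (guide-efficiency spread).
#' @param foci Named list of focus-simulation settings: `n_cells` per group
#'   per replicate, `n_replicates`, `damage_rate` (mean gH2AX foci per unit
#'   DNA content), `g2_fraction` (weight of the 4N-like DAPI mode),
#'   `coloc_fraction` (fraction of gH2AX foci paired with a RAD51 focus
#'   within `match_radius`), `rad51_background` (mean unpaired RAD51 foci),
#'   `field_size`, `match_radius`, `dapi_cv`.
#' @param seed Integer seed; each `simulate_*` call derives its own stream
#'   from it so the generators are independently reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_group = 2000,
                       n_genes = 1000,
                       n_signature_genes_per_phase = 40,
                       dosage_factor = 2,
                       dwell_fractions = list(
                         haploid = c(G1S = 0.25, S = 0.20, G2 = 0.20,
                                     G2M = 0.25, MG1 = 0.10),
                         diploid = c(G1S = 0.30, S = 0.25, G2 = 0.15,
                                     G2M = 0.15, MG1 = 0.15)),
                       program_amplitude = 3,
                       program_width = 6,
                       nb_dispersion = 0.5,
                       dropout_rate = 0.1,
                       deviations = NULL,
                       baseline_meanlog = log(2),
                       baseline_sdlog = 1,
                       n_ercc = 20,
                       ercc_meanlog = log(50),
                       screen = list(n_genes = 200, guides_per_gene = 4,
                                     n_controls = 100, n_essential = 20,
                                     depletion_log2 = 2, depth = 500,
                                     guide_sdlog = 0.2),
                       foci = list(n_cells = 300, n_replicates = 3,
                                   damage_rate = 3, g2_fraction = 0.3,
                                   coloc_fraction = 0.5,
                                   rad51_background = 2, field_size = 50,
                                   match_radius = 0.5, dapi_cv = 0.1),
                       seed = 1L) {
  cfg <- list(n_cells_per_group = n_cells_per_group, n_genes = n_genes,
              n_signature_genes_per_phase = n_signature_genes_per_phase,
              dosage_factor = dosage_factor,
              dwell_fractions = dwell_fractions,
              program_amplitude = program_amplitude,
              program_width = program_width,
              nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
              deviations = deviations,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              n_ercc = n_ercc, ercc_meanlog = ercc_meanlog,
              screen = screen, foci = foci, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object (or plain list with the same fields).
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_cells_per_group, cfg$n_genes,
              cfg$n_signature_genes_per_phase)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("config error: cell/gene counts must be positive integers")
  if (!is.numeric(cfg$dosage_factor) || cfg$dosage_factor <= 0)
    stop("config error: dosage_factor must be > 0")
  if (5 * cfg$n_signature_genes_per_phase > cfg$n_genes)
    stop("config error: more signature genes than genes")
  for (g in names(cfg$dwell_fractions)) {
    dw <- cfg$dwell_fractions[[g]]
    if (!setequal(names(dw), cc_phases()))
      stop("config error: dwell fractions must be named by the five phases")
    if (abs(sum(dw) - 1) > 1e-9)
      stop(sprintf("config error: dwell fractions for '%s' sum to %.10f, not 1",
                   g, sum(dw)))
    if (any(dw < 0)) stop("config error: negative dwell fraction")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stop("config error: dropout_rate must be in [0, 1]")
  if (cfg$nb_dispersion < 0)
    stop("config error: nb_dispersion must be >= 0")
  if (cfg$program_amplitude <= 0)
    stop("config error: program_amplitude must be > 0")
  if (!is.null(cfg$deviations)) {
    dv <- cfg$deviations
    if (!all(c("gene", "stage", "log2_offset") %in% names(dv)))
      stop("config error: deviations needs gene, stage, log2_offset columns")
    if (!all(dv$stage %in% cc_phases()))
      stop("config error: unknown stage in deviations")
  }
  if (cfg$n_ercc < 0) stop("config error: n_ercc must be >= 0")
  invisible(cfg)
}

#' Write a simulation configuration to a YAML file
#' @param cfg A `sim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$dwell_fractions <- lapply(x$dwell_fractions, as.list)
  if (!is.null(x$deviations)) x$deviations <- as.list(x$deviations)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#' @param path File written by [write_sim_config()].
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$dwell_fractions <- lapply(x$dwell_fractions, unlist)
  if (!is.null(x$deviations)) x$deviations <- as.data.frame(x$deviations)
  do.call(sim_config, x)
}
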