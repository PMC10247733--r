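# hapcycle

Cell-cycle-resolved dosage analysis of near-haploid and diploidized
leukemia cells.

## The problem

Near-haploid leukemias (karyotypes with one copy of most autosomes, as in
the KBM7 cell line and near-haploid B-ALL) can spontaneously double their
genome, yielding a "masked" diploid counterpart with the same relative
karyotype at twice the DNA content. Under pure genome doubling, every
gene's expression should follow the DNA dosage: the diploid:haploid
expression ratio is expected to be **2:1** (log2 ratio = 1) for every gene
in every cell-cycle phase. Genes that deviate from this expectation in a
*stage-specific* way — for instance DNA-damage-repair genes over-expressed
by haploid cells in G2/M — point at ploidy-specific biology and potential
ploidy-specific vulnerabilities.

`hapcycle` implements the computational workflow needed to find such
deviations and their consequences:

- **Phase assignment** — five metagene scores (G1S, S, G2, G2M, MG1) from
  filtered phase signatures (genes detected in ≥ 5% of cells and
  correlated r ≥ 0.5 with the signature mean); each cell is assigned the
  arg-max phase.
- **Cell-cycle pseudo-time** — an ellipse is fitted (direct least-squares
  conic fit) to the cells in the (G1S, G2M) score plane; expression is
  smoothed along the manifold with a rolling circle of radius 0.5 and 95%
  CI bands (1.96 × SEM).
- **Graph-diffusion imputation** — a kNN Markov matrix over cells
  (adaptive Gaussian kernel in PCA space), powered `t` times (default
  t = 3) and applied to normalized expression before correlation-based
  analyses.
- **Stage-specific dosage analysis** — per-stage diploid:haploid ratios on
  absolute-scale expression (the 2:1 structure is deliberately preserved),
  Wilcoxon rank-sum tests on per-cell-normalized expression (sensitive to
  deviations from dosage, not to dosage itself), BH q-values, and a census
  of genes below a log2 cutoff of 0.5 (~1.4-fold in linear space, versus
  the 2-fold expectation).
- **Supporting modules** — ERCC top-5 spike-in normalization for bulk
  tables, anchor-gene co-expression signatures with hypergeometric overlap
  tests, CRISPR screen depletion calls with ploidy-specific intersection
  logic, γ-H2AX/RAD51 focus colocalization statistics with DAPI-based
  cell-cycle binning, and growth-kinetics utilities (doubling times, stage
  durations, competition fitness).
- **Synthetic data** — `simulate_cells()`, `simulate_bulk()`,
  `simulate_screen()` and `simulate_foci()` generate every input the
  pipeline consumes with known ground truth (configurable dosage factor,
  ploidy-specific phase dwell, NB noise and dropout, planted essentials,
  planted dosage deviations, set colocalization fractions), so the whole
  workflow is testable without external data.

## Worked example

```r
library(hapcycle)

cfg <- sim_config(n_cells_per_group = 500, n_genes = 500, seed = 7)
sim <- simulate_cells(cfg)
res <- run_pipeline(sim, n_anchors = 90)

sprintf("Global diploid:haploid expression ratio: %.3f",
        res$global_dosage_ratio)
#> "Global diploid:haploid expression ratio: 1.996"

subset(res$proportions, phase != "unassigned")
#>    group phase   n fraction
#>  haploid   G1S 125    0.250
#>  haploid     S 115    0.230
#>  haploid    G2  93    0.186
#>  haploid   G2M 113    0.226
#>  haploid   MG1  54    0.108
#>  diploid   G1S 140    0.280
#>  diploid     S 121    0.242
#>  diploid    G2  90    0.180
#>  diploid   G2M  73    0.146
#>  diploid   MG1  76    0.152

res$census$linear_cutoff_rounded
#> 1.4

res$ellipses$haploid
#> EllipseModel: center (0.1704, 0.3655), semi-axes a=1.692 b=1.117, phi=2.24 rad
```

The recovered global ratio (1.996) matches the generating 2:1 dosage; the
per-group phase proportions recover the configured dwell structure (the
haploid group spends more of the cycle in G2 + G2/M: 0.41 vs 0.33 here);
the census reports the linear-space equivalent of the default log2 cutoff
(1.4); and the fitted ellipse is the cell-cycle manifold used for
pseudo-time smoothing. On this clean simulation, phase assignment agrees
with the generator's ground-truth labels for ~90% of cells.

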