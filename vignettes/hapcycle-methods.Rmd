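---
title: "Methods: cell-cycle-resolved dosage analysis in hapcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle-resolved dosage analysis in hapcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, defaults and numerical choices behind
`hapcycle`, in the order data flows through the pipeline. It is the place
where design decisions that were genuinely open are recorded, together
with their rationale.

## The dosage model

A near-haploid cell and its genome-doubled ("diploidized") counterpart
share the same relative karyotype at twice the DNA content. The null
model throughout the package is *pure dosage*: every gene's expected
expression scales with copy number, so the diploid:haploid expression
ratio is 2:1 (log2 = 1) globally and per gene. All statistics are built
to either (a) recover that global structure, or (b) detect genes whose
ratio deviates from it in specific cell-cycle stages.

Two scales matter and are kept deliberately distinct:

* **absolute scale** — per-cell totals retain the dosage; group mean
  ratios computed here have the 2:1 expectation. Per-cell normalization
  would erase the package's central quantity, so ratio tables and the
  cutoff census always use absolute-scale values (raw counts or imputed
  values mapped back through the inverse of the per-cell scaling,
  `descale_imputed()`).
* **normalized scale** — per-cell library normalization removes the
  global dosage; what remains are deviations from it. The per-gene
  Wilcoxon rank-sum tests in `stage_ratios()` run on this scale, so the
  q-values answer "does this gene deviate from the 2:1 expectation in
  this stage?" rather than the trivial "is diploid expression higher?".
  This mirrors standard single-cell differential-expression practice,
  which operates on library-normalized data.

## The synthetic-data generator

`simulate_cells()` draws the conditions the pipeline is designed for; the
defaults in `sim_config()` are the package's statement of those study
conditions and are not tuned per analysis.

**Cell-cycle geometry.** The circle is partitioned into five *fixed*
equal arcs in cycle order G1S → S → G2 → G2M → MG1. A cell's phase is
sampled from its group's dwell fractions, then its angular position
$\theta$ is uniform within that phase's arc. Keeping the arcs fixed
across groups (with dwell expressed as occupancy density rather than arc
width) means phase intervals, gene peak positions and the ground-truth
invariant "the phase label is the arc containing $\theta$" are common to
both groups.

**Dwell fractions.** Published evidence for this system is figure-level
only (a larger G2/M compartment in near-haploid cells), so the defaults
are qualitative choices, not measured values: haploid
(G1S .25, S .20, G2 .20, G2M .25, MG1 .10), diploid
(.30, .25, .15, .15, .15). Haploid G2+G2M = .45 versus diploid .30.

**Phase programs.** A phase gene's expression follows a cosine-power bump
$b(\theta) = ((1+\cos(\theta-\text{peak}))/2)^w$ peaking at its phase-arc
center. The default sharpness $w = 6$ gives a full width at half maximum
of roughly one arc (~77°), i.e. a program that is concentrated in its own
phase but overlaps its neighbours, as cyclic transcriptional programs do.
The program factor is normalized to unit mean over the circle, and the
baselines of the cyclic genes are *matched across the five phase
programs* (one log-normal draw reused per phase rank). Together these
make total expression exactly dwell-independent in expectation, so the
global diploid:haploid ratio of mean per-cell totals equals the
configured `dosage_factor` — no hidden interaction between dwell
asymmetry and the dosage recovery.

**Noise.** Counts are negative-binomial around the per-cell/per-gene mean
(`nb_dispersion` = 1/size, default 0.5; below 1e-8 the Poisson limit is
used), followed by independent Bernoulli dropout (default 0.1) — the
simplest noise model sufficient to exercise imputation. Baselines are
log-normal with `meanlog = log(2)`, giving ~3000–7000 total UMIs per cell
at the default 1000 genes, typical of droplet scRNA-seq.

**Planted deviations.** `deviations` multiplies the diploid group's mean
by $2^{\text{offset}}$ for the named genes only in the named stage,
enabling stage-specific recovery tests; the default set is empty.

**Other generators.** `simulate_bulk()` is deterministic by default
(expected counts) so spike-in normalization can be verified in closed
form; ERCC rows have identical true abundance across samples.
`simulate_screen()` plants haploid-essential genes whose guides are
depleted $2^{-d}$ (default d = 2) in the haploid endpoint only, at a mean
depth of 500 reads/guide with log-normal guide-efficiency spread.
`simulate_foci()` draws DAPI intensity from a two-mode (2N-like/4N-like)
mixture scaled by ploidy, gamma-H2AX counts as Poisson in DNA content,
and pairs a configured fraction of them with a RAD51 focus inside the
matching radius; the fraction may differ by group and, via
`coloc_fraction_high`, specifically in 4N-like cells.

Each `simulate_*` call derives its own RNG stream from the single
user-facing seed, so generators are individually reproducible and adding
one does not perturb the others.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: batch effects, doublets, ambient RNA,
hashtag demultiplexing, UMI saturation, transcriptional bursting beyond
NB dispersion, chromosome-level structure (deviations are planted per
gene, not per chromosome), and cluster structure beyond the cell-cycle
manifold.

## Imputation

`build_markov()` follows the standard diffusion recipe for single-cell
data: Euclidean kNN (default k = 30) in top-PC space (default 20
components), Gaussian kernel with per-cell adaptive bandwidth set to the
distance to the ka-th neighbour (default 10), symmetrization
(A + Aᵀ)/2, and row normalization. `impute_expression()` applies
$M^t X$; the diffusion time is a surfaced parameter with per-dataset
defaults of 3 (KBM7-style) and 7 (PDX-style). PCA is computed by eigen
decomposition of the smaller Gram/covariance matrix, which is exact and
fast at these sizes. The original diffusion-imputation tool's exact
output is a non-goal; the contract is the row-stochastic matrix-power
semantics, which the tests pin against explicit matrix multiplication.

A caveat discovered during validation and worth knowing: diffusion
averages over neighbourhoods on the cell-cycle manifold, so *stage-local*
signals are diluted — a −0.5 log2 deviation planted only in G2/M cells
shrinks to roughly −0.1 after t = 3 smoothing. Imputed values are
therefore used where correlation structure matters (signature filtering,
phase scores, co-expression signatures), while stage-specific
deviation testing is run on raw counts (the documented raw mode of
`stage_ratios()`).

## Phase scoring

Signatures are filtered per the detection rule (raw UMI > 0 in ≥ 5% of
cells) and the correlation rule (Pearson r ≥ 0.5 with the mean imputed
expression of the detection-passing members, computed once). When group
labels are given the filter runs within each group and keeps genes
passing in either — the permissive choice for a mixed-ploidy dataset.

Scores are means of z-scored imputed expression over each signature; the
z-scoring prevents high-abundance genes from dominating and makes the
(G1S, G2M) score plane comparable between groups. Raw-mean scoring is
available (`standardize = FALSE`). The assigned phase is the arg-max
score; exact ties give `"unassigned"` rather than an order-dependent
pick, so downstream proportions are not biased by column order.

## Pseudo-time

The manifold is an ellipse fitted to the (G1S, G2M) score pairs by the
direct least-squares conic method with the ellipse-discriminant
constraint (the numerically stable partitioned formulation), then
converted to center, semi-axes and rotation. Fits are per group by
default (a joint fit is just a concatenated input). `project_angle()`
minimizes Euclidean distance over the parametric angle with a 512-point
grid plus bounded refinement.

`rolling_profile()` averages expression over cells within a fixed-radius
disk (default radius 0.5, interpreted in the z-scored score units; the
value is configurable because any score rescaling changes its meaning)
centred at anchors on a uniform parametric grid (default 360; the grid
density is a resolution choice, not a statistical one). Windows use the
full cell set, not phase-restricted subsets. Empty windows are missing,
never zero; SEM (and hence the 1.96·SEM CI) is defined only for windows
with ≥ 2 cells — no fabricated precision. Orientation is decided by a
majority vote of assigned phases along the grid (circular means per
phase must advance in cycle order; otherwise the grid is flipped), and
the origin is anchored at the angle of maximal smoothed G1S score, so
pseudo-time always starts at the G1/S transition and runs forward.

## Dosage ratios, DE and the census

`stage_ratios()` restricts to cells assigned to one stage (≥ 20 per
group), reports absolute-scale means and log2 ratios (finite only when
both means are positive; zero-mean genes are excluded from ratios and
counted separately), and tests per-gene deviation on per-cell-normalized
values with the package's Wilcoxon implementation: exact enumeration of
the permutation distribution (tie-aware, by dynamic programming over the
rank multiset) when both groups have ≤ 25 observations, otherwise the
tie-corrected normal approximation with continuity correction. BH
correction is applied within stage (the per-stage gene family is the
natural unit here; the correction family was an open choice). A gene is
flagged DE at q < 0.01 with normalized fold change > 1.25, matching the
workflow's thresholds.

`cutoff_census()` counts genes below the log2 cutoff (default 0.5, i.e.
~1.4-fold linear versus the 2-fold expectation) per stage and emits ECDF
coordinates for plotting.

Power note: single-gene detection power depends strongly on expression
level; at the default depth, genes with stage means below ~2 UMI sit in
the zero-inflated regime where rank tests lose power. The acceptance
check therefore evaluates planted-deviation power over adequately
expressed targets (stage mean ≥ 2 in the haploid group), the same spirit
as the detection filters any single-cell DE method applies.

## Signatures, screens, foci, kinetics

*Co-expression signatures* include every nonzero-variance gene with
r ≥ 0.5 against the anchor, plus the anchor itself (r(anchor, anchor) = 1).
The overlap test is the upper-tail hypergeometric probability; the
universe defaults to the genes surviving the nonzero-variance filter in
the dataset where both sets were defined — the universe choice is
configurable because published overlap p-values rarely state theirs.

*Screen calls* use a deterministic, testable depletion rule: per-guide
log2 fold change on counts-per-million with pseudocount 1 (zero-count
guides are expected after ~20 doublings of depletion; fixed-total scaling
makes calls invariant to uniform depth rescaling), gene score = median
guide log2FC, essential iff the score and at least 2 individual guides
fall strictly below a threshold set at the 5th percentile of
non-targeting-control log2FCs. The intersection for ploidy-specific
essentials is pure set algebra with per-gene provenance: essential in
every haploid screen, in no diploid screen, absent from the panel-wide
common-essential list, present in the stage-overexpressed set.

*Foci* are binned by within-group DAPI quantiles (defaults 0.3/0.7;
low→G1/S, medium→S, high→G2/M) — quantile cuts are deterministic, unlike
mixture-peak calling. "Occupancy" is centroid distance ≤ `match_radius`
(default 0.5 image units); occupancy fractions are per-cell, averaged
over cells with at least one focus of the relevant channel. Ratios are
per replicate (ratio of mean counts) with a two-sided one-sample
Student's t-test against the dosage expectation of 2; between-group
comparisons are two-sided equal-variance two-sample t-tests. A zero
variance across replicate ratios leaves the test undefined (reported as
NA), and a zero denominator mean is an error, not an Inf.

*Kinetics*: doubling time is 1/slope of least-squares log2(count) vs
time per replicate. Stage durations default to proportional allocation
(duration = proportion × doubling time — consistent with the simple
arithmetic this kind of analysis reports); the exponential-age-structure
correction (inverting the steady-state age density, under which young
cells are over-represented) is provided but never applied silently.
Competition fitness is the slope of log2 marked:unmarked ratio,
normalized to the first time point, per doubling.

## Problem sizes in the test suite

The suite favours sizes that exercise each property well: oracle
equivalence on 6–80-cell instances (exact), generator invariants at
5000 cells/group (2 SE bands), phase recovery at 400–800 cells/group
with 500 genes, deviation power at the default 2000 cells/group, null
calibration with 200 genes and 1000 replicate t-tests. The full suite
runs in well under a minute on one CPU.

## Known limitations

* The ellipse is a 2-D manifold in one fixed score plane; no general
  principal-curve fitting.
* The rolling radius of 0.5 is meaningful only in z-scored score units.
* Diffusion imputation dilutes stage-local effects (see above); raw-mode
  analyses exist for exactly that reason.
* Screen scoring is a deliberate simplification: a median-guide
  depletion score with a control-derived threshold, not a full
  guide-level statistical model.
* Focus colocalization is centroid-based; pixel-mask overlap and 3-D
  foci are out of scope, as are image segmentation and focus detection.
* DAPI bin boundaries are quantile conventions, not inferred DNA-content
  peaks.
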