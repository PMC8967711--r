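---
title: "Methods: fate mapping and cross-species taxonomy of developing inhibitory neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fate mapping and cross-species taxonomy of developing inhibitory neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatelink)
```

# The problem

Inhibitory neurons of the mammalian telencephalon are produced in transient
germinal zones (the medial, lateral and caudal ganglionic eminences and the
ventromedial forebrain) as a small number of discrete transcriptional
"initial classes" of new-born neurons, each largely defined by the
regional transcription-factor program active at the final cell division.
Relating those developmental classes to annotated adult ("terminal")
populations, and comparing them between species, requires a chain of
computational steps: droplet quality control, selection of the inhibitory
lineage, batch-aware embedding and clustering, an ordering of cells along
differentiation (latent time) derived from RNA velocity, an absorbing
Markov-chain model that assigns developing cells to terminal classes,
cross-species homology via mutual nearest neighbours (MNN) and class-mean
correlation, and a regression screen for genes that activate or
inactivate along each trajectory.

`fatelink` implements this chain as composable, tidyverse-style functions
plus a pipeline driver (`run_pipeline()`), and ships a synthetic
two-species generator with full ground truth so that every stage can be
validated quantitatively. All tabular results are tibbles; fitted objects
have `tidy()`, `glance()` and `autoplot()` methods.

# The synthetic study design

The paper-scale datasets this kind of analysis is normally applied to are
sequencing studies with manual curation; they cannot be regenerated at
desk scale. The generator (`generate_dataset()`) therefore *emulates the
structure the methods assume* and makes every hidden variable observable:

* **Branches.** Each inhibitory initial class is one differentiation
  branch; cells receive a latent time drawn uniformly on $[0, 1]$
  (uniform placement avoids artefactual density modes). Four classes are
  shared between the two species; one (an analogue of the primate-specific
  MGE_CRABP1/TAC3 population) exists only in species A and co-expresses
  the identity program of a designated sister class
  (MGE_CRABP1/MAF-analogue) plus a disjoint marker set — mirroring how a
  novel class can arise by individuation from an ancestral one. One
  excitatory outgroup branch (GAD/DLX markers at leak level) exercises
  the inhibitory-selection rule.
* **Gene programs.** Per branch: constitutive identity transcription
  factors (on for the whole branch — initial classes are specified at
  birth), a shared progenitor program that switches off at $t = 0.15$
  (the "inactivated" truth set), class-specific genes switching on at
  $t = 0.35$ ("activated"), GAD/DLX-analogue markers in all inhibitory
  branches, mitochondrial/ribosomal genes (for QC fractions), and a large
  housekeeping background.
* **Kinetics.** Every gene follows the standard two-state transcription
  model ($u' = \alpha(t) - \beta u$, $s' = \beta u - \gamma s$, with
  $\alpha$ switching between an on rate and a 2% leak). Expected values
  use the closed-form ODE solution (`expected_expression()`, verified in
  the tests against an independent `deSolve` integration). At steady
  state $u/s = \gamma/\beta$, the slope the velocity estimator recovers.
  Defaults: $\beta = 8$, $\gamma \sim U(5, 7.5)$ per gene (kept away from
  $\beta$ and fast enough that a 0.65-time-unit on-phase approaches
  steady state), in units of inverse latent time.
* **Noise.** Observed counts are negative-binomial (size 10) around
  library-scaled expectations with log-normal per-cell library sizes
  (mean 8,000 spliced UMIs; unspliced libraries 25% of spliced) —
  the standard overdispersion model for UMI data. Transcription-rate
  budgets were chosen so healthy cells detect well over 1,000 of the
  1,500 genes and show ~5% mitochondrial and ~20% ribosomal reads,
  leaving wide margins to the QC thresholds.
* **Planted artifacts.** `plant_qc_artifacts()` corrupts a configurable
  fraction of cells (8% by default) so each decisively violates one
  droplet threshold: most genes zeroed (≈250 detected), mitochondrial
  reads inflated to ≈45%, or ribosomal reads to ≈65%.
* **Terminal extensions.** Species A carries "adult" cells per
  inhibitory class at latent time $[0.92, 1]$, used as absorbing states.
* **Orthologues.** A one-to-one table is emitted with a 10% dropout to
  exercise the orthologue restriction; species-B genes carry a `B.`
  prefix.

What the generator does **not** emulate: ambient RNA, doublets (the tools
that handle these are external and out of scope), discrete cell-cycle
structure, spatially graded expression within a class, and between-batch
shifts beyond random assignment. Passing the bundled recovery checks
therefore demonstrates correctness of the algorithms under a favourable,
fully specified data-generating process — not performance on real tissue.

# Stage-by-stage method notes

## Quality control

`filter_cells()` applies the droplet rules with strict inequalities read
literally: removal when *fewer than* 800 genes are detected or *more
than* 40% ribosomal or 15% mitochondrial reads (and, when an upstream
per-droplet cell-probability column exists, probability ≤ 0.99). Detection
is counted on the spliced matrix; fraction denominators are total spliced
counts. A cell exactly at a boundary is retained. Filtering is idempotent
and reasons are recorded per cell (a cell may fail several).

`select_inhibitory_clusters()` removes a cluster when its mean normalized
expression falls strictly below the dataset-wide mean (over all cells —
the most common reading; the rule's family, "the mean", is not otherwise
pinned down) for at least two of GAD1, GAD2, DLX1, DLX2, DLX5, DLX6.
Removal applies only to cells in non-exempt batches, so ganglionic-
eminence dissections can be protected; the per-gene comparisons are
returned for every cluster.

## Embedding and classes

Depth normalization uses the median of per-cell totals as the target sum
(the natural choice when only "normalized by read depth" is fixed),
followed by log1p and per-gene standardization with values clipped at
±10 to bound outlier leverage. Highly variable genes use the classic
dispersion flavour: per sample, dispersion = variance/mean on
depth-normalized values, 20 equal-frequency mean bins, z-scored within
bins; a gene is "variable in" a sample at z > 0.5 (a conventional,
configurable cutoff), and must be variable in ≥ 2 samples (relaxed with
a warning for single-sample data).

PCA is computed by an exact eigendecomposition of the smaller
cross-product (never a randomized solver): at these problem sizes the
exact factorization is cheap and removes one source of seed dependence;
signs are fixed by making the largest-magnitude loading positive.

The batch-balanced kNN graph links every cell to its `k` nearest cells
*per batch* (Euclidean distance in PC space; `k = 3` by default, the
developmental setting), so no batch can dominate a neighbourhood. Leiden
clustering (modularity objective, resolution 10) deliberately
over-partitions; cluster mean-expression vectors are then merged into
classes by complete linkage on the Pearson correlation distance
$1 - r$. The original merging step is manual and marker-guided, so no
height exists to reproduce. The automatic stand-in cuts the dendrogram at
the largest *relative* gap between consecutive merge heights (geometric
midpoint): within-class merges form a dense run of low heights and
between-class merges a sparse run of high ones, and the ratio — unlike
the absolute gap, which can fall between two spread-out between-class
merges — locates that boundary. A numeric height or an explicit
cluster-to-class map can override the cut.

## Velocity and latent time

The steady-state estimator fits, per gene, the zero-intercept slope
$\hat\gamma$ of unspliced on spliced over the extreme spliced quantiles
(bottom and top 5%), where cells are closest to equilibrium; velocity is
the residual $v = u - \hat\gamma s$. This replaces the full dynamical
transcription model (a large external contribution that the original
analysis calls as a tool): the steady-state form preserves exactly the
quantities downstream stages consume — a per-gene slope and signed
per-cell residuals — and is analytically testable against the generator.
A known limitation follows from the ODE itself: genes switched on late
(0.35) retain an induction transient at $t = 1$, biasing $\hat\gamma$
upward by up to ~20% at $\gamma = 5$; for genes whose sampled window
reaches (or returns to) steady state — constitutive genes, and repressed
genes whose both spliced tails lie on the steady-state line — recovery is
essentially exact, and that is the regime in which the recovery check is
stated.

Latent time is a root-anchored geodesic: shortest-path distance from the
root set along the distance-weighted symmetrized neighbour graph, min-max
rescaled to $[0, 1]$. It is invariant to global rescaling of the PC
coordinates. Roots default to the top 2% of cells by mean expression of
the progenitor markers, selected *per connected component* (every branch
carries its own progenitor-like cells, and a class that embeds as a
separate component would otherwise receive a constant time); with
explicit roots, unreachable cells get time 1 with a warning. New-born
neurons are cells strictly below their class's interpolated median
(quantile type 7) of latent time — a rank-based definition invariant to
monotone transforms of the time.

## Fate mapping

The transition kernel mixes, with equal weight by default, a
connectivity kernel (row-normalized symmetrized adjacency) and a velocity
kernel: for cell $i$, a softmax over neighbours $j$ of
$\cos(\delta_{ij}, v_i)$, where $\delta_{ij}$ is the PC-space
displacement and $v_i$ the velocity projected through the PCA loadings
(displacement and velocity must live in one space). The softmax
temperature self-tunes as the row median of $|\cos|$, a scheme chosen
because the cited tool documents only the cosine-softmax structure, not
its constants. Zero-velocity cells fall back to their connectivity row.

Terminal cells become absorbing states. With transient block $Q$ and
transient-to-absorbing block $R$ (aggregated by class), absorption
probabilities are the rows of $(I - Q)^{-1} R$, computed by sparse
linear solves with one right-hand side per terminal class. Transient
cells with no path to any absorbing state are flagged rather than fatal.
Because absorption probabilities are biased by class sizes, each initial
class is subsampled to at most 1,000 cells (seeded) before reporting;
for every terminal class the initial-class identities of the top 100
cells by absorption probability (ties broken by cell id) form the Sankey
edge weights, and the mean absorption per (initial, terminal) pair over
all subsampled cells gives the compositional-bias-free heatmap
(`autoplot()` on the summary).

## Cross-species homology

Species are merged on one-to-one orthologue pairs that are highly
variable in both species, after per-species standardization (so species-
level location/scale differences cancel; Pearson correlations are
invariant to such affine changes). MNN pairs are defined on cross-species
candidates only: $(a, b)$ is a pair iff each is within the other's 25
nearest cross-species neighbours in merged PC space. Class-pair MNN
counts and Pearson correlations of class mean-expression vectors over the
shared variable orthologues form the homology table. The shared-
orthologue count is data-dependent and reported per run, never asserted.

## Trajectory genes

Per class, each gene's depth-normalized log expression is regressed on
latent time by ordinary least squares (expression is *not* z-scaled:
scaling destroys the interpretability of the slope); two-tailed p-values
come from the t distribution with $n - 2$ df, with the convention
$p = 1$ for constant genes. Multiplicity is controlled by the
Holm–Šidák step-down — sorted ascending,
$q_{(i)} = \max_{j \le i}\,[1 - (1 - p_{(j)})^{m - j + 1}]$ clipped at 1 —
applied within each class (the correction family is configurable to
global; per-class matches one family per trajectory analysis). Genes with
$q < 0.05$ are "activated" or "inactivated" by slope sign, and per-class
sets are compared by Jaccard indices.

# Reproducibility and problem sizes

All randomness flows from one root seed through fixed per-stage
substreams, so a stage re-run in isolation reproduces its in-pipeline
result; the run manifest records the config snapshot, seeds, output
checksums and wall-clock per stage. The bundled validation design uses 2
species, 5 inhibitory classes (one species-specific), one excitatory
branch, 350 cells per branch, 250 terminal cells per class and 1,500
genes (~5,100 cells in total), chosen so the complete pipeline runs in
well under a minute on one CPU while keeping every per-class statistic
well-populated; the Monte-Carlo checks of the absorption solver use
200,000 walks per compared state. `inst/extdata/demo_config.yaml` is a
further-reduced configuration for quick interactive runs.

# Known limitations

* The generator's favourable structure (strong constitutive identity
  programs, clean branch geometry) makes clustering and fate recovery
  near-perfect; real tissue will not be.
* The steady-state velocity estimator inherits the transient bias noted
  above and ignores gene-specific capture efficiency differences between
  spliced and unspliced libraries.
* Geodesic latent time orders cells within a branch but has no absolute
  time calibration across disconnected components.
* The automatic dendrogram cut is a reproducible stand-in for a manual,
  marker-guided decision; for real analyses the explicit
  cluster-to-class map is the recommended path.
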