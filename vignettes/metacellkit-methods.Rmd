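---
title: "Metacell inference by kernel archetypal analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metacell inference by kernel archetypal analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Single-cell RNA and ATAC measurements are extremely sparse: a cell's profile
captures well under 10% of its transcripts and under 5% of its open chromatin.
Cells sampled from the same underlying state differ mostly by this sampling
noise. metacellkit aggregates groups of highly similar cells into *metacells*
— one group per cell state — producing count matrices dense enough for
regulatory analysis while retaining far more heterogeneity than coarse
clustering. A second-round aggregation of metacells across samples
(*meta2cells*) supports cohort-level differential-abundance analysis.

# The model

## From counts to a cell-cell kernel

1. **Normalization and embedding.** RNA counts are library-size normalized,
   log-transformed with a pseudocount of 0.1, reduced to highly variable
   genes (default 2,500 by normalized dispersion) and projected onto
   principal components (default 50). ATAC counts are TF-IDF normalized
   (`tf = count/total`, `idf = log(1 + n_cells/(1 + n_cells_with_feature))`)
   and reduced by truncated SVD (default 30 components); the first component
   is dropped when its absolute correlation with log total counts exceeds
   0.9, since it then tracks sequencing depth. The observed correlation is
   always reported rather than silently acted on.

2. **kNN graph.** An exact Euclidean k-nearest-neighbor graph in the
   embedding (default k = 50, via a kd-tree).

3. **Adaptive Gaussian kernel.** Densities vary enormously across a
   phenotypic manifold, and rare states live in its sparsest regions. A
   fixed-bandwidth kernel over- or under-smooths them; instead each cell
   gets bandwidth `sigma_i` = distance to its l-th neighbor (default
   l = 15 — a tuning knob, not a published constant), and for mutual
   neighbors

   `M_ij = exp(-0.5 * d_ij^2 / (sigma_i + sigma_j)) / sqrt(2 * pi * (sigma_i + sigma_j))`

   with `M_ij = 0` elsewhere. Mutual-neighbor support is the default
   (`kernel_support = "union"` is available); the diagonal carries the
   zero-distance value `1/sqrt(4 pi sigma_i)`, consistent with the formula.
   Bandwidths below 1e-12 (duplicate points) are replaced by the smallest
   positive bandwidth so the kernel stays finite without perturbing data.

## Kernel archetypal analysis

The kernel is decomposed as `M ~ M B A` with column-stochastic
`B (n x s)` — archetypes as convex combinations of cells — and
`A (s x n)` — cells as convex combinations of archetypes. The squared
reconstruction error `SRE = ||M - M B A||_F^2` is minimized by alternating
convex block updates; both blocks use Frank-Wolfe steps with exact line
search, so the SRE trace is non-increasing by construction. The constraint
text "entries non-zero" is implemented as the standard simplex (entries
`>= 0`, columns summing to 1).

Numerical strategy, chosen for a single-CPU budget at 10^4-10^5 cells:

* All SRE bookkeeping goes through the trace identity
  `tr(M'M) - 2 tr(A'C'M) + tr(A'HA)` with `C = MB`, `H = C'C`; the `n x n`
  reconstruction is never materialized.
* The A-subproblem separates over cells into independent simplex QPs. Each
  cell takes up to 30 *pairwise* Frank-Wolfe steps per outer iteration
  (move weight from the worst active archetype to the best one, exact line
  search clipped at the available weight), maintaining `H a_j` incrementally
  so a step costs O(s). Pairwise steps converge linearly and keep each
  cell's support small, which is also what the biology expects — a cell
  belongs to one or two archetypes.
* The B block takes a small number of Frank-Wolfe passes per outer
  iteration (chosen by a per-iteration compute budget). Each pass selects
  the vertex per archetype from the gradient, solves the small s x s system
  for jointly optimal per-column step sizes, clips them to \[0, 1\], and
  finishes with one exact global line search along the scaled direction —
  every step is therefore a descent step. The product `C = MB` is updated
  incrementally, so a pass costs two sparse-dense products and two small
  gemms.
* Convergence: stop when the relative SRE decrease is below `tol = 1e-5`
  for 3 consecutive iterations, after at least 10; `max_iter = 150`.
  Entries below 1e-12 are pruned with column renormalization, which keeps
  the stochasticity constraint exact to machine precision.

## Initialization

Random archetype seeds oversample dense regions. Initialization instead uses
max-min sampling on diffusion components of `M` (default 10 components):
per component, each new waypoint maximizes its minimum distance to the
chosen set. The first waypoint of each component is drawn at random under
the run seed; robustness across these random initializations is one of the
package's acceptance experiments, so a deterministic extremal start
(`init = "extremal"`) is available but not the default. Pooled waypoints are
de-duplicated and topped up by greedy column-subset selection on the kernel
(each step adds the column most reducing the projection residual). The
`maxmin_proportion` between the two schemes defaults to 1 — greedy selection
then only fills the de-duplication shortfall.

## Metacell construction

Metacells binarize `A`: per cell, weights below 0.05 are zeroed
(regularization), the rest renormalized, and the argmax taken (ties to the
lowest index). Raw counts are summed per metacell — totals are conserved
exactly — and normalized by total, rescaled by the median metacell total,
and log-transformed with pseudocount 0.1. The default count heuristic is
one metacell per 75 cells; rare-population protocols instead use one
metacell per rare-population-count cells. Assignment certainty is
summarized over max-weight bins [0, 0.5), [0.5, 0.8), [0.8, 0.9), [0.9, 1].

# The ATAC toolkit

* **NFR filter.** Fragments shorter than 147 bases (sub-nucleosomal) are
  retained for peak-level analysis.
* **Insertion-site counting.** A fragment hits a peak when either Tn5
  insertion site (`start` or `end - 1`; 0-based half-open) falls inside it,
  at most once per peak per fragment. With `augment = TRUE` each metacell's
  counts are pooled with its two nearest metacells (centroid distance in
  diffusion space), applied to all metacells alike to avoid bias.
* **Open-peak calls.** In-peak counts are modeled as Poisson with
  `lambda = 500 * total_fragments / (n_peaks * 5000)` — a local
  effective-genome-length background; a peak is open when the upper tail
  `P(X > n)` falls below 0.01.
* **Peak-gene links.** Candidates are peaks within 100 kb of the gene body.
  The statistic is the Pearson correlation (Spearman available) between
  normalized metacell accessibility and expression. Significance comes from
  an empirical background of 100 peaks drawn from the candidate's joint
  (GC content x total accessibility) bin — equal-frequency bins, default
  100 per covariate; use fewer for small peak sets so bins stay populated.
  The candidate is excluded from its own background (otherwise a small bin
  makes a peak its own null and the p-value saturates); sampling is with
  replacement when a bin is small. The one-sided add-one estimator
  `p = (1 + #{r_bg >= r})/(1 + 100)` can never be 0; links with `p < 0.1`
  are significant.
* **Gene scores and accessibility.** A gene's score in a metacell is the
  summed normalized accessibility of its significantly linked peaks; its
  gene accessibility is the fraction of linked peaks called open (0-1).

# TF activity inference

Gene trends along a supplied pseudotime are fit per gene with a cubic
regression spline GAM (`mgcv`), z-scored across lineage metacells; constant
genes give zero trends. The TF-target matrix weights motif scores by
peak-gene correlation over qualifying peaks (`p < 0.1`, `r > 0.1`):
`G_gt = sum_k c_kg F_kt / sum_k c_kg`. Per metacell, a lasso of the trend
column on column-standardized `G` (penalty by 10-fold CV, folds seeded)
yields coefficients `w`; TF activity is the *increase* in squared prediction
error when the TF's term is dropped from the predictor — prediction-time
exclusion, not a refit — signed by `sign(w_t)`, and exactly zero when
`w_t = 0`. The published formula subtracts in the opposite order to the
prose; the prose (error increase upon exclusion) is implemented. TFs are
ranked by total signed activity (absolute-value ranking available).

# Evaluation metrics

Compactness = mean per-component population standard deviation of member
cells in diffusion space (population, so singletons give 0); separation =
distance to the nearest other metacell centroid (a nearest-member variant is
available); purity = modal cell-type frequency. NMI uses arithmetic-mean
normalization with natural logs. Density strata classify cells by distance
to their 150th neighbor (upper quartile = low density), metacells inherit
the stratum capped at 30% each, prioritized by stratum-cell count.
Neighborhood mixing entropy is the Shannon entropy of types among the 10
nearest metacells.

# Cohort analysis

Metacells are computed per sample (75-cell heuristic), pooled, and mapped
across samples by mutual top-2 nearest neighbors on diffusion components of
the supplied batch-corrected embedding — correction itself is an input, the
module never corrects internally. Meta2cells re-run the whole kernel
archetypal pipeline on metacell rows with one meta2cell per 10 metacells;
annotations use the 80%-purity rule, otherwise "Mixed". The permutation
test shuffles metacell-to-meta2cell assignments (sizes fixed, condition
labels riding along, which is equivalent to permuting labels), builds each
meta2cell's null disease-proportion distribution over 5,000 trials, and
reports the add-one two-sided p (`min(lower, upper) * 2`, capped at 1;
one-sided available). Significance defaults to `p < 0.1`.

# The synthetic multiome generator

The generator exists so every module is testable without downloads. Each
state owns a disjoint block of marker genes/peaks raised `marker_fold`-fold
over a gamma baseline; counts are negative binomial (dispersion 0.5) around
state means scaled by log-normal library sizes (medians 2,500 RNA / 3,000
ATAC). Planted links tie a peak's cross-state accessibility to a gene's
expression profile (blend weight 0.8). Fragments get a two-mode length
mixture (nucleosome-free mode 80 +- 20 truncated below 147, weight 0.6;
mono-nucleosome 200 +- 30) with both ends inside the source peak, on a toy
genome of 50-kb-spaced genes. A trajectory mode interpolates programs along
a latent pseudotime for trend fitting.

Two deliberate regimes differ in separation. The multiome generator uses
`marker_fold = 8`: states are well separated, matching the purity, NMI and
rare-population experiments. The cohort generator uses `marker_fold = 3`:
states overlap enough that the mutual-kNN kernel stays connected, as in
real cohort data. This matters because with fully disconnected state blocks
the optimizer cannot move archetypes between blocks, metacell counts stop
tracking population mass, and differential abundance loses its signal —
a structural property of kernel archetypal analysis worth knowing: it
allocates archetypes by geometric complexity, not by mass, within connected
regions density gradients restore mass tracking.

What the generator does not emulate: batch effects beyond library-size
shifts, doublets, ambient RNA, sequence-composition bias (GC content is
drawn independently of peak behavior), or realistic genome coordinates.
Passing tests on this generator therefore demonstrate correctness of the
algorithms under the stated model, not robustness to every artifact of real
assays.

# Problem sizes in the validation suite

The packaged experiments use 10,000 cells x 20 states (robustness across
five initializations), 12,000 cells with one rare state at 0.7/0.5/0.2%
(rare-population recovery, one metacell per rare-count cells), 20 cohort
replicates of 8 samples x 1,000 cells (abundance-test calibration and
power), 300-peak/200-gene matrices for the empirical-background null, and
50 replicates of a 120-gene, 8-TF planted-regulator design. These sizes
were chosen as the smallest at which each qualitative claim is stable.

The rare-population runs set `max_iter = 60`: recovery is decided by
whether an archetype locks onto the rare cells, which the max-min
initialization settles immediately; the remaining iterations only refine
boundaries among abundant states. Two structural bounds keep the optimizer
predictable on large inputs: each cell's active-archetype support is capped
at 16 (further steps exchange weight within the active set — downstream
binarization uses only the top weights), and the number of B passes per
outer iteration follows a per-iteration compute budget (deep passes are
nearly free on small problems and redundant on large ones, where a single
exact-line-search pass per iteration already moves every archetype).

# Known limitations

* Archetype allocation ignores population mass across disconnected kernel
  components (see above); strongly fragmented manifolds should be analyzed
  per component.
* The permutation p-value is discrete: with meta2cells of ~10 metacells the
  two-sided test cannot reach p < 0.02, and its rejection rate at
  `alpha = 0.1` under the null sits below the nominal level. Larger
  meta2cells sharpen both.
* The exact kNN search is quadratic-ish in practice above ~10^5 cells;
  approximate search is deliberately not enabled by default.
* Lasso coefficients are reported on the standardized scale of `G`.
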