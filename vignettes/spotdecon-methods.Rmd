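---
title: "Methods: enrichment-guided dampened least squares for spot deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment-guided dampened least squares for spot deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdecon)
```

## The model

A spatial transcriptomics spot captures a handful of cells. Writing $t \in
\mathbb{R}^G$ for a spot's expression over $G$ signature genes and $S \in
\mathbb{R}^{G \times K}$ for the signature matrix of mean marker expression
per cell type, the spot is modelled as a convex mixture $t \approx S f$ with
$f$ on the probability simplex ($f_k \ge 0$, $\sum_k f_k = 1$). Two
departures from plain least squares make this work on real spots:

* **Cell-type pre-selection.** Because only a few types occupy any given
  location, all types are first screened per spot with a parametric
  gene-set enrichment score and only the passing types enter the fit.
* **Dampened relative-error weighting.** Genes span orders of magnitude of
  expression; unweighted least squares is dominated by the highest
  expressors. Weights $w_g = 1/(Sf)_g^2$ turn the objective into a relative
  error, and a damping cap keeps near-zero genes from dominating instead.

### Enrichment screening

The fold change of gene $g$ at spot $s$ is $x_{gs} / \bar{x}_{g\cdot}$ — the
plain ratio to the gene's across-spot mean, so every gene's fold changes
average to 1 and spots are comparable. (Classical parametric gene-set
enrichment uses *log* ratios; a `log2` option exists on `fold_change()` but
the plain ratio is the default here.) For a marker set of size $m$ with mean
fold change $S_m$ at a spot whose all-gene fold changes have mean $\mu$ and
standard deviation $\delta$,

$$\mathrm{ES} = \frac{(S_m - \mu)\,\sqrt{m}}{\delta}.$$

Choices the formula leaves open, fixed here and tested: $\delta$ is the
*population* ($1/n$) standard deviation; marker genes stay inside the
background $\mu, \delta$; genes with zero mean are dropped before scoring;
a spot whose fold changes are all identical ($\delta = 0$) scores 0 with a
warning. Binarization keeps types with $\mathrm{ES} \ge 2$ (inclusive); the
default cutoff of 2 reads as "two background standard deviations above
chance". A spot where no type passes would make the deconvolution
undefined, so its top-scoring type is kept and the spot flagged
(`enrichment_fallback`) rather than returning an empty spot.

### The constrained weighted solve

`solve_constrained_wls()` minimizes $\sum_g w_g ((Sf)_g - t_g)^2$ on the
simplex with a primal active-set quadratic program on the normal equations:
equality-constrained subproblems are solved through their KKT system,
coordinates that hit zero are clamped, and clamped coordinates re-enter when
their multiplier says the objective would improve. The simplex constraint is
enforced *inside* the solve; `post_normalize = TRUE` offers the
rescaled-nonnegative-least-squares reading for compatibility, but the
constrained program is the default because "fraction of each type" is a
statement about the feasible set, not a rescaling. Degenerate inputs are
defined rather than fatal: one active type returns 1; an all-zero spot
returns uniform fractions with a `zero_target` flag; a rank-deficient
signature falls back to a pseudoinverse KKT solve (the program is convex, so
a minimizer always exists) and flags the solution.

### Dampened iteration and the damping constant

Starting from the unweighted fit, weights $w_g = \min(1/\max((Sf)_g^2,
\varepsilon),\; d \cdot \min_{g'} w_{g'})$ are recomputed and the program
re-solved until the fractions move less than `tol` ($10^{-8}$) or 100
iterations. $\varepsilon = 10^{-12}$ floors the squared fitted value so a
gene fitted at exactly zero cannot produce an infinite weight. The cap
$d \cdot \min w$ interpolates between unweighted least squares ($d = 1$:
every weight collapses to the minimum) and raw relative-error weighting
($d \to \infty$).

$d$ is selected from the candidates $2^0, \dots, 2^{13}$ by a stability
criterion: for each candidate the iterated solve runs on `cv_folds` (10)
random half-gene subsamples — the same subsamples for every candidate, drawn
from the configured seed — and the candidate minimizing the mean
across-subsample variance of the fractions wins, ties going to the smallest
$d$. On noiseless data every candidate is equally stable and the smallest is
returned.

### Cluster sharing and the second round

Spots within an expression cluster are technical near-replicates, so the
damping constant and the gene weight vector are fitted once per cluster — on
the cluster's *mean* expression profile, over the union of the cluster's
enrichment-selected types — and reused for every member spot. Fitting on the
mean profile is this package's concrete reading of weight sharing: it is the
cheapest estimator of a cluster-typical weight vector and is deterministic.
Cluster labels are an input; when absent, `cluster_spots_kmeans()` (seeded
k-means on the top principal components of log1p expression) stands in.
Graph-based community detection is deliberately out of scope — the labels,
not the algorithm, are what the solver needs.

Because a spot holds roughly 5–10 cells, fractions below ~1/7 are already
suspect; after the first weighted solve, types under `min_frequency` (0.02,
strict `<`) are removed and the weighted solve re-runs on the survivors.
Removed and never-selected types are *exactly* zero in the output — an
invariant the tests assert with `identical()`, not a tolerance.

## Marker ranking and the signature

Markers are ranked per type by the product of (i) the Gini coefficient of
the gene's mean expression across types (specificity: 0 for a flat gene,
$(K-1)/K$ for a one-type-only gene) and (ii) a one-vs-rest detection
contrast — the fraction of in-type cells with a nonzero count minus the
fraction of out-of-type cells with one (prevalence). Ties break
lexicographically by gene id so rankings are reproducible. This score is a
self-contained definition, chosen for testability, not a bit-compatible
re-implementation of any toolkit.

A known limitation follows from the detection term: in a reference deep
enough that essentially every gene is detected in every cell, the contrast
— and with it the whole score — degenerates to zero and the ranking becomes
uninformative. Real droplet-based references are sparse (most genes
undetected per cell), which is the regime the score is designed for and the
regime the synthetic fixtures emulate.

The signature takes the union over types of each type's `top_n` (default
100) ranked genes; entry $(g, k)$ is the mean expression of $g$ over cells
annotated $k$. Reference and spots must share one normalization —
`normalize_library_size()` (column sums to $10^4$) is applied to both, since
$S$ and $t$ on different scales would make the weighted residual
meaningless. Whether mean signatures should use raw or normalized counts is
genuinely open; normalized is used throughout, and users supplying their own
signature should match their spots' scale. Curated marker sets and
signatures can bypass the ranking entirely.

## The synthetic benchmark generator

`synthetic_scenario()` defaults describe a small cortex-like tissue: 6 cell
types, 60 disjoint marker genes each, elevated 10-fold over a flat
background of 1000 genes; a reference of 50 cells per type; 100 spots each
mixing 7 cells drawn from at most 3 types (so most types are absent from
most spots — the case that motivates enrichment screening); Poisson counts
at an expected depth of 2000 transcripts per spot and per reference cell.
Ground-truth fractions are exact rationals (cells-of-type / cells-in-spot).
All draws flow from a single scenario seed.

What the generator does *not* emulate: within-type expression gradients,
correlated (over-dispersed) noise, segmentation errors, doublets, platform
gene-capture bias, and marker overlap between related types. Passing the
recovery tests therefore demonstrates correctness of the estimator under
its own model — Poisson noise around a true mixture of reference profiles —
not performance on any particular tissue.

`coarse_grain()` builds the complementary benchmark from single-cell-
resolution spatial data: cells are binned into squares of side `bin_size`
(half-open intervals $[kb, (k+1)b)$ per axis, origin at the minimum
coordinate, so boundary cells are assigned exactly once), expression is
aggregated per bin, and the exact per-bin type mixture is the truth. Both
`sum` and `mean` aggregation are offered (`sum` is the default; on the
simplex the unweighted fit is scale-invariant but the dampened weights are
not, so the choice is exposed rather than hidden). Bins below `min_cells`
(default 1) are dropped.

## Evaluation

`rmse_by_presence()` splits spots per type by `truth > 0` (exact — truth is
rational with small denominators) and reports RMSE over each subset:
errors on present spots measure sensitivity, errors on absent spots measure
specificity (phantom assignments). The exact identity
$n\,\mathrm{MSE} = n_p\,\mathrm{MSE}_p + n_a\,\mathrm{MSE}_a$ is asserted in
the tests. An empty subset reports `NA` rather than 0.

## Spatial assortativity

With $w_k^i$ the fraction of type $k$ at spot $i$, $e_{ij}$ the symmetric
neighbour indicator, and $N$ the number of spots:

$$q_{kk} = \frac{\sum_i \sum_j w_k^i w_k^j e_{ij}}{\sum_i \sum_j e_{ij}},
\qquad a_k = \frac{1}{N} \sum_i w_k^i, \qquad
Q = \frac{\sum_k q_{kk} - \sum_k a_k^2}{1 - \sum_k a_k^2}.$$

Ordered-pair double counting cancels in $q_{kk}$, so undirected edge lists
are used internally; self-edges are excluded; isolated spots still count in
$a_k$. $Q = 1$ iff every edge joins identically-composed one-hot spots of
more than one global type; a graph occupied by a single type makes the
denominator zero and is an explicit error.

One subtlety is worth stating precisely: with one-hot compositions this
statistic uses the *node* frequency $a_k$ as its chance expectation,
whereas the classical discrete assortativity coefficient uses the fraction
of *edge ends* attached to type $k$. The two coincide exactly on regular
graphs — which spatial transcriptomics arrays are, away from tissue edges —
and the test suite checks exact agreement with an independent
implementation (igraph) on every regular 2-labelled graph of up to 5 nodes,
alongside a literal loop-based oracle on all such graphs, regular or not.
On irregular graphs the two definitions differ and this package
deliberately keeps the node-frequency form, which extends naturally to
fractional $w_k^i$.

Neighbour rules: `grid` (default) connects spots within 1.05× the minimum
positive pairwise distance — rook neighbours on square arrays, the six
neighbours on hexagonal arrays, diagonals excluded; `radius` takes an
absolute cutoff for irregular platforms; `delaunay` keeps triangulation
edges, computed by the empty-circumcircle characterization ($O(n^4)$ —
adequate for the hundreds of spots of a section, not for whole slides).
Which rule a given published analysis used is generally not recoverable;
the default is documented and configurable.

## Numerical choices, in one place

* Active-set QP: feasibility tolerance $10^{-10}$, dual tolerance
  $10^{-9}$, pseudoinverse fallback for singular KKT systems.
* Dampened iteration: `tol` $10^{-8}$ on $\max_k |\Delta f_k|$, `max_iter`
  100, non-convergence returns the last iterate with a flag.
* Damping selection: tie-break to the smallest candidate within $10^{-12}$
  of the minimum variance.
* `min_frequency` removal is strictly below 0.02; if removal empties a
  spot, the largest-fraction type is retained.
* Output files print numbers as C-locale `%.10g`, so round-trips hold to at
  least 6 significant digits and equal-seed runs are byte-identical.
* Every random draw (reference synthesis, compositions, Poisson counts,
  k-means, cross-validation subsampling) derives from an explicit integer
  seed; generators restore the caller's RNG state.

## Problem sizes in the shipped tests

The suite runs the full pipeline at the default scenario (6 types ×
1000 genes × 100 spots), 50-instance noiseless-recovery and 20-instance
solver-optimality batches, a 10,000-point random-feasible-point oracle, an
exhaustive graph enumeration up to 5 nodes, and byte-identity checks over
every CLI subcommand — sizes chosen so the whole suite completes in well
under a minute while still exercising each claim at meaningful scale.

## Known limitations

* The Gini ranking degenerates on saturated (non-sparse) references, as
  discussed above.
* Cluster-shared weights assume clusters are compositionally coherent; a
  bad clustering degrades (but does not invalidate) the fit.
* The Poisson generator understates real technical variance; error
  estimates from the benchmark are optimistic relative to tissue data.
* The enrichment screen trades sensitivity for specificity: a type truly
  present at a low fraction can be screened out, which surfaces as
  present-subset RMSE concentrated near small true fractions.
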