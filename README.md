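# spotdecon

Cell-type deconvolution of spatial transcriptomics spots by
enrichment-guided dampened weighted least squares.

## The problem

Sequencing-based spatial transcriptomics platforms (e.g. 55 µm array spots)
measure the mixed expression of the handful of cells captured at each spot.
Downstream biology usually needs the *cell-type composition* of every spot:
the fraction of astrocytes, neurons, etc. contributing to each mixed
profile. `spotdecon` infers these fractions from an annotated single-cell
reference, for analysts who have (i) a genes × spots expression matrix with
spot coordinates and (ii) either an annotated scRNA-seq reference or a
ready-made signature matrix of mean marker expression per cell type.

## The method

Each spot holds few cells, so most cell types are absent from most spots.
`spotdecon` therefore works in two steps:

1. **Cell-type pre-selection by enrichment.** For each gene, the fold
   change at spot *s* is its expression divided by its mean over all spots.
   A cell type with marker set of size *m*, mean marker fold change *S_m*,
   against a background with per-spot mean *μ* and standard deviation *δ*
   over all genes, scores

   `ES = (S_m − μ) · √m / δ`

   (a PAGE-style z-score). Types with `ES ≥ 2` are considered candidates at
   that spot; a spot where nothing passes keeps its single best-scoring type.

2. **Dampened weighted least squares on the simplex.** With signature
   matrix *S* (signature genes × active types) and spot profile *t*, the
   fractions solve

   `min_f Σ_g w_g ((S f)_g − t_g)²  s.t.  f ≥ 0, Σ f = 1`

   by an exact active-set quadratic program. Weights are
   `w_g = min(1/(S f)_g², d · min_g' w_g')` — inverse squared fitted values
   so the fit minimizes *relative* error, capped by a damping constant *d*
   chosen by cross-validation (the candidate `2^0 … 2^13` minimizing the
   variance of the estimate over half-gene subsamples). Weights and *d* are
   shared across all spots of a cluster, and a second round is solved after
   removing types estimated below a minimum frequency (0.02 by default).

The package also provides: marker ranking by a Gini specificity score and
signature building from an annotated reference; a coarse-graining simulator
that bins single-cell-resolution spatial data into pseudo-spots with exact
ground-truth compositions; RMSE evaluation split by cell-type
presence/absence (sensitivity vs specificity); and a fractional spatial
assortativity coefficient
`Q = (Σ_k q_kk − Σ_k a_k²)/(1 − Σ_k a_k²)` measuring whether neighbouring
spots hold similar compositions.

## Worked example

```r
library(spotdecon)

# synthetic tissue: 6 cell types, 60 markers each at 10x elevation,
# 100 spots of ~7 cells, Poisson depth 2000
res <- run_benchmark(synthetic_scenario(seed = 7L), solver_config(seed = 7L))
round(colMeans(abs(res$truth - res$estimate)), 4)
#> type_1 type_2 type_3 type_4 type_5 type_6
#> 0.0364 0.0385 0.0250 0.0306 0.0286 0.0113
res$report
#> RMSE by cell-type presence/absence
#>    type rmse_overall rmse_present rmse_absent n_present n_absent
#>  type_1      0.10821       0.1779           0        37       63
#>  type_2      0.09446       0.1532           0        38       62
#>  type_3      0.08256       0.1619           0        26       74
#>  type_4      0.08327       0.1428           0        34       66
#>  type_5      0.09257       0.1663           0        31       69
#>  type_6      0.04875       0.1017           0        23       77
```

The mean absolute error per type stays below 0.05 — about a third of a cell
at seven cells per spot. The `rmse_absent` column is exactly 0: enrichment
pre-selection plus the minimum-frequency filter never assigned a type to a
spot it does not occupy, whereas the unweighted, unfiltered baseline
(`res$baseline_report`) leaks small spurious fractions onto absent types.

A shell interface wrapping the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "spotdecon.R", package = "spotdecon"))')" \
  deconvolve --spatial spots.tsv --signature sig.tsv --markers markers.tsv \
  --cutoff 2 --min-frequency 0.02 --seed 1 --out comp.tsv
```

Subcommands: `deconvolve`, `simulate coarse-grain`, `simulate synthetic`,
`evaluate`, `assortativity`, `benchmark`.

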