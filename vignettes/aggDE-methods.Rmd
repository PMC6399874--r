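---
title: "Methods and design notes for aggDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for aggDE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggDE)
```

aggDE merges many pairwise differential-expression contrasts into one master
gene × contrast result set and computes the numeric tables behind sixteen
standard visualizations of that set. This vignette records the statistical
procedures, the tunable parameters and their defaults, the numerical
conventions, and the design decisions that were genuinely open — the things
a maintainer or reviewer would want written down.

## Aggregation model

Each contrast is a five-column table per gene: normalized mean expression,
log2 fold change, raw p, adjusted p (Benjamini–Hochberg FDR). Significance
is `padj < p_cut` (strict) and `|log2fc| >= lfc_cut` (non-strict); the
boundary conventions are arbitrary but must be fixed somewhere, and
strict-on-p matches the common reading of "padj < 0.05". A gene with missing
`padj` is never significant: external engines emit NA for genes removed by
independent filtering, so NA means "no adjusted evidence", not zero. A
missing raw p-value, by contrast, indicates a corrupt table and is rejected
at read time.

The master result keeps the union or intersection of the per-contrast
significant sets and then *re-extracts* fold changes and adjusted p-values
for every retained gene from every contrast, significant there or not. The
alternative — storing NA for non-significant cells — would make
cross-contrast heat maps and profile plots unreadable, and the boolean
significance matrix preserves the distinction anyway. Genes entirely absent
from some contrast's table are retained with missing values in that column
under union mode and excluded under intersection mode, because intersection
semantics demand evidence in every contrast.

Two consequences worth noting: union mode can hold NA cells, so downstream
summaries ignore missing values gene-wise; and the intersection of disjoint
sets is a valid empty master result (with a warning), not an error.

The per-gene *overlap count* (in how many contrasts a master gene is
significant) and the per-contrast *agreement densities* — kernel density of
`padj` or `log2fc` restricted to the master genes, one curve per contrast on
a shared grid — are the diagnostic for whether a merge was sensible: curves
that disagree wildly suggest the aggregation mixes incompatible contrasts.

## Normalization

TMM scale factors follow the canonical trimmed-mean-of-M-values recipe.
Library sizes are column sums; the reference sample is the one whose
75th-percentile CPM is closest to the mean across samples (ties to the
earlier column, for determinism). For sample $k$ against reference $r$, over
genes with positive counts in both,

$$M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r},\qquad
  A_g = \tfrac12 \log_2\!\Big(\frac{y_{gk}}{N_k}\cdot\frac{y_{gr}}{N_r}\Big),$$

the top and bottom 30% of genes by $M$ and 5% by $A$ are trimmed
(`floor(n * trim)` from each end, ranks tie-broken by position so the
selection is reproducible), and the factor is $2$ to the mean of the kept
$M_g$ weighted by inverse delta-method binomial variances
$w_g^{-1} = \frac{N_k-y_{gk}}{N_k y_{gk}} + \frac{N_r-y_{gr}}{N_r y_{gr}}$.
Factors are rescaled to geometric mean 1. The trim fractions are exposed
(`trim_m`, `trim_a`) because no single pair is canonical for all designs.
Because the weights depend on absolute counts, rescaling a single column
moves factors at the $10^{-3}$ level; only globally proportional columns
give exactly unit factors.

Three transforms are offered on the counts-per-million scale: `cpm`,
`log2cpm` (prior 1) and `reglog`, a shrunken log
$\log_2\big(10^6 (y+\text{prior})/(N f)\big)$ with prior 4. `reglog` is this
package's regularized-log transform: a moderated log2cpm that tames the
variance of low counts for visualization. It is *not* a model-based variance
stabilization — that would require a fitted mean-dispersion model — but it
serves the same visual purpose at a fraction of the machinery.

## The reference NB test

`nb_reference_test` exists so the pipeline is exercisable end-to-end without
an external engine; it is deliberately simple (no dispersion shrinkage, no
independent filtering, two-group designs only) and external engines remain
the intended source of production contrasts. Per gene: group means on the
CPM scale, $\widehat{\beta} = \log_2\frac{m_a + 0.5}{m_b + 0.5}$; a pooled
method-of-moments dispersion $\alpha = (s^2 - \mu)/\mu^2$ on size-factor
normalized counts, df-weighted across the two groups and floored at
$10^{-8}$; a Wald z from the delta-method standard error of
$\widehat{\beta}$ under $\mathrm{Var}(y) = \mu + \alpha\mu^2$; BH adjustment
over all genes. With 5 + 5 replicates the null p-values are near-uniform
(Kolmogorov–Smirnov statistic ≈ 0.04 at 2000 genes in the test suite) and a
planted 4-fold change at dispersion 0.05 is recovered for ≥ 80% of planted
genes at FDR 0.05. The dispersion floor pins under-dispersed genes to
(nearly) Poisson variance on the observed count scale, which is why p-values
are invariant under global depth rescaling only up to that floor; fold
changes are exactly invariant.

## Distances, clustering, MDS

The Poisson sample distance divides counts by size factors
$s_i = N_i/\text{geomean}(N)$ and takes the square root of the Poisson
deviance divergence
$\sum_g x'_{gi}\ln(x'_{gi}/\mu_g) + x'_{gj}\ln(x'_{gj}/\mu_g)$ with
$\mu_g$ the pooled mean and $0\ln 0 = 0$. It is symmetric, zero iff the
scaled profiles coincide, and insensitive to sequencing depth — the property
Euclidean distance on raw counts lacks.

Agglomerative clustering supports complete (default), average and single
linkage. Ties in the minimal distance are broken toward the pair whose
cluster IDs (each cluster named by its lexicographically smallest member)
sort first — `stats::hclust` leaves tie order input-dependent, and
deterministic trees are required for reproducible figure layouts and golden
tests. Complete linkage is the default because it yields compact clusters
for the sample-distance heat map and satisfies monotone merge heights.
Dendrograms export to Newick with branch lengths equal to height
differences.

Classical MDS double-centers $-\tfrac12 J D^2 J$ and eigendecomposes;
coordinates are the top-k eigenvectors scaled by the square roots of
non-negative eigenvalues, with negative eigenvalues (non-Euclidean input)
truncated to unused and reported. Group overlays are either normal-theory
confidence ellipses — the 2-D sample covariance scaled by
$\chi^2_2(\text{level})$, default level 0.95 (scale 5.991) — or convex hulls
with vertices ordered counter-clockwise. The ellipse is a closed form and
exactly testable, which is why it was chosen over data-peeling contours;
groups with fewer than 3 points (or collinear points, for hulls) are
reported and skipped rather than fatal.

Profile clustering z-scores each gene's fold-change row (zero-variance rows
become all-zero profiles; genes with any missing value are excluded and
reported), then cuts a complete-linkage Euclidean tree at k groups. The
z-scoring is deliberate: the feature targets *shape* similarity across
contrasts, not magnitude.

## Statistical primitives

The Wilcoxon rank-sum statistic is the rank sum of the first group. With
$n_1 + n_2 \le 12$ and no ties the p-value is exact by full enumeration of
all $\binom{n_1+n_2}{n_1}$ rank assignments (at most 924 splits — instant,
and exactly testable against an independent enumeration); the two-sided
exact p doubles the smaller tail and is capped at 1. Ties or larger samples
take the normal approximation with tie-corrected variance and continuity
correction. Exact enumeration under ties was omitted deliberately: the
tie-corrected normal path is standard, and the exact tie-permutation
distribution buys little at the sample sizes where ties occur.

`bh_adjust` performs the step-up over non-missing entries with m equal to
the number of non-missing p-values; NA stays NA. This differs from
`p.adjust`'s default (which counts NAs in n), hence the in-package
implementation, cross-checked against `p.adjust` on complete vectors.

Kernel densities use a Gaussian kernel with Silverman's bandwidth
$0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$ and a 512-point grid
spanning the data ± 3 bandwidths; a degenerate sample (zero sd *and* zero
IQR) is an error that suggests an explicit bandwidth. The evaluation is the
exact kernel sum rather than a binned FFT so that several contrasts'
densities can share one caller-supplied grid, as the agreement-density plot
requires.

## Visualization registry and project workspace

Every plot type is split into `compute_plot_data` (pure: domain objects in,
numeric tables out) and `render_plot` (tables + theme + size to file). The
registry's census is sixteen: the sample-distance heat map, group
dendrogram, two MDS variants, pre- and post-normalization box plots,
fold-change box plot, divergence plot, up/down summary, volcano, gene heat
map, profile plot, Wilcoxon gene box plot, co-expression series, and the
aggregation agreement density split by statistic (p-value vs fold change).
Counting the normalization box plots and the two density statistics as
separate types is the registry's canonical reconciliation of the feature
list with the figure panels.

Conventions fixed for determinism: box-plot whiskers at 1.5 × IQR (Tukey);
volcano y-axis is $-\log_{10}$ adjusted p with zero padj clamped to the
table's smallest positive value; heat-map rows clustered
(complete/Euclidean) while columns stay in user order, because contrasts are
usually ordinal (time) and column clustering should be opt-in. The
divergence plot shows, per contrast, the mean fold change of the significant
up-set and down-set as signed bars; the alternative reading (per-group
deviation from a grand mean) was considered and rejected as harder to
interpret next to the up/down summary.

Six built-in themes supply palettes and layout parameters; every theme
renders every type. Figure sizes auto-rescale: row-indexed plots grow 0.15
inch per row beyond 20 (clamped at 4 × base height), sample/contrast-indexed
widths grow 0.3 inch per item beyond 12 (clamped at 4 × base width);
non-indexed plots keep the base size.

The project scaffold (`results/de_lists`, `results/master`, `figures/pdf`,
`figures/png`, `figures/data`, `logs`, `config`) is created on init,
re-init with merge is idempotent and lossless, and refuse-mode on a
non-empty root fails without touching anything. Exports never overwrite:
collisions get `_v2`, `_v3`, … suffixes, and every written file gets exactly
one log line, so the log is a complete audit of the scaffold. The config
snapshot is flat `key = value` text — diff-able and durable.

## The synthetic data generator

`simulate_counts` emulates a miniature infection time-course: a factorial
grid (default 3 time points × 4 treatments, 3 replicates per cell), gene
baselines drawn log-normal (meanlog `log(100)`, sdlog 1.2 — a realistic
spread of expression magnitudes), negative-binomial counts parameterized by
mean and dispersion (`var = mu + alpha mu^2`, default alpha 0.05, a typical
bulk RNA-seq value), library-size factors log-uniform on [0.7, 1.4] so scale
normalization is exercised non-trivially, and planted multiplicative
`2^lfc` effects on chosen genes for chosen treatment levels, recorded in a
truth table. The same seed reproduces the counts bit-exactly, and the
generator restores the caller's RNG state.

What it does *not* emulate: batch effects, gene–gene correlation, per-gene
dispersion trends, outlier samples, or read-level artifacts. Tests passing
on this generator therefore demonstrate correctness of the algebra and the
inference machinery under clean NB assumptions, not robustness to the full
messiness of real data.

Problem sizes used in the test suite and acceptance script — 2000 genes for
the inference checks, 120–600 genes for pipeline and rendering smoke tests,
5 replicates per group for the recovery runs — were chosen as the smallest
sizes at which the statistical assertions are stable.

## Known limitations

- The reference test supports exactly two groups of ≥ 2 samples; no GLMs,
  interactions, or dispersion shrinkage.
- `reglog` approximates, not implements, model-based variance
  stabilization.
- Merge algebra is union/intersection only; k-of-n membership is a natural
  extension.
- Hierarchical clustering is quadratic per merge in pure R — fine for
  samples and master gene sets (hundreds), not for clustering all genes of
  a genome-scale matrix.
- The Wilcoxon exact path excludes tied data by design.
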