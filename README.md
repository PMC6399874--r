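# aggDE

Aggregation, exploration and visualization of multi-contrast differential
expression results.

## The problem

Time-course and multi-treatment RNA-seq studies produce one differential
expression (DE) result table *per contrast* — e.g. each virus against mock at
each time point — and the per-contrast gene lists rarely coincide. Before any
cross-contrast question can be asked ("which genes respond to both viruses,
and how do their fold changes evolve over time?"), those tables have to be
merged onto one gene universe, re-aligned, filtered and reshaped. aggDE does
that bookkeeping once, correctly, and derives the standard visualizations
from the merged result.

The core object is the **master result set**. Given contrasts
$c = 1, \dots, k$ with per-gene adjusted p-values $q_{gc}$ and log2 fold
changes $\beta_{gc}$, gene $g$ is *significant* in contrast $c$ when

$$q_{gc} < p_{\text{cut}} \quad\text{and}\quad |\beta_{gc}| \ge \beta_{\text{cut}},$$

and the master gene set is either the union or the intersection of the
per-contrast significant sets. Crucially, $\beta_{gc}$ and $q_{gc}$ are then
**re-extracted for every retained gene in every contrast** — including
contrasts where the gene was not significant — so heat maps, profile plots
and agreement densities can show the full gene × contrast picture, while a
boolean significance matrix keeps the original calls.

Around the aggregator the package provides, with every figure split into a
pure data-computation step and a rendering step:

- trimmed-mean-of-M-values (TMM) scale factors and cpm / log2cpm /
  regularized-log transforms;
- a minimal negative-binomial Wald test (`nb_reference_test`) so the whole
  pipeline runs without an external DE engine, plus dialect-tolerant readers
  for tables produced by external engines;
- Euclidean and Poisson-deviance sample distances, deterministic
  hierarchical clustering, classical MDS with confidence ellipses or convex
  hulls, and cross-contrast profile clustering;
- exact/approximate Wilcoxon rank-sum testing, Benjamini–Hochberg
  adjustment and Gaussian kernel densities;
- 16 registered plot types under 6 themes, each rendering from a
  serializable `plot_data` table set;
- a standardized project workspace (`init_project`) with toggled auto-export
  of figures (pdf + png), plot-data sidecars and an append-only audit log;
- a deterministic negative-binomial count simulator with planted DE genes
  (`simulate_counts`) used throughout the tests.

## Worked example

```r
library(aggDE)

## a miniature infection time-course: 2000 genes, ebov/restv/mock at 5
## replicates, 200 genes planted DE per virus (overlapping in 100)
design <- sim_design(
  n_genes = 2000, times = "6h",
  treatments = c("ebov", "restv", "mock"), replicates = 5,
  dispersion = 0.05,
  effects = list(
    list(treatment = "ebov",  genes = 1:200,   lfc = rep(c(2, -2), 100)),
    list(treatment = "restv", genes = 101:300, lfc = rep(c(2, -2), 100))),
  seed = 101)
sim <- simulate_counts(design)

ebov  <- nb_reference_test(sim$counts, sim$metadata, "treatment", "ebov",  "mock")
restv <- nb_reference_test(sim$counts, sim$metadata, "treatment", "restv", "mock")

shared <- aggregate_contrasts(list(ebov, restv), "intersection", p_cut = 0.05)
shared
#> master_result (intersection): 111 genes x 2 contrasts (padj < 0.05, |lfc| >= 0)

doubly_planted <- rownames(sim$counts)[101:200]
mean(doubly_planted %in% shared$genes)
#> [1] 0.99
table(overlap_counts(shared))
#>   2
#> 111
```

99% of the genes planted in *both* contrasts are recovered by the
intersection; every retained gene is significant in both contrasts (overlap
count 2), which is what intersection mode guarantees. A project workspace
collects figures and their exact numbers:

```r
pl <- init_project("ebola_mini")            # creates the 7-folder scaffold
pd <- compute_plot_data("volcano", list(contrast = ebov),
                        list(p_cut = 0.05, lfc_cut = 1))
render_plot(pd, theme = "standard", project = pl)
#> writes figures/pdf/volcano.pdf, figures/png/volcano.png,
#> figures/data/volcano.points.tsv (+ .meta.tsv), one log line per file
```

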