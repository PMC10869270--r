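---
title: "Mosaic single-cell integration via regression bridges"
author: "mosaicbridge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic single-cell integration via regression bridges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicbridge)
```

## The problem

Single-cell experiments increasingly measure different feature panels on
different sets of cells: full-transcriptome RNA in one experiment, a few
hundred targeted probes in a spatial assay, chromatin peaks or surface
proteins in another. *Mosaic* integration is the task of embedding all of
these cells in one common low-dimensional space when no feature is shared
by every dataset — and possibly no feature at all is shared by some pairs.

Methods that operate on the feature intersection discard most of the
measured signal, and fail outright when the global intersection is empty.
`mosaicbridge` instead organises the datasets in a *mosaic data topology*
(MDT): a graph with one node per dataset and an edge wherever two datasets
share at least one feature, weighted by the shared-feature count. As long
as this graph is connected, every cell can be carried into the coordinate
system of any chosen reference dataset by walking a path through the graph.

## The model

For a reference dataset $D_r$ (features $\times$ cells) we fit a linear
reduction with loadings $A_r$ (features $\times$ $d$) and scores
$S_r = (D_r - \mu_r)^T A_r$: PCA on all of the reference's features by
default ($d = 50$), or LDA when discrete cell labels are supplied (then
$d \le$ classes $- 1$), or a caller-supplied reduction (for example from a
vertical multi-omic factor model). Every other dataset $D_i$ is projected
onto these coordinates by one of three routes:

* **Self** — the reference maps to its own scores.
* **Direct** — if $D_i$ carries every loading feature,
  $S^r_i = (X_i - \mu_r)^T A_r$ with $X_i$ the matching submatrix.
* **Regression bridge** — otherwise, each score dimension $S_r[j]$ is
  regressed (ordinary least squares, with intercept) on the features
  shared between $D_r$ and $D_i$, and the fitted coefficients predict
  scores from $D_i$'s shared-feature submatrix. When $D_i$ shares nothing
  with $D_r$, the weighted shortest path of the MDT (edge cost
  $1/\text{shared count}$, so large overlaps are preferred) is walked
  node by node, re-fitting a bridge at every hop on the previous node's
  estimated scores — *multi-hop* integration.

With several references (the default is all datasets) the per-reference
score blocks are made commensurate by dividing each by its own overall
L1 norm, multiplied by a user weight $w_j \in [0,1]$, and concatenated
column-wise. Two references at the default 50 dimensions therefore give a
100-column embedding.

The key assumption is linearity: reference scores must be well
approximated by linear combinations of shared features. This is the same
assumption that justifies PCA itself on log-normalised expression, and it
is what makes the bridge estimable by least squares. Nonlinear bridge
models are deliberately out of scope.

## Numerical choices

* **Intercept and centring.** The projection formula has no explicit
  intercept, but reference scores are computed on centred data while query
  datasets have unknown means. Every bridge regression therefore includes
  an intercept, and direct projection centres by the stored reference
  feature means; in the full-overlap, full-rank case the two routes then
  agree to machine precision (this is asserted in the test suite).
* **Reweighting norm.** Blocks are divided by their own L1 norm (sum of
  absolute entries) by default; a Frobenius/L2 option is provided. The two
  differ only by a per-block scalar and give the same downstream topology
  for equal weights.
* **Rank-deficient bridges.** Shared panels smaller than the number of
  cells — or larger, as in short-bridge multi-hop designs — make the OLS
  system singular. The fit falls back to minimum-norm least squares
  (Moore–Penrose) with a warning rather than failing: small shared panels
  are the normal situation in mosaic designs, and the minimum-norm
  solution is the conventional continuous extension of OLS.
* **Determinism.** PCA loadings are sign-fixed (largest-magnitude entry
  positive) so results do not depend on cell order; shortest paths break
  ties by fewer hops, then lexicographic node order; k-NN distance ties
  break by cell identifier; vote ties by the nearest neighbour among tied
  classes. Requested dimensions are silently capped (with a warning) at
  what the data supports.
* **LDA.** The LDA reference fit is delegated to `MASS::lda`, centring on
  the prior-weighted grand mean so that stored scores equal direct
  projection of the reference data.

## Downstream tools

* `knnClassify` transfers labels by majority vote among the $k = 5$
  nearest labelled cells (Euclidean distance in the embedding).
* `imputeFeatures` predicts a reference's original features for query
  cells as the unweighted mean over the $k$ nearest reference cells; the
  neighbour search is chunked so memory scales with the chunk, not the
  query set. $k = 5$ mirrors classification and is exposed as an argument.
* `jaccardNeighborhood`, `nearestCellsCurve` and
  `classificationAccuracy` quantify integration quality for matched
  multi-omic cells. The nearest-cells count uses the inequality
  $D(S_{i1}, S_{j2}) \le D(S_{i1}, S_{i2})$ literally, so a perfectly
  aligned pair scores 1 (the matched cell counts itself); within-layer
  Jaccard neighbour sets exclude the cell itself. Both conventions are
  documented rather than silently shifted.
* `neighborMeanFeatures` averages each gene over the cells at most two
  hops away in a spatial neighbour graph (isolated cells keep their own
  value so the feature stays defined), producing spatial-context features
  that can be concatenated with the measured panel before integration.
  When only coordinates are available, `spatialGraph` builds a
  symmetrised k-NN graph with $k = 6$, approximating Delaunay edge
  density.
* `localEnrichmentTest` asks, per query cell, whether marked (for
  example lineage-labelled) cells of a perturbed genotype are locally
  enriched: among each sample's `nNeighbors = 1000` nearest cells it
  computes the marked fraction and fits the binomial logistic model
  $\mathrm{logit}(p) = \beta_0 + \beta_1 x_1 + \beta_2 x_2$ with the
  sample-wide marked proportion $x_1$ and genotype indicator $x_2$,
  neighbourhood sizes entering as binomial weights (so equally sized
  replicates are exchangeable). $\beta_2$ is tested by a 1-df
  likelihood-ratio test and Benjamini–Hochberg adjusted across query
  cells. $x_1$ defaults to each sample's observed marked fraction and can
  be supplied directly when an external baseline (for example injection
  efficiency) is known; it is held constant per sample rather than
  recomputed per neighbourhood.

## The synthetic generator and what the tests show

`generateMosaic` draws cells from a Gaussian mixture in a shared latent
space (one component per cell type), maps them to observed features
through a fixed random loading matrix, adds i.i.d. Gaussian noise, and
hands each dataset only its own feature panel. The linear observation
model makes the projection algebra exactly recoverable, which gives sharp
oracles: noiseless draws have known rank, direct and bridge projections
have closed-form targets, and latent-space distances are the ground truth
against which embedding distances are checked. A fraction of features can
be made uninformative (near-zero loadings) to emulate panels dominated by
features that carry little biological signal.

What this generator does *not* emulate: count noise and zero inflation,
batch effects, nonlinear trajectories, or the marginal distributions of
any real assay. Passing tests therefore demonstrate that the algorithms
are implemented correctly and behave as designed under a linear latent
model — not that any particular biological dataset will integrate well.

The end-to-end properties in the suite use these fixed study conditions,
chosen once as representative regimes:

* *Feature-subset recovery*: 600 cells, 500-feature pool, 3 types
  (latent dimension 10, separation 3), query half keeping 50 random
  features; a low-noise regime (noise SD 0.5, half the features
  uninformative) where recovery should be near-perfect, and a degraded
  regime (noise SD 3, 80% uninformative) where projecting through the
  reference's full-feature PCA should beat PCA restricted to the noisy
  shared panel. With 50 retained features and 50 components the naive
  baseline is simply the centred shared subspace, so any advantage comes
  from the full-panel reference reduction.
* *Bridge-size sweep and sequential chain*: separation 2, noise SD 3,
  half the features uninformative — deliberately off-ceiling so that
  accuracy responds to bridge size (50/200/1000 bridge cells, 2100 cells
  total) and to panel width (8-dataset chain, 300 cells per dataset,
  100 vs 1000 features with 50% sequential overlap). At these sizes the
  full suite runs in about a minute on one CPU.
* *Enrichment calibration*: an "island" design in which each query cell
  has its own cluster of exactly 500 cells from each of 7 samples
  (4 perturbed, 3 control, baseline marked rates 0.30–0.42), making
  neighbourhood draws independent across query cells; the null rejection
  rate at $p < 0.05$ and the recovery of a +1 log-odds local shift are
  checked. For the recovery check the true baselines are passed as
  $x_1$, since locally enriched regions would otherwise inflate the
  observed sample-wide fraction and bias $\hat\beta_2$ toward zero —
  the same caveat applies to real data when enrichment is widespread.

## Known limitations

* Bridges are linear; strongly nonlinear cross-modal relationships (for
  example chromatin-to-expression) are only captured to first order.
* Minimum-norm fits on very small bridges interpolate noise; the
  bridge-size sweep quantifies how quickly quality recovers as the bridge
  grows past the score dimension.
* No batch correction is performed; the embedding is intended as input to
  any downstream horizontal integration tool.
* Imputation densifies per query chunk; extremely wide references with
  very many query cells should be imputed in batches (the chunking keeps
  memory bounded but not the output size).
* File I/O covers Matrix Market with TSV sidecars and dense
  CSV/TSV; the command-line interface in `inst/cli/` is a thin wrapper
  over the exported functions.
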