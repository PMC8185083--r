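---
title: "Models and methods behind scmskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmskit)
```

This vignette documents the statistical models, parameter choices and
numerical conventions of `scmskit`. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The measurement model

A booster-channel scMS experiment reports, for each protein $p$ and each
cell $c$ (one TMT channel in one LC–MS file), a reporter signal-to-noise
ratio $x_{pc} \ge 0$, with `NA` marking non-detection. Three systematic
distortions dominate:

1. **Multiplicative batch effects.** Each LC–MS file and each TMT channel
   imposes its own gain. We model the observed value as
   $x_{pc} = t_{pc}\, f_{\mathrm{file}(c)}\, g_{\mathrm{chan}(c)}\,
   \varepsilon_{pc}$, with $t$ the true abundance, $f, g$ positive scalar
   factors and $\varepsilon$ log-normal measurement noise.
2. **Censoring at the noise floor.** Values below roughly 1.1 s/n are
   indistinguishable from reporter noise.
3. **Abundance-dependent missingness.** The probability of quantifying a
   protein rises with its abundance, so missing values are informative and
   naive imputation biases low-abundance proteins.

## The processing chain

### Iterative median equalization (`normalize_medians`)

Per iteration, two sweeps: (i) per protein, each file's median is pulled
onto that protein's grand median across files (the median of per-file
medians); (ii) the same per channel. Factors accumulate into one
per-protein-per-file and one per-protein-per-channel correction. Missing
values are ignored in every median. Iteration stops when the largest
elementwise change between successive matrices falls below
`convergence_threshold` (default **1.1 s/n**, slightly above the noise
floor). Reading the criterion in absolute s/n units (not as a ratio) keeps
it tied to the instrument noise level; a `metric = "ratio"` variant is
available. Each iteration compares against the previous iteration's matrix
(Gauss–Seidel style), which empirically converges in about 10 iterations on
plate-scale data. Proteins observed in fewer than two levels of a factor
are left untouched by that factor's sweep. Non-convergence at `max_iter`
warns and flags the factor object rather than failing silently.

The grand-median target means factors are identified only up to a global
scale; `estimated_level_factors()` therefore renormalizes per-level
estimates to geometric mean 1 before comparison with injected truth.

### Quality control

* `mask_noise_floor` sets normalized values **strictly below** 1.1 to
  missing; a value exactly at the floor is retained.
* `filter_cells` removes cells whose log2 summed s/n leaves
  $\mathrm{median} \pm 3 \times \mathrm{MAD}$ (MAD with the 1.4826
  normal-consistency constant; multiplier configurable) or that observe
  fewer than `min_proteins_per_cell` proteins (default 10). Total summed
  intensity separates intact cells from empty wells, doublets and sample
  loss.
* `filter_proteins_min_cells` drops proteins seen in fewer than 3 cells —
  the bound is exclusive, a protein in exactly 3 cells stays.
* `median_shift_and_log2` rescales each cell's total to the median total
  (cell size and sampling depth normalization), then log2-transforms. The
  shifted pre-log layer is retained because fold changes are always
  computed from it, never from log or imputed values.
* `qc_factor_diagnostics` audits summed intensity and protein counts across
  files, channels and plate rows (Kruskal–Wallis plus per-level rank tests,
  BH within factor) and reports Cramér's V between each technical factor
  and the population label: a population sorted onto particular rows cannot
  be distinguished from a row batch.

### Imputation and embedding

`impute_knn` fills a missing $(p, c)$ with the mean of $p$'s observed
values among the $k = 5$ nearest cells; distance is Euclidean over mutually
observed proteins divided by the shared-feature count (a root-mean-square
difference), which keeps cells of different coverage comparable. The
observation mask, not zero values, defines sharing, so observed zeros are
handled exactly. If no neighbour observes $p$ the global observed mean is
used. Observed entries are never altered.

`select_coverage_threshold` sweeps coverage fractions from keep-everything
to complete-cases-only, embedding each candidate to 2-D UMAP under a fixed
seed and scoring the mean silhouette of the provided labels; ties go to the
lowest threshold, which keeps the most proteins.

`embed_cells` runs PCA (centred, on the scaled matrix), builds a
k-nearest-neighbour graph with a locally scaled Gaussian kernel
($\sigma_i$ = distance to the k-th neighbour), and derives UMAP
(`n_neighbors = 15`, `min_dist = 0.5` by default — values the upstream
literature leaves unstated, so they are package defaults recorded in
`pipeline_config()`), force-directed layouts, and diffusion components from
the density-normalized transition operator. Diffusion pseudotime is the
root-referenced distance in diffusion space with components weighted by
$\lambda_i/(1-\lambda_i)$, rescaled to $[0, 1]$; cells unreachable from the
root get missing pseudotime rather than a sentinel. The default root is the
cell with the extremal first diffusion component; because an unsupervised
axis has no intrinsic direction, recovery of a latent coordinate is
assessed by absolute Spearman correlation. For trajectory work on datasets
of a few hundred cells we use `n_neighbors = 30` and 20 PCs: a larger
neighbourhood stabilizes the diffusion operator at these sizes.

### Differential expression and enrichment

`welch_de` computes, per protein with at least 3 observed values in each
group, the two-sided Welch statistic with Satterthwaite degrees of freedom
on the **log2 layer**, excluding missing values; BH correction runs across
tested proteins only. Fold changes come from the **pre-log normalized
layer** (ratio of group means). The two layers serve different purposes by
design: log2 values stabilize the t-statistic, while pre-log means give
fold changes on the measurement scale. Proteins failing the minimum-values
rule are reported `tested = FALSE`, not dropped.

`hypergeom_enrichment` uses the upper tail $P(X \ge k)$ (over-representation
only), BH across terms; a term absent from the foreground gets $p = 1$.

`trajectory_protein_selection` clusters the cell graph with leiden
(modularity objective, resolution 1 by default — unstated upstream, so a
package default) and Welch-tests each community against the rest on the
normalized, non-imputed data. A protein is kept when, in any community, it
is detected in ≥ 200 cells, moves by ≥ 0.15 absolute log2FC and clears the
5% level (BH-adjusted by default; a switch allows raw p). If only one
community is found the function warns and falls back to variance ranking.
`protein_cluster_signatures` clusters selected proteins hierarchically
(correlation distance, average linkage — a pattern-based choice, since the
upstream method names neither) into 5 clusters, smooths over the
pseudotime ordering with a 50-cell moving average (truncated, shrinking
windows at the edges rather than padding), min-max normalizes each protein
to $[0,1]$ (constant rows map to 0), and aggregates cluster means into
signatures.

### Replicate evaluation

Technical replicates of one pooled sample are equalized per protein: each
replicate is scaled so its median across single-cell channels equals the
median of those medians (the common target — the most symmetric choice).
The CV of protein $p$ in channel $j$ is the **sample** standard deviation
(ddof 1, appropriate at $n = 3$) of the normalized values across replicates
divided by the mean of the **raw** values; a channel must be observed in
every replicate to contribute, and only proteins quantified in all
replicates enter the %CV < 20% summary, computed on the per-protein mean
CV. Fold-change agreement with a bulk reference supports complete-case,
shared and top-N-coverage protein selections; binned fold-change error uses
equal-count bins over mean log2 s/n (quantile binning keeps per-bin sample
sizes equal; configurable).

### Integration of unbalanced datasets

Median equalization assumes every file carries the same population mix;
unbalanced designs (e.g. a marker-enriched plate next to an unsorted one)
violate it. `coverage_filter` first restricts each dataset to proteins with
≥ 40% valid values. The built-in `mnn_simple` backend then: imputes and
scales **within** each dataset (per-batch centring removes any global
dataset shift outright and keeps batch variance out of the per-protein
scale factors), projects the shared-protein matrices into a joint PC space,
finds mutual-k-nearest-neighbour cell pairs between the largest dataset and
each other, deduplicates to each target cell's closest partner (which makes
duplicated data map exactly onto itself), rejects pairs farther than three
times the median within-batch neighbour distance (the signature of
populations with no counterpart, raising an informative error when nothing
survives), and translates target cells along a Gaussian-smoothed correction
field whose bandwidth is the median target–anchor distance — wide enough to
average out pair-matching noise while still bending for local shifts. A
`panorama` backend delegates to an external panorama-stitching
implementation supplied by the user via `backend_fn`.

## The synthetic-data generator

`simulate_dataset()` draws: a latent differentiation coordinate
$\tau \in [0,1]$ per cell (three Gaussian populations with 5/5/4 mixing by
default, matching the balanced channel split, or a uniform continuum);
per-protein baseline log2 abundance $\mathcal{N}(4, 1.5^2)$; trajectory
effects on 10% of proteins, slope ±1.5 log2 over the $\tau$ range, plus two
dedicated markers (CD34 falling, CD38 rising, slope 2.5) whose FACS
counterparts are monotone transforms of $\tau$ with log-normal noise.
Trajectory effects are **compositional**: after applying the slopes, each
cell's total is rescaled to a size factor drawn independently of $\tau$
(log-normal, $\sigma = 0.15$). Cell size varying independently of
differentiation stage is the realistic regime; without the rescaling a few
strong markers make total proteome content trend with $\tau$, and the
median shift then writes an artifactual trend into every null protein.

Technical structure: scalar per-file ($\sigma = 0.3$) and per-channel
($\sigma = 0.2$) log-normal factors; log-normal measurement noise with
$\sigma = 0.15$ at the 500 ms reference injection time, scaling as
$\sqrt{\mathrm{IT_{ref}}/\mathrm{IT}}$ while the signal scales with
$\mathrm{IT}/\mathrm{IT_{ref}}$ — longer ion sampling collects more signal
and tightens precision; logistic detection
$P(\mathrm{obs}) = \mathrm{logit}^{-1}(-2 + 1.2 \log_2 t)$, rising in
abundance; empty wells carrying only ambient background (0.3 s/n) plus any
configured booster bleed; doublets as pre-noise sums of two cells' true
abundances (two cells occupy the well before measurement). Booster bleed is
an additive fraction $\lambda = 0.002$ of the booster signal (200 cell
equivalents mirroring the mean cell) into the adjacent 127C channel — the
channel left empty in the plate design for precisely this reason; the
magnitude is a free parameter, not a published value, and the affected
channel set is configurable. `simulate_technical_replicates()` shares one
true 14-channel pooled sample across all injections; only the
per-replicate loading factor, the IT-dependent noise and the detection
depth differ.

What the generator does **not** emulate: peptide-to-spectrum ion
statistics, co-isolation interference, full isotope-impurity envelopes,
peptide-to-protein rollup, FAIMS gas-phase fractionation, or correlated
protein modules beyond the single latent axis. Passing tests therefore
demonstrate that the pipeline recovers the structure this model injects at
realistic noise; they cannot certify behaviour under distortions the model
omits.

## Problem sizes and seeds

The test suite and the acceptance script run at desk scale: 500 proteins ×
280 cells (20 files × 14 channels) for factor recovery, 500 cells for
trajectory recovery, 400-cell experiments split into two batches for the
integration contract, 1000 proteins × 3 seeds for null calibration, and
100 random 8-protein × 10-cell instances for the imputation oracle. These
sizes were chosen so each property is measured with adequate power while
the whole suite stays quick to run; all randomness flows from explicit
seeds and every simulation is deterministic given its seed.

## Known limitations

* Median equalization assumes each file and channel carries a comparable
  population mix; it is restricted to balanced plate sets, and unbalanced
  designs must go through `integrate_unbalanced()`.
* The convergence criterion in absolute s/n units is scale-dependent by
  intent; rescaled inputs need a rescaled threshold (or the ratio metric).
* kNN imputation shrinks low-coverage proteins toward their observed means;
  fold changes and DE deliberately bypass imputed values, but embeddings do
  not.
* The `mnn_simple` correction is a translation field; it cannot repair
  batch differences in covariance structure.
* With a single leiden community the trajectory selection falls back to
  variance ranking, which has no significance control.
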