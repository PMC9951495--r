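---
title: "Reconstructing 3D chromosome configurations from multi-way SPRITE contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D chromosome configurations from multi-way SPRITE contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spritemds)
```

## The problem

Distance-based 3D genome reconstruction takes a bin-by-bin contact matrix
$C$, converts contact counts to dissimilarities, and solves for coordinates
whose Euclidean distances best match them. Hi-C produces strictly pairwise
contacts, so $C$ is immediate. SPRITE instead captures *clusters*: sets of
$k$ loci that co-occupied one spatial complex ($k$-mers). Before any
distance-based method can be applied, every $k$-mer must be decomposed into
its $\binom{k}{2}$ pairwise components, and there is no single canonical way
to weight those components. This package implements the full comparison
pipeline for three weighting schemes:

* **U-W** (under-weighting): each pair from a $k$-mer adds $2/k$ to $C_{ij}$;
* **N-W** (neutral-weighting): each pair adds $1$;
* **O-W** (over-weighting): each pair adds $k(k-1)$.

At $k = 2$ the schemes coincide up to a global factor (U-W $=$ N-W $= 1$,
O-W $= 2$), which is why a corpus dominated by 2-mers constrains all three
reconstructions to be similar — the mechanistic core of the
scheme-insensitivity phenomenon the pipeline measures.

Clusters are binned at fixed resolution (default 25 kb) with duplicate reads
per bin counted once, so $k$ is the number of distinct bins touched;
clusters whose reads all fall in one bin are retained as 2-mers (they
increment only the diagonal, which reconstruction ignores). Only clusters
with at least two intra-chromosomal reads qualify, and a MAPQ $\ge 30$
filter is applied where the input carries mapping qualities.

## From contacts to coordinates

Counts become dissimilarities by a power law, $D_{ij} = C_{ij}^{\alpha}$
with $\alpha = -1/3$ by default (the volume-scaling argument: contact
frequency $\propto d^{-3}$), $-1.08$ available as the conventional
alternative. Zero-count pairs and the diagonal are *unobserved*: they get
MDS weight 0 rather than an imputed distance, keeping the stress
well-defined without inventing data. Observed pairs get weights
$w_{ij} = 1/D_{ij}$ (inversely proportional to distance; the exponent is a
parameter, `weight_power`, for sensitivity runs, with 0 giving unweighted
stress).

`smacof_mds()` minimises the weighted raw stress
$\sigma(X) = \sum_{i<j} w_{ij}\,(D_{ij} - d_{ij}(X))^2$
by majorization: each iteration applies the Guttman transform
$X \leftarrow V^{+} B(X)\, X$, where $V$ is the Laplacian of the weight
graph and $B(X)$ its counterpart built from $w_{ij} D_{ij}/d_{ij}(X)$. The
update never increases $\sigma$, so the stress trace is monotone — asserted
on every run in the test suite. Design choices:

* **Raw stress, not stress-1.** Normalised variants have the same
  minimisers; raw stress keeps the Guttman update in its standard form.
* **Pseudo-inverse once.** For a connected weight graph,
  $V^{+} = (V + J/n)^{-1} - J/n$ ($J$ the all-ones matrix); computed once
  per matrix and reused across iterations.
* **Deterministic default initialisation.** Classical scaling on the
  observed dissimilarities, with unobserved entries filled by shortest-path
  distances over the observed graph. On perfectly embeddable full input
  this is already optimal; on partial input it is a reproducible,
  restart-free starting point. Random starts (`init = "random"`,
  `n_restarts`) remain available.
* **Convergence** at relative stress decrease below `rel_tol` (default
  1e-6), capped at `max_iter` (default 1000). A disconnected observation
  graph is an error naming the component sizes: no distance information
  links the components, so the embedding would be arbitrary.

Reconstructions are compared after reflection-similarity Procrustes
alignment (`procrustes_align()`): the query configuration is mapped onto the
fixed target by the closed-form SVD solution over translation, rotation,
reflection and scale, and the residual
$\mathrm{RMSE} = \sqrt{\min \sum_i \lVert x_i - T(y_i)\rVert^2 / n}$ is the
disagreement measure. The convention is deliberately asymmetric
(query-onto-target) because the pipeline uses the N-W reconstruction as the
referent target; the output records it. Degenerate queries (all points
coincident) are rejected.

## The comparison pipeline

`run_comparison()` executes, per chromosome: bin clusters → build the three
weighted matrices (optionally balanced) → transform → reconstruct with
*matched* MDS seeds and initialisation across schemes (so RMSE differences
reflect weighting, not optimisation noise) → align U-W and O-W onto N-W.
Chromosome-level covariates are computed from the same binned clusters that
fed the matrices: percentage of many-contact clusters ($k > 3$ and
$k > 10$), percentage of long-range clusters (span above the pooled upper
quintile and decile), and chromosome length. Span quantiles are pooled
across chromosomes *before* per-chromosome features, so "long-range" means
the same physical span everywhere; quantiles use linear interpolation
between order statistics (type 7), fixed because quintile membership feeds a
headline covariate. Spans are measured between bin indices (differing from
read-level spans by under one bin width and reproducible from the binned
representation alone).

Per-chromosome RMSEs are regressed on each feature by OLS, unadjusted and
adjusted for chromosome length, with two-sided t-test p-values; no
multiple-testing correction is applied (raw p-values are reported, as is
conventional for this analysis — treat them descriptively). Chromosomes
that fail (e.g. a disconnected contact graph) are skipped with a recorded
reason, never aborting the run; chromosomes with zero clusters are excluded
from regressions.

Matrix balancing (`balance_matrix()`) is a generic symmetric iterative
proportional fitting that equalises row sums (target: unit mean row sum,
tolerance 1e-6, 200 sweeps), serving the role that dedicated Hi-C
correctors play; all-zero rows are excluded and preserved. The primary
analyses run unnormalised — the comparison is within-sample and
scheme-to-scheme — with balancing available as a sensitivity switch.

`run_hic_comparison()` sends a Hi-C matrix through the identical
transform/MDS path (same $\alpha$, same MDS settings, same seeds) and uses
it as the Procrustes target for the three SPRITE reconstructions, reporting
the per-chromosome winning scheme.

## What the synthetic generator emulates

Every stage is testable without downloads because `synthetic_config()` /
`generate_backbone()` / `simulate_sprite_clusters()` / `simulate_hic()`
generate data with known 3D ground truth:

* **Backbone**: cumulative 3D Gaussian steps smoothed by a moving average
  (`smoothing_window`, default 5 bins) — a locally stiff curve that folds
  back on itself globally.
* **Cluster sizes**: 75% 2-mers, 12% 3-mers, and a $k^{-3}$ tail over
  $4..k_{\max}$ carrying the remaining 13%. The tail exponent is calibrated
  so that clusters of order above 10 are ~15% of all multi-way clusters,
  matching the composition observed in deposited GM12878 SPRITE data;
  $k_{\max} = \min(50, n_{\mathrm{bins}}/4)$ keeps a complex a bounded
  fraction of the territory.
* **Cluster membership is spatial, not genomic.** An anchor bin is drawn
  with probability proportional to its total contact propensity
  $Z_b = \sum_{b'} K(d_{bb'})$, then $k-1$ distinct members with
  probability $\propto K(d_{b,\mathrm{anchor}})$. The default kernel is the
  softened inverse power $K(d) = (d^2 + bw^2)^{-3/2}$, so expected 2-mer
  counts decay as the inverse-cube law that the $-1/3$ transform inverts; a
  Gaussian kernel is available (`proximity_kernel = "gaussian"`).
  Propensity-weighted anchors matter: uniform anchors would stamp an
  additive $1/Z_i + 1/Z_j$ coverage bias onto every expected pair count —
  a bias that row/column balancing *cannot* remove (it is not
  multiplicative) and that corrupts reconstruction benchmarks. Because
  membership is spatial, multi-way clusters naturally straddle large
  genomic distances wherever the backbone folds back; the span-versus-order
  pattern emerges rather than being hard-coded.
* **Bandwidth** (`proximity_bandwidth`, default 3 length units against a
  backbone step scale of ~1 and an RMS radius of ~11 at 200 bins): the
  complex is small relative to the territory, large enough that mid-range
  contacts are informative.
* **Hi-C counts**: independent Poisson draws with mean
  $\propto d^{-3}$ calibrated to a total coverage; diagonal zero.
* **Randomness**: one master seed; each stage derives its own stream, so
  adding a stage never perturbs another stage's draws.

What it does **not** emulate: polymer physics, TADs/loops/compartments,
ligation noise, barcode collisions, diploid ambiguity, inter-chromosomal
contacts. Passing tests therefore demonstrate correctness of the
*pipeline machinery* and its behaviour under a known spatial generative
model — not biological realism of any particular reconstruction.

## Study sizes and known limitations

Test and demonstration runs use 40–200 bins and $10^3$–$3\times10^5$
clusters per chromosome, sizes at which the full three-scheme comparison
completes in seconds to a couple of minutes on one core.

Two limitations are worth stating plainly, both measured with this package
and both consequences of the multi-way decomposition itself:

* **Hub flattening.** Every pair inside one $k$-mer receives the same
  increment regardless of that pair's own distance, so multi-way
  decomposition flattens the count–distance profile. The effect grows with
  the weight given to large clusters: at dense synthetic coverage the
  backbone-recovery error is ~16% of the RMS radius for U-W, ~26% for N-W
  and ~42% for O-W (distance correlations 0.99/0.98/0.93), and the
  corresponding effective count-decay exponents are visibly shallower than
  the 2-mer kernel's. This is the same distortion that motivates $2/k$
  down-weighting in the first place: U-W recovers best precisely because it
  suppresses hub contributions. A single high-fidelity recovery bound
  cannot hold for all three schemes at once — the schemes genuinely differ
  in geometric fidelity, which is the point of comparing them.
* **Smooth-mode similarity.** Independent smoothed random walks share their
  dominant low-frequency shape modes, so even reconstructions of unrelated
  backbones align with non-trivial fidelity. Negative controls in the test
  suite therefore compare against the *average* over several independent
  backbones rather than a single draw.

Smaller numerical decisions: counts of zero stay unobserved rather than
becoming large imputed distances; the diagonal never enters the stress;
self-alignment of the referent is reported as a computed (numerically zero)
self-check row rather than a hard-coded 0; exact ties in
`region_dominance()` mean "not a strict maximum", and on a symmetric matrix
windows are enumerated above the diagonal band only, since every
below-diagonal window mirrors one above it and would always tie.
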