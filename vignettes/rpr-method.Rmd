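---
title: "Recurrence-plot-based reconstruction of 3D chromosome structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence-plot-based reconstruction of 3D chromosome structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpr3d)
```

## The problem

Single-cell Hi-C detects which pairs of genomic loci were spatially close in
one nucleus. The data are extremely sparse — each contact is essentially seen
once or not at all — so methods that model read counts have little to work
with, and stochastic-optimization reconstructions return a different structure
on every run. `rpr3d` takes the opposite route: it treats the binary contact
map as a *recurrence plot*, the nonlinear-dynamics object that records, for a
trajectory \(x_1, \dots, x_n\), whether every pair of states is within a
threshold of each other:

\[
R(i, j) = \begin{cases} 1 & \lVert x_i - x_j \rVert \le \varepsilon \\
0 & \text{otherwise.} \end{cases}
\]

Reading chromosome position as the "time" axis makes a Hi-C contact map and a
recurrence plot the same object, and a deterministic machinery exists for
inverting recurrence plots back into a metric space. The pipeline recovers a
*unique* 3D structure from contacts alone — no read counts, no binarization
threshold, no random restarts.

## The method

1. **Binarize.** Any pair of segments detected as neighbors at least once gets
   a 1; the diagonal is always 1. Counts are discarded (`binarize()`); the
   same rule serves single-cell and ensemble Hi-C.
2. **Backbone.** Consecutive bins on a chromosome are declared neighbors,
   \(R(i, i+1) = 1\) (`add_backbone()`). This encodes the polymer continuity
   of the fiber and guarantees the contact graph of each chromosome is
   connected — the method's one structural precondition. For toy
   trajectories the same augmentation joins successive time points.
3. **Local distances.** Every contact becomes a graph edge weighted by the
   Jaccard distance between the two *neighbor sets*
   \(G_i = \{k : R(k, i) = 1\}\):
   \[
   d(i, j) = \frac{\lvert G_i \,\triangle\, G_j \rvert}
                  {\lvert G_i \cup G_j \rvert}.
   \]
   Two loci in contact whose neighborhoods coincide are locally
   indistinguishable (distance 0); the less their neighborhoods overlap, the
   closer the weight gets to 1. Unlike a constant edge weight (the
   `mode = "constant"` variant, which this package also provides), the
   neighbor-set weight lets every edge borrow information from the whole
   column of the contact map, which is what makes the method usable at
   single-cell coverage. Neighbor sets are computed on the
   backbone-augmented matrix, so backbone edges carry ordinary neighbor-set
   weights like any other edge.
4. **Metric completion.** Global distances are all-pairs shortest paths over
   the weighted graph (`all_pairs_shortest()`, Dijkstra by default, Johnson
   above 2000 nodes — with non-negative weights the two are exact and
   identical, so the choice is purely a speed matter).
5. **Classical MDS.** The squared distance matrix is double-centered,
   \(B = -\tfrac12 J D^{\circ 2} J\), eigendecomposed, and the three largest
   positive eigenvalue components give the coordinates
   (`classical_mds()`). Everything upstream is deterministic and the
   eigendecomposition is made sign-canonical, so `reconstruct()` is
   reproducible to the byte.

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `resolution` | `make_bins()` | 250 kb | genomic bin width; rows/columns of the map |
| `mode` | `reconstruct()` | `"rpr"` | neighbor-set weights vs constant weights |
| `algorithm` | `reconstruct()` | `"auto"` | Dijkstra, Johnson above 2000 nodes |
| `ndim` | `reconstruct()` | 3 | embedding dimension |
| `epsilon` / `target_rate` | `recurrence_plot()` | — | closeness threshold, or the fraction of pairs to plot |
| `flip_rate`, `loss_rate` | `corruption_spec()` | 0, 0 | false-contact rate per pair; deletion rate per contact |

There is deliberately **no** read-count threshold and no balancing
(ICE/KR-style normalization would reintroduce the coverage information the
method is designed to ignore).

## Numerical choices

* **Negative MDS eigenvalues.** Shortest-path metrics are usually not exactly
  Euclidean, so \(B\) has negative eigenvalues. They are never selected; if
  fewer than `ndim` positive eigenvalues exist (e.g. collinear
  configurations, or extremely sparse maps whose completed metric is almost a
  line), the remaining axes are zero-padded with a warning.
* **Sign canonicalization.** Eigenvectors are sign-ambiguous; each axis is
  flipped so its largest-magnitude coordinate is positive, which is what
  delivers byte-level determinism. Eigenvalue ties are left in the stable
  order LAPACK returns them.
* **Zero-weight edges.** Two nodes with identical neighbor sets get local
  distance 0. This is legitimate (they are indistinguishable at resolution
  \(\varepsilon\)) and harmless to Dijkstra, which requires only
  non-negativity.
* **Disconnected graphs** are refused with a component report rather than
  silently reconstructed per component: global distances between components
  would be undefined. The fix is `add_backbone()` (automatic for genomic
  maps in `reconstruct()`), per-chromosome reconstruction
  (`extract_region()`), or `drop_empty_bins()`.
* **Quantile thresholds.** `target_rate` converts a desired contact density
  into \(\varepsilon\) via the empirical quantile of the *off-diagonal*
  pairwise distances; including the zero diagonal would make small rates
  ill-defined. `keep_nearest_fraction(traj, f)` is exactly
  `recurrence_plot(traj, target_rate = f)`.

## What the synthetic generators emulate

`simulate_lorenz()` and `simulate_rossler()` integrate the classic chaotic
systems (fixed-step RK4 via `deSolve`, 1000-step burn-in) as stand-ins for
arbitrary smooth 3D objects: their recurrence plots are structurally the same
object as a contact map, so reconstruction quality can be scored against a
known ground truth. `synthetic_chromosome()` generates a momentum-correlated
random walk with unit steps (default 200 bins, smoothness 0.8, 250 kb bins) —
a minimal chromatin-fiber surrogate with local stiffness and global folding.

What these fixtures do **not** emulate: territory formation, loop extrusion,
A/B compartmentalization, unmappable regions, or the coverage biases of real
Hi-C libraries. Passing the packaged tests therefore shows that the
*inversion machinery* is correct and noise-tolerant, not that any particular
biological structure is recovered from real data; the reconstruct workflow
(`cmd_reconstruct()`, or the `inst/cli/rpr` script) applies the identical
pipeline to real pairs-format contacts when those are supplied.

## The corruption experiment and its operating point

The robustness experiment mimics single-cell Hi-C pathologies on toys: each
unordered pair is bit-flipped with probability 0.01 (false
positives/negatives), then each remaining contact is deleted with
probability 0.90 (sparse detection). One random draw per unordered pair keeps
the matrix symmetric; flips are applied before loss, so spurious contacts are
thinned at the same rate as real ones.

Two regimes behave very differently. Loss alone is almost harmless — the
clean-vs-degraded distance correlation stays near 0.97 even at 90% deletion,
because shortest paths reroute around missing edges. Random *flips* insert
false long-range edges that shortcut the metric, and their impact shrinks as
the recurrence rate grows (each false edge is then a smaller perturbation of
large neighbor sets). The package's documented operating point for the
corrupted-toy experiment is **1000 states at recurrence rate 0.30**, where
the median clean-vs-corrupted correlation over 10 corruption seeds is
~0.74–0.76 for both Lorenz and Rössler (recomputed by
`scripts/acceptance.R` and the acceptance tests); at a 5% recurrence rate
the same statistic drops to ~0.5. The rate of the original supplementary
experiments is not published, so it is exposed as an explicit parameter
(`--rate` in the CLI) rather than hard-coded.

"Correlation between original and noisy data" is implemented as the Pearson
correlation between the upper triangles of the clean-reconstruction and the
corrupted-reconstruction global distance matrices — an interpretation, since
the quantity could also be read as coordinate- or raw-data-based; the
distance-matrix reading is the only one that needs no arbitrary alignment.

## Downstream comparisons

* `distance_matrix_correlation()` — upper-triangle Pearson between two
  reconstructed distance matrices (the cross-cell statistic).
* `cross_resolution_correlation()` — block-averages the fine matrix to the
  coarse binning, then correlates; used to check that 250 kb and 500 kb
  reconstructions tell the same story.
* `local_3d_correlation()` — the "3D correlation coefficient" profile: for
  each genomic window (default 1 Mb, non-overlapping; a stride parameter
  allows overlap) the Pearson correlation between the two structures'
  intra-window pairwise-distance vectors. The published recipe for this
  statistic is in an unavailable supplement; the windowed pairwise-distance
  form was chosen because it is isometry-invariant, so no Procrustes step
  can bias it. Pearson is the default reading of "correlation coefficient";
  Spearman is an option.
* `radial_profile()` — per-bin distance from the centroid; protruding loops
  and telomeres appear as peaks.
* `cell_similarity_dendrogram()` — average-linkage (by default) hierarchical
  clustering on 1 − correlation, serialized as Newick.
* `procrustes_align()` — least-squares superposition for when coordinates
  (not distances) must be compared; reflection allowed by default because
  MDS output has no handedness.

## Problem sizes and limitations

The packaged experiments use 1000-state trajectories, 200-bin synthetic
chromosomes and 10 corruption seeds; at those sizes the full suite runs in
well under a minute, and the method scales to whole single-cell genomes at
250 kb (the Johnson all-pairs stage and the dense eigendecomposition dominate
beyond a few thousand bins).

Known limitations: zero-coverage bins are bridged by backbone edges by
default (collapsing them onto the fiber path; `drop_empty_bins()` is the
alternative); false-positive contacts are the dominant error mode at low
recurrence rates and the method has no long-path down-weighting to counter
them; and the embedding is defined up to rigid motion and reflection, so all
shipped comparison statistics are built on distances rather than raw
coordinates.
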