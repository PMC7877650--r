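---
title: "Growth-curve embeddings, fractal dimensions and cluster validation for planar point patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve embeddings, fractal dimensions and cluster validation for planar point patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalpp)
```

## The model

A planar point pattern — `n` points with metric coordinates inside a
*validity domain* (the region where the phenomenon can exist: a border
polygon minus exclusions such as lakes) — is characterized here through
one object: the **local growth curve** (LGC). For point $j$ and radii
$R_1 < \dots < R_d$,

$$N_j(R_i) = \#\{\,k \ne j : \lVert x_k - x_j \rVert \le R_i\,\},$$

the number of *other* points within the closed ball of radius $R_i$.
Three analyses hang off this single object:

* **Global sandbox dimension** $f_{sb}$: the OLS slope of
  $\log \langle N(R) \rangle$ vs $\log R$, where the counts are averaged
  over all points. For a homogeneous planar pattern far from boundaries
  $\langle N(R)\rangle \propto R^2$, so $f_{sb} = 2$; clustering lowers
  it. **Box counting** is the complementary estimate: occupied-cell
  counts $N(l)$ on regular grids scale as $l^{-f_b}$.
* **Local fractal dimension** (fDim): the same slope computed per point
  from its own curve. It maps local dimensionality: points on a
  filament-like stretch give $\approx 1$, plane-filling neighborhoods
  $\approx 2$; locally the slope may legitimately exceed 2 (a sparse
  point whose neighborhood fills in abruptly at large radii).
* **The embedding**: the $n \times d$ matrix of curves is a feature
  space in which points with similar multi-scale density environments
  are close, regardless of *where* they sit. Unsupervised clustering of
  this space groups points by the geometry of their surroundings.

Because every estimator is boundary-biased (balls leak out of the
domain; no edge correction is applied), observed patterns are compared
against **CSR simulated inside the same domain** with the same $n$,
rather than against the unconditioned theoretical value. The worked
example in the README shows that even pure CSR in a holed square yields
$f_{sb} \approx 1.90$, not 2 — that shift *is* the boundary signal, and
it is the correct reference level for data in the same domain.

## Morisita index, intrinsic dimension, redundancy

The multipoint Morisita index on a grid of $Q$ cells of edge $\delta$,

$$I_{m,\delta} = Q^{m-1}\,
  \frac{\sum_i n_i (n_i - 1) \cdots (n_i - m + 1)}
       {N (N-1) \cdots (N - m + 1)},$$

is $\approx 1$ for random, $> 1$ for clustered and $< 1$ for regular
patterns. For data supported on a $d$-dimensional manifold inside an
$E$-dimensional feature cube, the index scales as
$\delta^{(d-E)(m-1)}$, so with $S_m$ the slope of $\log I_{m,\delta}$ vs
$\log\delta$,

$$\mathrm{ID} = E + \frac{S_m}{m-1}.$$

The sign convention is pinned by a calibration property the test suite
enforces: uniform data in the full $E$-cube has $I \to 1$ at all scales,
slope $\to 0$, and must recover $\mathrm{ID} = E$ (checked for
$E = 1,\dots,5$ within $\pm 0.3$). A duplicated coordinate must *not*
raise the ID — which is exactly what makes the estimator useful for
**Morisita-based redundancy reduction** (MBRR): greedy forward selection
that at each step adds the feature maximizing the ID of the selected
subset and stops when the best gain drops below a threshold (default
0.05 ID units). Growth curves are heavily redundant (neighboring radii
nearly determine each other), so MBRR typically keeps a handful of radii
spanning local, intermediate and global scales; clustering in the
reduced space should approximately reproduce the full-space partition,
and `compare_full_vs_reduced()` quantifies that with the adjusted Rand
index.

## The clustering pipeline

The stages of `run_pipeline()` mirror the standard unsupervised-learning
methodology: preprocessing, redundancy analysis, clusterability, choice
of $k$, clustering, interpretation.

* **Preprocessing** (default `log1p` then per-feature z-score): raw
  counts span orders of magnitude across radii, and Euclidean clustering
  of raw counts is dominated by the largest radius. Both the transform
  and a `raw` option are exposed; the run report records the choice.
  Constant features are dropped with a warning rather than silently
  dividing by zero.
* **Clusterability**: Hopkins statistic
  $H = \sum u / (\sum u + \sum w)$ comparing nearest-neighbor distances
  of uniform probes (to the data) against sampled data points (to the
  rest). $H \approx 0.5$ for spatial randomness in the feature box,
  $\to 1$ for clustered data; the documented verdict thresholds are
  0.7 (clusterable) and 0.6 (uniform below).
* **Number of clusters**: one clustering method is fixed and five
  internal validity indices each vote for their best $k$: mean
  silhouette width (max), Calinski–Harabasz (max), Davies–Bouldin (min),
  gap statistic with uniform-box references (first-SE-max rule, argmax
  fallback), within-SS elbow (max second difference). Majority vote,
  ties toward the smallest $k$. This is deliberately a *mechanism* — a
  representative index subset rather than an exhaustive catalogue; every
  vote and score table is returned so disagreement is visible, and an
  index that fails at some $k$ forfeits its vote with a warning.
* **Clustering**: k-means (k-means++ seeding, Lloyd, 10 restarts), PAM
  (`cluster::pam`, BUILD+SWAP; medoids are actual curves, which makes
  centers interpretable), CLARA for large $n$ (PAM on subsamples that
  are forced to contain the incumbent medoids, winner judged on *all*
  points; classical defaults of 5 draws of size $40 + 2k$), hierarchical
  clustering (Euclidean, average linkage default — the common choice
  when no linkage is dictated; quadratic cost, so inputs above 10 000
  must be subsampled), and a classical online Kohonen SOM (hexagonal
  20×15 default grid, Gaussian neighborhood, learning rate
  0.5 → 0.01 and radius max(rows, cols)/2 → 1, both decaying linearly)
  whose codebook is then clustered and labels pass through each point's
  best-matching unit.
* **Interpretation**: per-cluster histograms of local fDim and of local
  density, the latter taken as the LGC column nearest a profiling radius
  (default 4000 length units — a mid-scale radius for kilometer-scale
  patterns; it snaps to the closest grid radius). Bins are
  Freedman–Diaconis on the pooled values and shared across clusters so
  the distributions are directly comparable; histogram totals must
  partition the cluster sizes exactly, and invalid-fDim points are
  counted, never silently dropped.

## Numerical conventions and degenerate inputs

* Sandbox and LGC counts use the **closed ball** and **exclude the
  center point**; both conventions are fixed and documented (gridded
  data can sit exactly at distance $R$).
* Log–log fits are plain OLS on natural logs; zero values are dropped
  via a `used_mask`, never offset by $+1$ — an offset biases exactly the
  small-radius end that carries the local signal. Rows with fewer than 3
  usable radii get `NA` fDim and a `valid = FALSE` flag; they are
  excluded from fDim histograms but keep their (well-defined) feature
  rows for clustering.
* Box-count scales default to 12 dyadic subdivisions of the longer
  bounding-box side; the fit window keeps scales with
  $1 < N(l) < n/10$. The upper cutoff matters: occupied-cell counts
  flatten toward $n$ well before reaching it, and fitting into that
  saturation plateau visibly biases the slope down (a CSR sample drops
  from 2.0 to ≈1.4 if the plateau is included). When the strict window
  leaves fewer than two scales, it relaxes to $N(l) < n$. Points exactly
  on the top/right bounding-box edge clamp into the last cell — a
  regular lattice otherwise opens a spurious extra cell row and reads
  ≈1.67 instead of 2.
* Morisita gridding min-max rescales features to $[0,1]$ (cells
  half-open, last cell closed; `rescale = FALSE` is available when the
  absolute layout matters). The $\delta$ grid is $2^{-1}, \dots, 2^{-5}$;
  the $Q^{m-1}$ factor is carried in log space (it overflows a double
  around $E(m-1) \gtrsim 1000$ bits while the log stays exact to
  rounding). Zero-index scales are dropped; among the two finest scales,
  those with mean occupancy of occupied cells below $m$ are also
  excluded — falling factorials on cells holding fewer than $m$ points
  carry no signal, only variance.
* Domain containment is closed-set: boundary points (outer ring *or*
  hole ring) count as inside, because gridded cell centers can lie
  exactly on borders. CSR uses rejection sampling from the bounding box
  — correct for arbitrary hole geometry at the cost of wasted draws
  proportional to the area deficit.
* All randomness flows from explicit integer seeds; SOM initialization
  and presentation order are generated on the R side so a seed fully
  determines the trained codebook. Every assignment method is
  deterministic under a fixed seed, and a pipeline run regenerates its
  artifacts byte-identically from the echoed config.

## What the synthetic generators emulate — and what they do not

The fixture generators provide ground truth the estimators must recover:
the Sierpinski triangle (chaos game; dimension $\log 3/\log 2 \approx
1.585$), a line (dimension 1), a lattice and in-domain CSR (dimension 2),
Gaussian blob mixtures with known labels, and a Thomas-style cluster
process. The test suite uses them at these scales: dimension
calibrations at $n = 10^5$, ID recovery at $n = 10^4$ per dimension,
oracle equivalence at $n \le 500$, pipeline recovery on 1 500-point blob
fixtures.

One design point deserves honesty. A growth-curve embedding clusters
points by their *density environment*, not their location. Three
identical blobs at the corners of an equilateral triangle are therefore
**indistinguishable** in LGC space — every blob sees the others at the
same distances. The pipeline-recovery fixture uses tight blobs at
*asymmetric* centers, with radii chosen between (not at) the inter-blob
distances, so each blob's curve is a distinct step function and the
three groups are cleanly recoverable. Real settlement data is never this
clean: growth curves vary continuously, cluster boundaries are fuzzy,
and the vote across validity indices is typically split rather than
unanimous. Passing these tests shows the machinery is correct and
calibrated; it does not promise that any particular real pattern has
three clusters.

Likewise, the local-fDim boundary contrast (boundary clusters are both
sparser and flatter than interior ones) emerges reliably only when
counts are large enough: with sparse curves the zero-dropping fit biases
fDim *upward* for exactly the low-density points, and at small $n$ this
bias can mask the edge effect. The property test therefore runs at
$n = 10^4$ with radii reaching the boundary-layer scale.

## Limitations

* No edge-corrected estimators: the domain-conditioned CSR comparison is
  the intended workflow, not correction factors.
* No multifractal spectrum, no functional-data treatment of the curves,
  no density-based/spectral/kernel clustering; the SOM is the standard
  Kohonen version without geographic constraints.
* Coordinates must be planar metric. Readers reject inputs that look
  like geographic degrees and ask for a projection; for legitimately
  unit-scale planar data the check is overridable (`assume_planar`).
* PAM and hierarchical clustering are quadratic in $n$ and guarded at
  10 000 points; CLARA and the SOM are the large-$n$ paths.
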