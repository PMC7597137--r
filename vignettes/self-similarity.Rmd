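---
title: "Shape self-similarity from BLS entropy profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape self-similarity from BLS entropy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blsentropy)
```

This vignette records how the package's statistics are defined, which
choices were genuinely open and how we resolved them, and what a green test
suite does and does not establish.

## The model

A silhouette is reduced to its boundary: an ordered, counterclockwise
sequence of planar nodes, closed (wrap implicit) or open. For each node we
form the star network joining it to every other node and score the branch
lengths with the branch length similarity (BLS) entropy

$$S = -\sum_{j=1}^{n} p_j \log p_j / \log n, \qquad p_j = L_j \Big/ \sum_k L_k,$$

so $S \in (0, 1]$ with $S = 1$ exactly at equal branch lengths. The
normalisation by $\log n$ cancels the logarithm base. Because $p_j$ is a
ratio of distances, the per-node profile of $S$ values is invariant under
translation, rotation and uniform scaling of the shape — the property the
whole approach leans on. Profile computation is $O(N^2)$; at the default
$N = 1000$ a profile takes well under a second.

Distances are Euclidean in the plane. Coordinates are real-valued so that
the invariance holds exactly for synthetic contours; traced pixel
boundaries are the integer special case.

## Self-similarity Γ

The profile is min–max normalised to $[0, 1]$ per profile (see
"Numerical choices"), split into $K = L/W$ consecutive non-overlapping
windows of $W$ values, and each window is summarised by its least-squares
slope against abscissae $0..W-1$. Two windows are *similar* when the
slopes agree in sign and the magnitude ratio
$\min(|w_1|,|w_2|)/\max(|w_1|,|w_2|)$ is at least $c$. Rows of the count
matrix repeat this at cyclic offsets $j\varphi$, $j = 0..\theta$ with
$\theta = \mathrm{LCM}(W,\varphi)/\varphi - 1$; row $j$ yields the
percentage $\gamma_j$ of similar unordered window pairs, and
$\Gamma = \max_j \gamma_j$.

Parameters, defaults, and why:

- **Window size $W = 20$** (profile samples). Small enough that the 20
  entropy values in a window are close to linear, large enough that the
  fitted slope is not noise. Sensitivity checks across lags found windows
  below ~15 overfit and above ~30 break linearity.
- **Lag $\varphi = 20$** (samples). Offsets between window tilings; values
  5, 10, 15, 20 behave statistically alike on smooth silhouettes, so the
  coarsest (cheapest) is the default. With $\varphi = W$ there is a single
  row ($\theta = 0$).
- **Threshold $c = 0.8$** (dimensionless, in $(0,1]$). Above ~0.95 almost
  no pairs qualify; below ~0.65 almost all do. $\Gamma$ is non-increasing
  in $c$ (a property test asserts this).
- **Profile length $L = 1000$** after arc-length resampling, divisible by
  $W$ so windows tile the profile exactly; the package refuses
  non-divisible lengths and tells the user to resample.

Design choices that were genuinely open:

- **Slope fitting.** The windowed slope is described procedurally as a
  gradient-descent fit; we use the closed-form ordinary least-squares
  slope, which is the unique fixed point of that descent and is
  deterministic.
- **Negative slopes.** The printed similarity rule divides the smaller
  slope by the larger, which exceeds 1 when both are negative. We restate
  it on magnitudes with a sign-agreement condition; on positive slopes
  this reproduces the printed rule exactly (including the boundary case,
  ratio $= c$ counts as similar).
- **Zero slopes.** Strictly, a zero slope is similar to nothing (the sign
  product must be positive), so a constant profile gets $\Gamma = 0$. An
  optional `flat_tol` lets near-flat windows match; the default is 0
  (strict).
- **Self-comparison.** The count matrix includes the trivial
  self-comparison so every entry is $\geq 1$, and the pair count
  $h_j = \sum_k (M_{jk}-1)/2$ removes it. We define the diagonal
  contribution as 1 even for a zero slope, keeping the matrix invariant
  intact.
- **Range of the max.** The max defining $\Gamma$ runs over the offset
  rows $j = 0..\theta$ (the set over which $\gamma_j$ is defined), not
  over window indices.
- **Open contours** get entropy profiles (the star construction needs no
  wraparound) but not $\Gamma$: cyclic window shifts are meaningless
  without a wrap, so `self_similarity` rejects open-contour profiles.

## Group statistics Q and Z

$Q$ between two equal-length profiles is the maximum Pearson correlation
over all cyclic shifts of one of them, computed via FFT cross-covariance
(cyclic shifts change neither mean nor variance, so one FFT product gives
the whole correlation-by-shift curve exactly). For each member $j$ of a
group, $\bar Q_j$ is the mean of $Q$ against the *other* members; then
$Z = \mathrm{BLS}(\bar Q_1, ..., \bar Q_G)/10$. $Z = 0.1$ exactly when all
members correlate equally with the rest.

Two notes:

- **$Q$ is never negative.** For mean-centred profiles the circular
  cross-covariances sum to zero over all $L$ shifts, so their maximum is
  $\geq 0$, with equality only when every shifted correlation vanishes
  (exactly orthogonal Fourier modes). The non-positive-mean error path in
  `group_z` is therefore a guard for degenerate inputs, not a practical
  code path, which resolves the question of whether $Q$ values can serve
  as branch lengths: they can.
- **The 1/10 prefactor** is kept literally (it reflects a group size of
  10); `prefactor = "size"` switches to $1/G$ for other group sizes.

## Classification in (Γ, Z)

The package classifies a shape by nearest group centroid in standardized
$(\bar\Gamma, Z)$ space. A held-out shape has its own $\Gamma$, but $Z$ is
a group-level quantity, so the shape's $Z$ coordinate relative to a
candidate group is defined as *the Z that group would have with the shape
appended* (all per-member mean-$Q$ values recomputed including it). A
shape that correlates like a member leaves $Z$ essentially unchanged; a
foreign shape adds an outlier branch and drags $Z$ down. Distances are
standardized by the across-group standard deviations of the centroid
coordinates (falling back to 1 when degenerate); exact ties go to the
earlier group in list order and are flagged. This rule is the package's
own choice — the separation of gesture groups in $(\Gamma, Z)$ motivates
it, but no particular classifier is canonical.

## The synthetic generators: what they emulate

- `make_segmented_line(n1, n2)` — two collinear equal-length segments with
  different node densities; the canonical probe for the node-density
  effect. The second segment is built as an exact mirror of a uniform
  grid, so equal counts give bitwise mirror-symmetric node positions.
- `make_triangle(n_ab, n_bc, n_ca)` — equilateral triangle with per-side
  densities (shared vertices counted once, so 100/120/120 gives 337
  nodes).
- `make_regular_polygon` — square/pentagon fixtures.
- `make_random_polygon(n_vertices, seed)` — sorted random angles, uniform
  radii in $[0.5, 1]$: star-shaped, hence simple, and fully seeded.
- `make_shape_groups` — a stand-in for a multi-class gesture dataset: one
  random-polygon template per group, members are the template with
  Gaussian vertex displacement of standard deviation 1% of the template's
  mean vertex radius, resampled to a common length of 1000. The 1% level
  is the stated boundary-noise amplitude of the scaled-down group
  experiment; it produces within-group $Q$ near 1 while keeping groups
  visually distinct.

What the generators do **not** emulate: pixelisation artifacts of real
silhouettes (anti-aliased edges, quantised densities along obliques),
occlusion, articulated deformation, or left/right mirror pairs — $\Gamma$
cannot distinguish a shape from its mirror image. A green leave-one-out
test on the synthetic groups therefore establishes that the statistics and
the classifier behave as specified under the stated noise model, not that
any particular real-world accuracy is reproduced.

## Numerical choices

- **Normalisation** is min–max per profile: the simplest map achieving the
  stated $[0,1]$ range. Profiles flat to within $10^{-12}$ (relative) are
  flagged `constant` and mapped to zeros instead of amplifying rounding
  noise; a flagged profile has $\Gamma = 0$ under the strict zero-slope
  rule.
- **Boundary tracing** is Moore-neighbour tracing with Jacob's stopping
  criterion, started at the topmost-then-leftmost foreground pixel, with
  orientation normalised to counterclockwise (positive signed area). The
  start convention only fixes the profile's phase: $\Gamma$ and $Q$ are
  invariant to cyclic shifts by construction.
- **Resampling** is linear interpolation at uniform arc-length stations,
  keeping the first node as phase origin. It can only shorten a polyline
  (chords cut corners); at 10 samples per vertex the loss is below 1% for
  mild corner angles but can exceed it for spiky star polygons — the test
  suite checks the 1% bound on regular polygons and monotonicity
  everywhere.
- **Zero branch lengths** (coincident nodes) are an error naming the node,
  not silently dropped: a coincident pair would inject $-\infty$ terms
  into the entropy.
- **Seeding**: all generators take explicit seeds, derive any sub-seeds
  deterministically, and restore the caller's RNG state.

## Limitations

- $\Gamma$ compares windowed *slopes* only; profiles that differ by a
  smooth vertical stretch within windows can score as similar.
- Symmetric shapes and their mirrors are indistinguishable in both
  $\Gamma$ and $Q$.
- The entropy profile is $O(N^2)$ per shape; very long profiles
  (say $N > 10^4$) get slow in pure R.
- Only the outer boundary is used: holes are ignored, and masks must
  contain a single 4-connected component.
- TIFF masks are not supported (no TIFF reader in the dependency set);
  use PNG, ASCII PGM/PBM, or CSV.
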