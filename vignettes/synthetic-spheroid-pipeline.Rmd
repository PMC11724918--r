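---
title: "Biophysically motivated synthetic 3D microscopy data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysically motivated synthetic 3D microscopy data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Training 3D segmentation networks for cultured spheroids requires instance
labels that are prohibitively expensive to annotate by hand. `spheroidsim`
generates synthetic nuclei/membrane training images whose *geometry* comes
from a biophysical simulation rather than from random object placement: a 3D
Cellular Potts Model (CPM) rearranges a real (or phantom) segmented cell
configuration under volume, surface and adhesion constraints, and synthetic
nuclei images with exact instance labels are derived from the simulated cell
borders. This vignette explains the models, the tunable parameters, the
numerical choices, and what the built-in phantom does and does not emulate.

## The Cellular Potts Model

Each lattice site (voxel) carries a cell id; id 0 is the surrounding medium.
The free energy of a configuration is

$$H=\sum_i \lambda_V\big(V_i-V_i^{t}\big)^2+\sum_i \lambda_A\big(A_i-A_i^{t}\big)^2
 +\sum_{i<j}J^{(c\text{-}c)}A^{(c\text{-}c)}_{ij}+\sum_i J^{(c\text{-}m)}A^{(c\text{-}m)}_i ,$$

with per-cell volumes $V_i$ (voxel counts), surface areas $A_i$
(boundary-pair counts), their targets, and contact energies between unlike
neighbours. Dynamics are label-copy Metropolis: a random site and a random
neighbour are drawn; copying the neighbour's label is accepted with
probability 1 if it lowers $H$ and $e^{-\Delta H/T}$ otherwise. One Monte
Carlo step (MCS) is $N$ attempts, $N$ the lattice size.

Parameter defaults are the best-ranked set of the calibration scan
($\lambda_V = 10$, $\lambda_A = 0.001$, $J^{(c\text{-}c)} = 2$,
$J^{(c\text{-}m)} = 55$, $T = 30$, Potts neighbour order 3, contact order 4,
1000 MCS). Neighbour "orders" follow the squared-distance shell convention
(order $k$ = all offsets with $\|d\|^2 \le k$, i.e. 6/18/26/32 sites);
simulation tools in this field configure shells this way without further
definition, so the convention is stated here explicitly.

Design choices where the model leaves room:

* **Targets by derangement.** Each cell's target volume/area is the *initial*
  volume/area of another cell, via a uniformly drawn derangement (rejection
  sampling until no fixed point). Every cell is therefore out of equilibrium
  at the start — guaranteeing dynamics — while the ensemble's volume/area
  distribution is exactly preserved.
* **Area bookkeeping.** $A_i$ is counted with the *contact-order*
  neighbourhood, so the area constraint and the contact terms see one
  geometry; the morphology module counts exposed faces the same way. The
  face/pair count overestimates areas of smooth objects (staircase bias);
  self-consistency across modules was preferred over unbiased area
  estimation.
* **Boundaries.** The box has fixed (no-flux) walls; sites beyond the wall
  count as medium in contact and area terms, but a copy source drawn beyond
  the wall is a null attempt. Allowing walls to *inject* medium would make
  boundary proposals asymmetric (up to 5 of 6 directions propose medium) and
  visibly distort the stationary distribution of small test systems.
* **Vanishing cells** are allowed; their constraint terms remain in $H$
  (penalising disappearance) and they score IoU 0 in the calibration metric.
* **Medium is unconstrained** and there is no connectivity constraint.

The Metropolis kernel maintains $V_i$, $A_i$ and the contact tallies
incrementally (Rcpp); the test suite checks every incremental $\Delta H$
against a from-scratch Hamiltonian recomputation, and checks the empirical
state frequencies of a minimal two-state system against
$e^{-H/T}/Z$. That toy is a $1\times1\times3$ lattice in which only the
middle site can flip between the two cells: the smallest system for which
label-copy proposals are exactly symmetric, which the Boltzmann comparison
requires. (No 2-*site* system has that property.) Because the per-MCS
occupancy samples are autocorrelated, the acceptance band uses the
Markov-chain variance $n\pi(1-\pi)(1+\rho)/(1-\rho)$ rather than the plain
multinomial variance.

## Calibration metric

A simulation run is scored against its own start by

$$m=\Big(\tfrac{1}{N_F}\sum_k W_k\Big)\cdot\Big(\tfrac{1}{N_C}\sum_i \mathrm{IoU}_i\Big),$$

where $W_k$ is the 1-Wasserstein distance between the per-cell distributions
of morphological feature $k$ (volume, surface area, V/A ratio, minor/major
axis, sphericity, eccentricity — in raw units) at start vs end, and
$\mathrm{IoU}_i$ measures how much cell $i$ stayed in place. Small $m$ wants
*distributions preserved* but *individual cells moved*. Note the product
form scores a completely frozen run ($W_k = 0$, IoU $= 1$) as $m = 0$ even
though freezing is undesirable; `metric_m()` therefore reports `mean_W` and
`mean_IoU` separately so freezes are detectable, and `grid_scan()` keeps
both columns in its ranking table. The grid scan runs the Cartesian product
of parameter lists (defaults: the calibration-scan values, 648 combinations)
with one shared target derangement and per-combination seeds derived from
the parameter values, so results are schedule-independent and duplicates are
bit-identical.

Feature conventions the source material leaves open, fixed here: axis
lengths are $4\sqrt{\lambda}$ from the eigenvalues of the voxel-coordinate
covariance (the ellipsoid-equivalent convention; exact for a solid cuboid's
side), eccentricity is the meridional form $\sqrt{1-\lambda_3/\lambda_1}$,
and features are computed after z-upsampling to isotropic voxels, so
absolute values can differ from pipelines that measure on anisotropic grids.

## Nucleus placement and imaging simulation

For each simulated cell (ascending label), a nucleus prototype — a masked
intensity subvolume — is drawn uniformly, rotated so its major principal
axis aligns with the cell's (skipped for sphere-like cells, axis ratio
< 1.05), and isotropically rescaled until its support volume is within 5%
(practically 1%) of `volume_ratio` × cell volume. Positions are drawn from
an isotropic Gaussian at the cell centroid with
$\sigma = \texttt{sigma\_frac}\cdot r_{eq}$; the first position where the
support overlaps the cell's *unoccupied* voxels by at least
`overlap_threshold` of its volume is accepted. Counting only unoccupied
voxels enforces the overlap rule and prevents nucleus–nucleus collisions in
one test. Budgets (`max_positions`, then `max_prototypes`, then skip the
cell) terminate pathological cells. Accepted intensity is max-blended with
the full mask (soft boundary), while labels keep only mask ∩ cell, with the
nucleus label equal to the parent cell label so all stage outputs stay
joinable. The mechanism parameters are exposed with defaults
`volume_ratio = 0.35`, `overlap_threshold = 0.8`, `sigma_frac = 0.25`,
`max_positions = 10`, `max_prototypes = 5` — values in the plausible range
for packed epithelial-like cells, since the procedure's source states the
mechanisms but not the numbers. Note that with `overlap_threshold` $= t$,
claimed nucleus volumes lie in $[0.95\,t\rho,\ 1.05\,\rho]\times V_{cell}$
by construction; only $t = 1$ pins them to the ratio itself.

The imaging simulation applies, in physical order: exponential depth
attenuation ($e^{-z/L}$, decay length in µm; the functional form is a
package choice, exposed in the config), separable Gaussian PSF blur
(normalised, truncated at $4\sigma$), block-average downsampling (labels
follow by majority vote, ties to the lowest label), and shot/read noise
$\mathrm{Pois}(I/g)\,g+\mathcal N(0,\sigma)$ clipped at zero. A neutral
configuration is the exact identity.

## Label-co-generating GAN objectives

The membrane-to-nuclei transformation uses a generator whose last layer
emits *two* channels — the nuclei signal $\hat y$ and a soft binary label
channel $\hat v$ sharing the decoder — plus an extra unconditional
discriminator $D_{Seg}$ that judges binary label masks only, so arbitrary
unpaired label pools can train it. The conditional objective is
$\mathcal L_{cGAN}+\mathcal L_{sGAN}+\lambda_{L1}\mathcal L_{L1}$; the
cycle-consistent variant adds the two domain terms, the $D_{Seg}$ term and
$\lambda_{cyc}(\|x-\tilde x\|_1+\|y-\tilde y\|_1)$. Losses are implemented
in the literal log form with $\varepsilon$-clamping ($10^{-7}$) — practical
trainers often substitute least-squares or BCE variants, but the log form is
the specified contract here, and backbone architectures are deliberately not
fixed: `smoke_train_harness()` accepts the objectives with a built-in
miniature base-R backend (affine generator, logistic discriminators,
finite-difference gradients) purely to demonstrate the objectives are
optimisable end to end. $\hat v$ is passed to $D_{Seg}$ soft
(unthresholded); $\lambda_{L1} = 100$ and $\lambda_{cyc} = 10$ follow common
image-to-image practice since no values are prescribed.

Post-processing to instance labels: threshold $\hat v$ (default 0.5),
subtract the binary membrane condition to split touching nuclei, binary
opening (ball radius 1 voxel) against artifacts, then assign each remaining
foreground voxel the simulated cell label underneath — foreground over
medium has no label and disappears automatically. Threshold and radius are
package defaults; the procedure names the steps but not the parameters.

## Quality measures

**KID.** Since pretrained feature networks are 2D, the Kernel Inception
Distance is computed slice-wise along each of xy, xz and yz and averaged
over the three directions, each direction averaging the unbiased polynomial
MMD² ($k(a,b)=(a^\top b/d+1)^3$) over random slice subsets (defaults: 20
subsets of 50, the usual subset convention). The default feature extractor
is a fixed random orthogonal projection of bilinearly resized slices to
$d = 64$ — deterministic and download-free; an InceptionV3 adapter can be
plugged in via the `fx` argument (weights are external to this package, and
slice resizing/normalisation for it are adapter options). For equal-sized
sets the estimator excludes matched-index cross pairs, the fully unbiased
paired form, which makes identical inputs score exactly zero; the price is
that the cross term depends on the row pairing (jointly reordering both sets
is safe). With unequal sizes the standard full-cross-sum form is used.

**SEG/DET.** Cell Tracking Challenge conventions: a ground-truth object
matches the predicted label covering a strict majority of its voxels; SEG is
the mean Jaccard over objects (0 when unmatched); DET uses the detection
AOGM with the standard weights (5 per required split, 10 per false negative,
1 per false positive), normalised by the cost of building the detection from
nothing. The whole-image-then-crop protocol scores a full-image prediction
cropped to the ground-truth patch, so objects truncated by the crop are
scored as cropped and objects outside the crop never count as false
positives.

## The phantom

Real spheroid recordings are not required: `make_phantom_spheroid()` samples
seed points uniformly in a digital ball and labels voxels by nearest seed
(ties to the lowest label). Voronoi cells intersected with a ball are
convex, connected and roughly isotropic — a reasonable stand-in for packed
spheroid interiors — and the construction is cheap and deterministic.
Prototypes are solid ellipsoids (semi-axes uniform in a configured range)
textured with Gaussian-smoothed white noise rescaled to [0.3, 1]. What the
phantom does *not* emulate: segmentation errors and irregular cell shapes,
necrotic cores and proliferation gradients, chromatin substructure, and
anisotropic acquisition artefacts. Tests passing on the phantom therefore
validate the *mechanics* of the pipeline (energies, bookkeeping, placement
rules, measures), not biological realism of any particular dataset.

## Problem sizes and numerics

The test suite and the acceptance script run everything at desk scale,
chosen so each stage still exercises its full code path: 16³–48³ lattices,
6–50 cells, up to 1000 MCS (a 48³ × 1000 MCS run is ~10⁸ attempt updates,
about 12 s via the Rcpp kernel), 10⁵-MCS toy chains for the equilibrium
check. Determinism is managed by one top-level seed from which every stage
derives an independent substream keyed by the stage name (FNV-1a hash), so
adding a stage never perturbs another stage's draws; all stochastic
operations draw from R's RNG and are reproducible from the logged seed.
Numerical tie-breaks are fixed throughout: nearest-seed ties and label
conflicts to the lowest label, majority-vote ties to the lowest label, scan
ranking ties lexicographic in the parameter tuple.

Known limitations: surface areas carry the face-count staircase bias;
`clean_labels()`'s final dilation grows labels by one voxel per application
(by construction, it is not idempotent); the temperature does not auto-scale
with lattice size, so absolute parameter transfer between very different
lattice scales is the user's responsibility; and the CPM kernel is
single-threaded.
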