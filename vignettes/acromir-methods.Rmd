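---
title: "Retrieval-based acromion typing: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-based acromion typing: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acromir)
```

## The problem

The acromion — the posterolateral extension of the scapular spine — is
conventionally typed by the shape of its undersurface on sagittal shoulder
MRI: Type 1 (flat), Type 2 (curved), Type 3 (hooked), Type 4 (convex).
Hooked and curved undersurfaces are epidemiologically associated with
rotator cuff tears, so a system that, given a query slice, retrieves the
most similar previously typed slices gives a radiologist immediate visual
context for the classification.

`acromir` implements such a content-based image retrieval (CBIR) pipeline
end to end: texture descriptors, supervised feature selection, a fused
searchable index, similarity ranking, and a precision–recall evaluation
harness. Because clinical shoulder MRI cannot be redistributed, the package
also ships a synthetic phantom generator that reproduces the *structure* of
the problem (four classes distinguished only by a ridge's lower contour) so
every stage is testable end to end.

## Pipeline

For a labeled database of `n` images the pipeline computes, per image:

* **HOG** — gradients by central differences (edge-clamped), unsigned
  orientations on $[0^\circ, 180^\circ)$ in 9 bins, $8\times 8$-px cells,
  $2\times 2$-cell blocks at one-cell stride with L2-Hys normalization
  (L2-normalize with an $\varepsilon$ guard, clip at 0.2, renormalize). At
  the 224-px working size this gives $27 \cdot 27 \cdot 36 = 26244$
  dimensions.
* **LBP** — each interior pixel is coded from its $3\times3$ ring
  (neighbor $\ge$ center, top-left neighbor as the most significant bit,
  clockwise), and the code image is pooled over a $4\times4$ spatial grid of
  256-bin histograms, each normalized to sum 1 ($4096$ dimensions).
* **Deep blocks** — any deterministic extractor with a declared output
  length can be registered; the pipeline treats the vector opaquely. The
  bundled `pool32`/`gradpool32` stand-ins (mean-pooled intensities and
  gradient magnitudes) exist so the two deep slots of the default layout are
  exercised without pretrained networks; they are plain image summaries and
  make no claim to CNN-like behavior.

Each block is then reduced by greedy **mRMR** — relevance is the plug-in
mutual information $I(X_j; Y)$ between the equal-width-discretized feature
and the class label, redundancy the mean MI with the already-chosen
features; the default criterion is the difference form (MID), with the
quotient form (MIQ) available — to 400 (HOG), 500 (LBP) and 400 per deep
block. The reduced blocks are concatenated and min-max normalized per
column, yielding the default $748 \times 1700$ index on the phantom
database. Selection and normalization are fitted once on the labeled
database and frozen; queries are projected through the stored selection and
normalization, so a database image queried against its own index reproduces
its row exactly.

Ranking uses either **Euclidean distance** (lower is closer) or **PSNR**
$10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$ in dB (higher is closer;
identical vectors give $+\infty$ and rank first). The top $K = 20$
neighbors are returned, ties broken by ascending image id.

Evaluation queries every database image leave-one-out and summarizes each
ranked list as an interpolated 11-point precision–recall curve: at grid
recalls $0.0, 0.1, \dots, 1.0$ the interpolated precision is the maximum
precision over observed points with recall at or above the grid value, and
AP is the mean of the 11 values. Class-level AP averages that class's
queries; dataset AP averages all queries unweighted.

## Conventions the literature leaves open

Several details are not fixed by common usage; the package pins them down
explicitly and tests them:

* **Working size 224 px.** Fixes HOG/LBP dimensionality and matches the
  canonical CNN input side. All descriptors consume the same canonical
  image: single channel, per-image min-max rescaled to $[0,1]$ (a constant
  image maps to all zeros so descriptors of degenerate inputs stay
  defined), bilinear resize, row-major with origin top-left.
* **HOG bin geometry.** Bin centers sit at integer multiples of the
  $20^\circ$ bin width with bilinear voting between adjacent centers
  (wrapping), so a pure horizontal gradient votes wholly into the first
  bin.
* **LBP pooling.** A single 256-bin histogram could never support a
  500-feature selection, so a spatial grid of per-cell histograms is used.
  The code image is two pixels narrower than the working size; the grid
  partition is therefore near-equal (cell sides differ by at most one
  pixel), which the per-cell normalization makes immaterial.
* **mRMR discretization.** Equal-width, 10 bins by default; a constant
  column maps to bin 0. The MI estimator is the empirical plug-in in nats.
  MID is the default criterion because it is the filter's original,
  fully deterministic form; all ties break to the lowest column index.
  One behavior worth knowing: because redundancy enters as a *mean* over
  the chosen set, an exact duplicate of an already-chosen feature is
  excluded at the second pick (its redundancy is its full entropy) but can
  legitimately win later picks once the mean is diluted by other selected
  features — the greedy step optimum genuinely re-admits it.
* **PSNR in feature space.** PSNR needs a peak value; per-column min-max
  normalization of the fused space makes `peak = 1` exact. This is the
  package's largest interpretive step, made deliberately and documented
  here. A consequence worth stating plainly: on equal-length vectors both
  Euclidean distance and PSNR are monotone transforms of the same MSE, so
  their rankings — and therefore their APs — coincide up to ties in this
  implementation. The test suite asserts this rather than hiding it;
  reported per-metric differences elsewhere in the CBIR literature must
  arise from choices (per-image PSNR, unnormalized inputs) that their
  authors rarely state.
* **Recall denominator.** By default recall is relative to the relevant
  items *within the retrieved list*, so every query's curve spans recall 0
  to 1 at depth $K$; the alternative database denominator (relevant in the
  database minus the query) is available via
  `pr_points(..., denominator = "database")` and is labeled in reports.
  Queries that retrieve nothing relevant contribute AP 0 rather than being
  dropped — dropping would inflate averages invisibly.
* **Self-exclusion.** Evaluation always excludes the query from its own
  candidate list (leave-one-out); ad-hoc queries via `cmd_query()` keep the
  query by default, which is a useful sanity check (it must rank first with
  infinite PSNR).

## The phantom generator

`generate_phantoms()` renders a bright ridge (intensity 0.85) on a dark
background (0.12) whose *lower contour* is the only class-bearing feature:
a straight line (flat), a shallow arc (curved), an arc ending in an
anterior downward hook (hooked), or a broad deeper bulge (convex). Rotation
and translation jitter are applied analytically before rasterization (no
resampling), edges are softened over ~1.5 px, and Gaussian intensity noise
(sd 0.05 by default — visible speckle at display contrast, roughly the
upper end of what leaves the classes cleanly separable) is added and
clipped to $[0,1]$. Jitter defaults (±3 px, ±3°) reflect the modest
patient-positioning variability of a protocolized sagittal acquisition.
Class counts default to 178/337/104/129 — the class balance of the clinical
cohort this pipeline targets — for 748 images in total, one per simulated
patient. The generator is a pure function of its configuration: the same
config and seed give a bit-identical dataset, and the session RNG is left
untouched.

What the phantoms do *not* emulate: anatomy beyond the single ridge,
intensity inhomogeneity, partial-volume effects, scanner-dependent noise
correlation, or any within-class morphological continuum. Passing tests on
phantoms therefore demonstrate that the machinery is correct and that the
pipeline recovers class structure when it exists; they say nothing about
clinical accuracy, and the near-ceiling APs on phantoms (the classes
differ by construction in exactly the feature the descriptors measure)
should not be read as expected clinical performance.

## Numerical choices

* Block L2-Hys uses $\varepsilon = 10^{-6}$ inside both square roots; a
  zero-gradient block maps to the zero vector.
* MIQ floors mean redundancy at $10^{-10}$ before dividing.
* The 11-point grid is compared against observed recalls with a $10^{-9}$
  slack so binary representation of `3/10` never drops a point.
* The persisted index stores float32 (with an MD5 checksum verified on
  load); reloaded matrices therefore differ from in-memory ones by up to
  ~$6\times10^{-8}$ per value. Exact row-reproduction holds for the
  in-memory index.
* The mutual-information kernels are compiled (C++) with logs of integer
  counts taken from a precomputed table; they are cross-checked in the
  test suite against the plain-R estimator to $10^{-12}$.

## Problem sizes used in the bundled checks

The test suite exercises small 64-px, 24-image configurations for unit
behavior and one full-scale build — 748 phantoms at 224 px with the
400/500/400/400 reduction — for the end-to-end properties (index shape,
leave-one-out bookkeeping at $K=20$, chance-level calibration against a
Monte-Carlo random-retrieval oracle, and above-chance signal for the fused
HOG+LBP index). The same full-scale computation is what
`scripts/acceptance.R` reruns from scratch.

## Known limitations

* DICOM ingestion is not implemented (PNG/TIFF only); single-frame DICOM
  export to PNG/TIFF is assumed upstream.
* PNG output is 8-bit; lossless round-trips use 16-bit TIFF.
* No approximate nearest-neighbor index: search is exhaustive, appropriate
  for databases of hundreds of images.
* The deep-feature slots are contracts, not networks; plugging in real CNN
  activations requires the user to supply an extractor function.
* With both bundled metrics monotone in MSE, metric choice cannot change
  rankings here (see above); the dual metrics exist for protocol
  compatibility and for extractors/metrics a user may add.
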