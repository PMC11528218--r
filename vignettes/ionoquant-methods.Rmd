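---
title: "Methods: segmentation, quantification and counting statistics for neuromast ionocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, quantification and counting statistics for neuromast ionocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionoquant)
```

## The problem

Neuromast-associated ionocytes are ion-transporting cells that insert in
pairs around the sensory organs of the zebrafish lateral line. Typical
experiments produce two kinds of data this package analyses:

* **multichannel confocal z-stacks** in which a Notch reporter labels the
  target ionocytes *and* the central support cells of the neuromast, so
  that the binarized cell masks fuse into one shared structure at the
  bottom of the stack; additional channels carry in situ (HCR) or
  transgenic fluorescence to be measured per cell;
* **count tables** of mature ionocytes and their progenitors over a fixed
  panel of ten neuromasts per larva, compared across ionic conditions
  (e.g. embryo medium versus deionized water).

## Segmentation model

The reporter channel is preprocessed as a fixed chain with the reference
parameter set recorded in every result:

1. **3D white top-hat**, box footprint 50 × 50 × 3 voxels (y, x, z). The
   residual of a grey-scale opening removes background structure larger
   than the footprint while passing nuclei (diameter ≈ 10–13 voxels at
   0.3 µm lateral sampling). The box is separable, so the filter runs as
   six 1D min/max passes in compiled code.
2. **Gaussian smoothing**, σ = 1 × 1 × 0.5 voxels, separable with
   reflective boundaries.
3. **Threshold at grey value 500** (16-bit range). The rule is inclusive:
   a voxel exactly at 500 is foreground. The threshold is a fixed grey
   value by design — reporter-positive nuclei sit several-fold above it —
   so segmentation is reproducible across images without per-image tuning.
4. **EDT shrink**: the exact 3D Euclidean distance transform (computed by
   the lower-envelope algorithm, in voxel units, deliberately ignoring
   anisotropy, and counting only background voxels inside the volume) is
   thresholded at 2: voxels closer than 2 to background are dropped. This
   narrows each mask and separates near-touching cells. A per-slice 2D
   variant is available (`edt_mode = "2d"`); the volumetric transform is
   the default.
5. **z-tracking with merge events**: the stack is traversed slice by slice
   (by default from the first slice towards the last, where the fused base
   sits; `traverse_from` flips this). Per slice, 2D connected components
   (8-connected by default) are linked to open trajectories by ≥ 1 voxel
   of (y, x) overlap with the previous slice. A component overlapping two
   or more open trajectories — or a previously merged region — raises a
   *merge event*: the participants end at the previous slice, and the
   merged component and everything it flows into stays unlabelled (label
   0, never measured). A component overlapping exactly one trajectory
   continues it; when one trajectory splits into several components the
   largest overlap continues it and the others open new trajectories (the
   symmetric counterpart of the merge rule); a component overlapping
   nothing opens a new trajectory. Final labels are trajectories with at
   least `min_object_voxels` (default 20, a speck filter; set 0 for the
   strictest behaviour) renumbered by first slice, then centroid.

Thresholding at a fixed grey value slightly dilates bright objects (the
smoothed edge crosses 500 outside the true boundary) while the EDT shrink
trims roughly two voxels back; at peak intensities four to five times the
threshold the two effects nearly cancel, which is the regime the synthetic
scenes emulate.

## Quantification model

Three measurement dialects coexist, matching how such data are analysed in
practice:

* **3D label means** — measurement channels are background-subtracted by a
  white top-hat with footprint (15, 15, 1) (per-slice lateral subtraction,
  no mixing across z) and averaged over each cell's voxels;
* **projection + ROI** — maximum intensity projection, rolling-ball
  background subtraction (radius 50 px), then the mean within a drawn ROI.
  The rolling ball is implemented as a grey opening with a spherical-cap
  (non-flat) structuring element; this is a dialect of the interactive
  tools' algorithm and may differ in minor boundary details, so its tests
  are tolerance-based;
* **raw paired** — for sibling-cell asymmetries, the brightest slice (or a
  projection of up to three brightest slices, ranked by slice sum within
  the ROI if one is given; `k` defaults to 1) is measured *raw*. No
  background subtraction is applied and the comparison is strictly
  pairwise within an image: `pair_asymmetry()` orders the two cells into
  high and low and reports their ratio; exact ties are flagged and broken
  deterministically by cell id. Display gamma has no code path into any
  measurement function — no such parameter exists in this module.

## Counting conventions

* a **progenitor** is a *foxi3a*-positive, *trpv6*-negative cell
  immediately adjacent to a neuromast with crescent morphology; a
  **mature** ionocyte is *foxi3a*- (or *foxi3b*-) positive and
  *trpv6*-positive, inside or invading a neuromast;
* singletons and pairs of progenitor cells both count as **one unit**.
  Pairing eligibility is a centre distance of at most one cell diameter
  (10 µm by default, configurable). The unit count is the minimal one:
  for up to 12 cells an exact maximum matching is computed by exhaustive
  branching (a neuromast carries only a few progenitors, so this is the
  operative path); beyond that a greedy nearest-neighbour pairing stands
  in. Greedy pairing alone can over-count units on chain-like layouts,
  which is why the exact matching is the primary rule;
* per-larva values are **means over the quantified neuromast panel** (ten
  neuromasts: five anterior, five posterior lateral line), so values below
  1 are meaningful; frequencies are the percentage of neuromasts carrying
  at least one unit;
* when replicates spread widely, per-larva values are **normalized by the
  mean of the control condition within the same replicate**, making the
  control mean exactly 1 per replicate.

## Statistical scheme

Two-group comparisons run a Kolmogorov–Smirnov check of each group against
a normal with the sample's own mean and SD; if both groups pass at 0.05
the comparison is a two-tailed unpaired *t*-test, otherwise a two-tailed
Mann–Whitney *U* test (exact p when both groups have ≤ 8 untied values,
normal approximation with tie correction otherwise). Paired data use the
Wilcoxon matched-pairs signed-rank test; identical paired samples return a
flagged degenerate result with p = 1. KS with estimated parameters is
known to be anticonservative as a normality test (it passes too easily);
it is implemented as stated because it is the field's common practice, and
a Lilliefors-corrected option (`method = "lilliefors"`) is provided. Note
that the gate only *selects* between two tests that both hold their level
under the null, so the overall type-I error of the adaptive procedure
stays near nominal even under skewed data — the test suite verifies
0.03–0.07 at nominal 0.05 under normal and lognormal nulls.

Multi-group designs run one-way ANOVA or Kruskal–Wallis as the omnibus
test. Post-hoc families: Dunnett's test against a control (via `multcomp`;
its single-step adjustment integrates a multivariate t by quasi-Monte
Carlo, so the stream is pinned to a fixed seed for reproducibility) or
Dunn's rank-based z tests with tie correction, all-pairs or versus the
control, with Bonferroni adjustment by default (Dunn's classical
correction; configurable). Both ANOVA+Dunn and Kruskal–Wallis+Dunn are
available because both phrasings occur in practice; the default for
control-anchored designs is ANOVA+Dunnett. Group summaries report
mean ± s.e.m. with s.e.m. = sd/√n.

## The synthetic-data generator

`generate_stack()` renders cells as **flat-top ellipsoids with a 1-voxel
Gaussian edge falloff** — a saturated nuclear reporter with edge blur, no
PSF convolution — plus an optional basal disc spanning the last few slices
into which all cells must dip (≥ 1 voxel overlap is enforced), a smooth
background plane, and scaled-Poisson shot noise plus Gaussian read noise
(variance = `poisson_scale` × signal + `read_sd`²). The ground-truth
instance label of a cell is its flat-top support; the edge falloff is
treated as blur *outside* the cell, so the true per-channel mean over a
cell equals its peak. Default scene parameters: 16-bit range, 0.3 µm
lateral / 0.9 µm axial sampling (3:1 anisotropy), lateral radii 5–6.5
voxels and axial radii 2.5–3, peaks 2000–2600 grey values (four to five
times the threshold, the near-cancellation regime described above),
background plane 40 + 0.3/voxel, `poisson_scale` 40–60 and `read_sd`
60–80, giving peak SNR above 5. Axis order is `(y, x, z)` — the natural R
array layout where slice `z` is `x[, , z]` — with the fused base at the
highest z indices.

`generate_count_experiment()` draws per-neuromast unit counts from a
**zero-inflated Poisson** (most neuromasts carry 0 or 1 unit; a
negative-binomial alternative is configurable): with probability
`zero_inflation` (default 0.2) a neuromast is empty, otherwise counts are
Poisson with rate = baseline (default 0.5 mature units) × condition
multiplier × optional lognormal replicate effect. Defaults mirror the
experimental scale: 18 larvae per condition, 10 neuromasts per larva.

For Monte-Carlo studies of the *statistical* stages (power of the 45-pair
asymmetry comparison, type-I rates, detection of a doubled count rate),
`simulate_pair_measurements()` works at measurement level: each pair
shares a lognormal image brightness (sd 0.4), the two cells differ by the
true ratio, each measured mean carries ~20% multiplicative noise, and the
high/low orientation is carried by an independent reporter designation —
under ratio 1 the designation is arbitrary, which is what makes the
type-I check meaningful. Image-level fidelity (that a true ratio survives
rendering, segmentation and measurement) is validated separately on full
stacks; repeating thousands of full renders would add nothing but time.

What the generator does **not** emulate: PSF anisotropy and diffraction,
spectral bleed-through, motion, autofluorescence texture, or segmentation
errors from touching nuclei of similar intensity. Passing tests therefore
demonstrate algorithmic correctness under the stated model, not
performance on arbitrary real acquisitions.

## Numerical choices and degenerate inputs

* even footprint entries are rounded **up** to odd so windows are centred;
* erosion/dilation ignore out-of-bounds positions (padding with ±∞), the
  standard border rule; the Gaussian uses half-sample symmetric
  reflection;
* the EDT counts only in-volume background (a mask touching the border is
  not eroded from outside), matching the common scientific-python
  semantics;
* thresholding is inclusive (≥); label 0 is reserved for background and
  merged voxels; all user-facing coordinates are 1-based (y, x, z);
* empty stacks segment to zero cells; an all-zero difference vector in the
  paired test is reported degenerate rather than an error; requesting a
  label absent from the volume, a zero control mean, or a Dunnett run
  without a control are errors.

## Problem sizes used in validation

The bundled validation experiments run on one CPU in a few minutes:
ground-truth recovery uses 20 stacks of 128 × 128 × 20 voxels with 2–6
cells; oracle-equivalence sweeps use 100 random masks up to 64 × 64 × 16;
EDT contracts use 50 masks around 20³; power studies use 200 simulated
experiments (2000 for type-I rates). These sizes give binomial standard
errors of ~1.5% on power estimates and ~0.5% on type-I rates, tight
enough for the accepted bands.

## Known limitations

* The rolling-ball implementation is a morphological dialect; absolute
  agreement with interactive tools is not claimed.
* The z-tracking linker uses plain overlap with no motion model; cells
  whose sections jump laterally by more than their radius between slices
  would fragment (not observed at 3:1 anisotropy with nucleus-sized
  objects).
* Counts are modelled independent across neuromasts within a larva;
  per-larva averaging absorbs within-larva correlation for testing
  purposes, and no mixed-effects model is fitted.
* OME-TIFF axis metadata is not parsed: stacks are read as one multi-page
  grayscale TIFF per channel.
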