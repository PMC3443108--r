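---
title: "Counting bead-labeled monocytes in multiphoton plaque mosaics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting bead-labeled monocytes in multiphoton plaque mosaics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquebeads)
```

## The measurement

Non-classical (Gr1-low) murine monocytes are pulse-labeled in vivo by
intravenous injection of 1-µm FITC latex microspheres, which the cells
phagocytose and carry into atherosclerotic plaques. The number of beads in a
plaque, counted some days later, measures subset recruitment. Imaging the
intact aorta by multiphoton microscopy replaces mechanical sectioning:
overlapping z-stacks (10 % overlap, 10 µm axial steps) tile the lesion, the
bead channel (490–530 nm emission; beads plus collagen/elastin
autofluorescence) is sum-projected per stack, bead-sized spots are detected
and counted, and duplicates in the tile overlaps are removed. Labeling
efficiency is verified beforehand by flow cytometry: live gate, CD115-high
monocyte gate, Gr1 split, FITC bead positivity.

`plaquebeads` implements this chain together with a seeded synthetic-data
layer, so every stage can be validated against planted ground truth without
any instrument data.

## Synthetic scenes

A scene is a three-channel voxel grid (`ceil(extent/step)` voxels per axis;
voxel `(i,j,k)` covers the half-open interval `[(i-1)s, is)`, so continuous
micron coordinates are 0-based at the volume corner). Channel textures are
phenomenological, not optical-physics simulations:

* **Collagen second-harmonic band** — random oriented line segments,
  laterally blurred: fibrous anisotropic texture.
* **Bead/autofluorescence band** — a diffuse level with low-frequency
  modulation plus faint fibers (elastin), and the planted beads.
* **Lipid band** — broad Gaussian blobs with a wide axial envelope.

Noise follows the standard photon-limited detector model: intensities are
scaled into photons (`photons_per_unit`, default 5), Poisson-resampled,
rescaled, and Gaussian read noise (default sigma 1) is added; results are
clipped at zero. The instrument's gain and noise figures are not known, so
these defaults are chosen to make the texture contrast and speckle scale
qualitatively plausible, and detection is required to cope with them rather
than being tuned around them.

### Bead model and axial visibility

A bead is a uniform disk of its physical diameter (1 µm) convolved with an
anisotropic Gaussian point-spread function. Laterally we use the
error-function edge model
$$I(r) \propto \Phi\!\left(\frac{R - r}{\sigma_\text{lat}}\right),$$
with $\sigma_\text{lat} = 0.3$ µm, which is ~1 at the centre and 0.5 at the
disk edge; axially a Gaussian with $\sigma_\text{ax} = 5$ µm. Two
constraints fix the axial width. First, the acquisition was designed so a
single bead is visible in at least two 10-µm-spaced sections; the
second-nearest plane can be up to 10 µm from a bead centre, and with
$\sigma_\text{ax} = 5$ µm it still receives
$\exp(-100/50) \approx 13.5\,\%$ of the peak — above the base detection
threshold (10) for the default peak amplitude (100). Second, low-NA deep-
tissue imaging shows pronounced axial elongation, which is exactly what the
best-focus correction exists to undo. A narrower PSF (e.g. sigma 2.5 µm)
would make an on-plane bead visible in one section only and contradict the
two-section property, so we treat the axial sigma as calibrated to the
instrument's stated behaviour. Beads are planted axially within
`[z_step/2, depth − z_step/2]` (the sampled plane range) and laterally with
a margin holding the full blurred profile in frame.

Distinct beads keep a minimum lateral separation of 3 µm (twice the upper
detection diameter bound). A fraction of beads — each bead independently
with probability `clump_fraction`, default 0.05 — is placed in clumps of
2–3 with centres within one bead diameter. The binomial realization matters:
rounding the expected clump count would silently give small plaques a zero
clump rate and bias cross-group comparisons.

## Detection

Each tile's bead channel is sum-projected, and the local background is
estimated with a median filter of radius 5 µm — robust to the beads
themselves, removes the diffuse autofluorescence and smooth texture.
Pixels exceeding background + threshold form 8-connected components.

**Sizing.** The component's equivalent-circle diameter is measured from the
pixels at the *half-peak-above-background* level (never below the
threshold), not from the raw threshold mask. The raw mask diameter of a
blurred bead depends strongly on the threshold/peak ratio, so a single
threshold could not simultaneously keep 1-µm beads and reject 2.5-µm
objects; the half-max footprint is threshold-independent and matches the
"observed size" the diameter bounds (0.5–1.5 µm) were chosen from.
Centroids are intensity-weighted over the half-max core, giving sub-pixel
accuracy (about 0.04 µm on noise-free beads at 0.25 µm/px).

**Clumps.** Over-size components are split when they contain 2–3 pruned
internal maxima (each at least half the component peak, pairwise separated
by at least the minimum diameter); flat plateaus produce many maxima and are
not split. Unsplittable over-size components up to 2.4 µm — the footprint of
2–3 clumped beads — are emitted once and flagged; anything larger is
rejected as a non-bead structure. Tightly clumped pairs therefore count as
one, an accepted limitation of the counting approach (fewer than 5 % of
beads are clumped, so the proportional undercount is ~2 % and identical
across groups).

**Threshold calibration.** The threshold is not a free constant: following
the method's own procedure, `calibrate_threshold()` (projection level) and
`calibrate_count_threshold()` (whole-sample level) scan a grid and return
the value minimizing the summed absolute disagreement with reference
("visual inspection") counts on representative data sets, ties toward the
smallest threshold. Count error, not per-bead matching, is the criterion
because reference counts are totals. On the default synthetic conditions
the calibration plateau is wide (15–40) and the procedure returns 15.

**Best focus.** For the 3D reconstruction, `best_focus_plane()` scans the
detection's footprint across planes and returns the axial argmax of mean
background-subtracted signal, provided it exceeds a stricter focus
threshold; ties break toward the lowest index.

## Mosaic and de-duplication

Tile offsets come from the stage model: step `round((1 − overlap) ×
extent)` pixels, row-major. No cross-correlation registration is performed
(the acquisition software places tiles; sub-pixel residuals are absorbed by
the merge radius). Stitched composites take the per-pixel maximum in
overlaps — a bead must not be dimmed by averaging against a neighbouring
tile's background — and record per-pixel provenance.

De-duplication merges detections from *different* tiles within a match
radius (default 1.5 µm, the largest accepted diameter: one bead cannot
yield two centres farther apart than its own size), keeping the brighter
member. The greedy pass runs in decreasing brightness with deterministic
tie-breaks, making the result idempotent and independent of tile order;
same-tile neighbours are never merged, since they are distinct beads by the
separation the detector enforces.

## Statistics

Per-group summaries use SEM = sd/√n (n−1 denominator); a singleton group
reports SEM 0 with a flag. The comparison statistics are the ratio of group
means (fold change), `100·(1 − mean_treated/mean_control)` (percent
reduction) with a first-order delta-method standard error
$$\mathrm{SE} = 100\sqrt{\left(\frac{s_t}{m_c}\right)^2 +
\left(\frac{m_t\, s_c}{m_c^2}\right)^2},$$
and a pooled-variance (Student's, not Welch) one-tailed t-test — the
directions (accumulation grows with time; statin reduces recruitment) are
fixed a priori, so the caller must state them. How the published ±9 % on
the reduction was computed is not stated; we adopt the delta method as the
standard propagation.

## Flow model and gating

Events are a multinomial mixture over latent classes (debris, non-monocyte
leukocyte, Gr1-high/low monocytes, bead-positive variants) with per-class
normal marker intensities. Class separations default to ≥ 8 pooled sigma on
the deciding markers, so rectangular gates (live gate in FSC/SSC, scalar
CD115/Gr1/FITC cutoffs) recover planted fractions up to binomial error —
real cytometry gates are polygons drawn on correlated, compensated data,
which this deliberately does not model. Bead positivity is confined to
Gr1-low cells by default (the labeling protocol labels non-classical
monocytes; very few beads appear in Gr1-high cells). Both denominators for
the bead-positive fraction are supported; the default reports bead-positive
Gr1-low cells as a percentage of all monocytes, the convention used when
quoting labeling efficiency.

## Problem sizes and tolerances

The validation suite uses desk-scale conditions chosen once: per-animal
scenes of 64 × 64 × 30 µm at 0.25 µm/px tiled 2 × 2 with 10 % overlap;
cohorts of 5 + 5 animals planted at mean 20 vs 60 beads (3-fold design) and
3 + 3 animals at 100 vs 63 (37 % reduction design), each replicated over 20
seeded cohorts; flow tables of 10,000 events. Stochastic recoveries are
asserted within 3 standard errors (binomial SE for gating fractions,
delta-method SE for ratios and reductions). Exact checks (projection
arithmetic, offsets, page counts, conservation laws) use identity or
floating-point tolerance.

## Limitations

* The synthetic textures emulate contrast, not optics: no refractive
  aberrations, depth-dependent attenuation, vignetting, or motion; passing
  tests show the algorithm chain is correct on its stated model, not that
  the defaults match any particular instrument.
* Clumped beads merge into single counts unless separable maxima exist;
  dense clumps undercount.
* Each ground-truth point is one bead; whether a cell carries several beads
  is not modeled.
* Tile placement is trusted; there is no registration refinement or
  flat-field correction.
* The FCS binary format is out of scope; event tables are CSV.
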