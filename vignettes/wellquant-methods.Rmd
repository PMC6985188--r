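---
title: "Methods: quantifying micropatterned pancreatic-endoderm colonies"
author: "wellquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying micropatterned pancreatic-endoderm colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement models, numerical choices and
validation design behind `wellquant`. The package quantifies multi-channel
immunofluorescence rasters of pancreatic-endoderm (PE) colonies confined on
circular adhesive microwells, plus unconfined monolayer fields, and it ships
its own synthetic image generator so that every estimate can be checked
against known truth.

## The measurement problem

A stained micropattern image carries four channels: a nuclear counterstain
(DAPI), the F-actin cytoskeleton (phalloidin), and two transcription factors
(PDX1, NKX6.1) whose *nuclear* accumulation is the biological readout. The
quantities of interest are

1. local cell density across **equal-area concentric zones** of each well,
2. per-nucleus mean TF intensity and the **nuclear:cytoplasmic (N:C) ratio**,
3. well nuclear intensity **normalized to the surrounding unconfined
   monolayer** (the in-image control), and
4. the radial **actin architecture class** of the colony
   (uniform / peripheral / central).

All geometry is carried in micrometres. Rasters use a 0-based pixel grid with
the origin at the centre of the top-left pixel, x rightward (columns), y
downward (rows); a centroid at 0-based pixel `(j, i)` is at
`(x, y) = (j, i) * pixel_size`. The default pixel size is 0.65 µm/px, typical
of a 10x objective on a standard scientific camera; every operation takes the
pixel size as data, so nothing depends on that default.

## Equal-area zoning

`equal_area_zones(R, K)` partitions the well disc into K annuli of equal
area; the closed form for the boundaries is `r_k = R * sqrt(k / K)`. K = 4
matches the standard four-ring spatial analysis of cell density. Zone
membership is decided by the nucleus centroid alone (the natural reading of
"nuclei enumeration"), with half-open intervals `[r_{k-1}, r_k)` and the
measure-zero case `r = R` assigned to the outermost zone, so membership is
deterministic. Densities are reported in cells/mm², the standard monolayer
unit. Discretized (pixel-counted) annulus areas agree with the analytic areas
to within 2% for wells of at least 50 px radius; the analytic area is what
density calculations use.

## Segmentation

Nuclei are segmented from the background-subtracted DAPI channel by Otsu
threshold followed by a distance-transform watershed that splits touching
nuclei. Two numerical choices matter:

* **Mask extent** (`mask_frac = 0.5`): the component mask is taken at half
  the Otsu level. The Otsu level itself sits high on the flank of a
  Gaussian-profiled nucleus, so thresholding at it would keep only the bright
  core (~0.7 of the true radius) — small nuclei would then fall below the
  debris area filter. At half the level the mask reaches ~0.9 of the true
  radius: still inside the nucleus (which keeps intensity measurements free
  of cytoplasmic contamination) but large enough to be robust.
* **Watershed tolerance** (0.5 px of the distance map): deep enough to avoid
  splitting single convex nuclei under modest noise, shallow enough to split
  pairs whose centre distance is ~70% of their summed radii.

A minimum-area filter (20 µm² by default) removes debris. Because published
workflows often rely on manually curated regions, `segment_nuclei()` also
accepts an externally supplied label raster and then only measures it.

The tissue mask — the cytoplasmic reference region — is the Otsu-thresholded
phalloidin channel after morphological closing and hole filling. Note that
when an image contains both the colony and the unconfined control ring, the
filled mask spans both (and the enclosed gap); the pipeline therefore
intersects the mask with the well disc for colony measurements.

## Background subtraction

`subtract_background()` offers a flat scalar estimate (a chosen percentile of
the image) and a morphological estimate (grayscale opening with a disc, the
flat-kernel rolling-ball analogue). The *pipeline* default is the flat
percentile (p25): a confluent colony is an intensity plateau hundreds of
pixels wide, and any morphological background with a ball smaller than the
colony absorbs the cytoplasmic plateau itself, which would push the measured
cytoplasmic mean toward zero and inflate N:C without bound. A flat estimate
matches the notion of subtracting "the average background fluorescence of
each image". The 25th percentile lies safely inside the background population
as long as background pixels make up more than a quarter of the image, which
holds for all canvas layouts the generator produces; under noise it sits
slightly below the background median, a sub-1% conservative bias. The
rolling-ball mode remains the right choice for uneven illumination over
fields of discrete objects, and is validated on exactly that case.

## N:C ratio and normalization

For each TF channel, per-nucleus means are taken over the segmented ROIs. The
cytoplasmic mean is defined by totals: channel total over the tissue mask
minus total over nuclear regions, divided by the corresponding pixel count;
per-nucleus N:C divides the nuclear mean by this shared cytoplasmic mean, and
the colony N:C uses the mean of nuclear means. Uniform intensity over the
mask gives N:C = 1 exactly, and the ratio is invariant under any positive
gain.

One refinement: segmentation ROIs end at the dim nuclear rim, so a thin ring
of genuinely nuclear signal would otherwise be counted as cytoplasm and bias
N:C low by ~10% at realistic nucleus sizes. The pipeline therefore passes a
*dilated* copy of the ROIs (3 px by default, `exclusion_dilate_px`) as the
region excluded from cytoplasm — a perinuclear exclusion buffer. Nuclear
means still come from the un-dilated ROIs; the cytoplasmic definition above
is unchanged, only its "nuclear region" argument is the buffered one.

Normalization divides the mean nuclear intensity of well cells by that of
cells in the surrounding unconfined ring (annulus from R + 20 µm to
R + 120 µm, configurable); 1.0 means "equal to unconfined". Both N:C and
normalized intensity are checked to be invariant under a global ×3 gain.

## Actin architecture

The radial profile averages bilinear samples along 8 full diameters at
22.5° steps (16 half-lines after folding), at 1 px spacing. Eight diameters
through the centre are the natural reading of "8 intersecting lines" and make
the profile invariant (to interpolation error) under rotation by π/8.
Classification works on the folded 0..R profile with centre mean C (inner
30% of R), edge mean E (outer 20%) and mid mean M:

* coefficient of variation < 0.15 → **uniform**;
* else `E / max(C, M) > 1.25` → **peripheral**;
* else `C / max(E, M) > 1.25` → **central**;
* else the larger of C and E wins, flagged *weak*.

The thresholds replace a qualitative visual call with explicit criteria; both
are exposed as parameters. All criteria are ratios of means of the
background-subtracted profile, so the label is gain-invariant, and offsets
smaller than the contrast margin are removed by background subtraction.

## PDX1-high cells and aggregates

High-cell calling is deliberately a knob: thresholds of nuclear accumulation
drive reported positive-cell frequencies, so `mean + k·sd` (default k = 2),
percentile and absolute rules are all available and the applied threshold is
reported with the flags. Aggregates are single-linkage components of flagged
centroids with link distance 30 µm (~two cell diameters) and at least 5
members; geometry (convex-hull area, equivalent-circle diameter,
circularity) is computed on member centroids. The implementation rides on
`hclust(method = "single")` cut at the link radius and is verified against a
brute-force union-find oracle.

A geometric caveat worth knowing: the convex hull of n points scattered in a
disc is strictly inside the disc, so the equivalent diameter of an aggregate
is biased low at small n (~25% at 35 cells, ~8% at 90). At the monolayer
seeding density the generator emulates (5000 cells/mm², i.e.
5×10⁵ cells/cm²), a 150 µm aggregate holds ~90 cells and the recovered
diameter lands within 15% of truth.

## The synthetic generator

`render_microwell_image()` draws each nucleus's zone from the configured
radial density profile, places it uniformly within the zone annulus under a
pairwise separation constraint (rejection sampling; fraction 0.6 of summed
radii by default, i.e. overlapping projections as in real dense colonies),
and renders: DAPI as isotropic Gaussian blobs (σ = radius/2, truncated at
3σ); TF channels as `tf_nuclear_mean` over each nucleus disc on a cytoplasm
plateau of `tf_nuclear_mean / tf_nc_ratio` over the colony; actin as a flat
base plus a Gaussian ring at 0.95 R (width 0.08 R) for peripheral or a
Gaussian dome (width 0.3 R) for central; additive background; additive
Gaussian read noise. An unconfined control ring (monolayer at 1500 cells/mm²
with its own nuclear TF level) surrounds the well beyond a 20 µm gap. A
fixed seed makes renders bit-reproducible, and every render returns the full
ground truth (positions, radii, zones, true N:C, class).

Generator-side conventions chosen once and documented here:

* nucleus radii come from a ±2 sd truncated normal (mean 5, sd 0.5 µm) — PE
  nuclei have a tight size distribution and unphysical tails would only test
  the debris filter;
* nuclei keep 1 µm clear of zone boundaries (`zone_margin_um`) so truth zone
  labels are unambiguous at sub-pixel centroid accuracy; zone *frequencies*
  are untouched because the zone is drawn before the position;
* default colony sizes (50 / 160 / 300 cells for 150 / 300 / 500 µm) encode
  the observed decrease of colony density with well diameter;
* the default monolayer density is the 5×10⁵ cells/cm² seeding density.

What the generator does **not** emulate: optical PSF blur beyond the
Gaussian nucleus model, photobleaching, shading/vignetting, autofluorescence
texture, cell shape variation, or 3D structure (it renders 2D projections
only — the bulged multilayer morphology of small wells is out of reach).
Passing recovery tests on these renders therefore demonstrates correctness
of the measurement code under the stated image model, not robustness to
every real-microscope artefact; the external-label entry point exists
precisely so curated segmentations of real data can be injected.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: closed-form
zone boundaries; pixel-integration of noise-free renders for N:C; analytic
radial sections for profiles; a union-find oracle for clustering; and a
hand-computed sums-of-squares + `ptukey` oracle for ANOVA/Tukey. Scales were
chosen to exercise the claims while staying desk-sized:

* exact counting/zoning: 50 seeds × 3 diameters, noise-free. These wells use
  non-overlapping placement (separation 1.15× summed radii) at ~70% of the
  default density — the default density is geometrically unreachable without
  overlap, and overlapping projections make exact counting ill-posed for any
  segmenter, so the exactness claim is defined on the non-overlapping
  construct;
* N:C recovery: 100 wells at true ratios {1, 1.5, 2, 3} with noise at 5% of
  the nuclear mean (median error well under the 5% bound);
* actin classification: 3 classes × 3 diameters × 50 seeds, noise-free and at
  10% of the archetype amplitude;
* statistics: 2000 null ANOVA simulations for the type-I rate at α = 0.05.

The cohort simulator (`simulate_significance_cohort()`) reproduces the
study design — 21 / 13 / 9 wells at 150 / 300 / 500 µm plus an unconfined
control group — with N:C elevated (2.4 vs 1.5) only in the two smaller
diameters, and asks how often ANOVA + Tukey recovers exactly that pattern.
It is two-level by design: rendering 5300 wells per run is not what the
question needs, so the imaging estimation error is first *calibrated* by
rendering and fully quantifying a small set of wells, and cohort replicates
then draw per-well true values (between-well biological sd 0.15) plus
calibrated estimation noise and run the real test code. The biological
effect and variability values are the simulator's configured conditions, not
estimates; the calibration step is real imaging, so the simulated cohorts
inherit the pipeline's actual measurement error.

## Known limitations

* Overlapping nuclei merge in segmentation (no shape-model splitting); counts
  at realistic density run ~15% low, which cancels in ratio metrics but not
  in densities. Injected curated labels bypass this.
* The N:C definition shares one cytoplasmic mean across the colony; true
  per-cell cytoplasmic territories are not estimated.
* The actin classifier sees only the radial profile; azimuthally asymmetric
  architectures fold into one of the three classes.
* Statistics treat wells as independent units (the study's own design);
  nesting within experiments is not modelled.
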