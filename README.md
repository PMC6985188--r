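# wellquant

Quantitative image analysis for micropatterned pancreatic-endoderm cultures.

Directed differentiation of pluripotent stem cells toward beta cells passes
through a pancreatic-endoderm (PE) stage in which cells spontaneously form
dense, roughly circular aggregates of PDX1-high cells. Confining PE-stage
cells on circular adhesive microwells (150–500 µm islands surrounded by
non-adhesive agarose) makes this clustering controlled and reproducible, and
the readouts of interest are spatial: where cells densify inside a colony,
how much transcription factor accumulates in nuclei relative to cytoplasm,
and what radial architecture the F-actin cytoskeleton adopts. `wellquant`
implements that entire quantification layer for multi-channel
immunofluorescence rasters (DAPI / phalloidin / PDX1 / NKX6.1), together with
a seeded synthetic image generator that provides exact ground truth, so every
stage of the pipeline is testable without any microscope data.

## What it computes

* **Equal-area concentric zoning.** A well of radius R is split into K
  annuli of identical area with boundaries `r_k = R * sqrt(k / K)` (K = 4 by
  default). Nuclei are segmented from DAPI (Otsu threshold +
  distance-transform watershed), assigned to zones by centroid radial
  position, and reported as per-zone densities in cells/mm².
* **Nuclear and N:C intensity metrics.** Per-nucleus mean transcription
  factor intensity (nuclear cross-sectional area as the volume proxy); the
  nuclear-to-cytoplasmic ratio `N:C = mean nuclear intensity / mean
  cytoplasmic intensity`, where the cytoplasmic total is the channel total
  over the actin-defined tissue mask minus the total over nuclear regions;
  and normalization of well nuclear intensity to the surrounding unconfined
  monolayer control, all after per-channel background subtraction.
* **Radial actin architecture.** The phalloidin intensity profile averaged
  over 8 diameters through the well centre (bilinear sampling, folded to
  0..R), classified as `uniform` (flat profile), `peripheral` (edge-peaked;
  the purse-string contractile-ring signature) or `central` (centre-peaked)
  from coefficient-of-variation and edge/centre contrast criteria.
* **PDX1-high cells and aggregates.** Threshold rules (mean + k·sd,
  percentile, absolute) flag high cells; single-linkage grouping of flagged
  centroids yields aggregates with convex-hull area, equivalent-circle
  diameter and circularity 4πA/P².
* **Comparison statistics.** One-way ANOVA with Tukey HSD across well
  diameters, Student's t tests, the confocal-vs-epifluorescence modality
  consistency control (constant per-cell intensity ratio), and a cohort
  simulator for the diameter significance pattern at the study group sizes
  (21 / 13 / 9 wells for 150 / 300 / 500 µm).

## Worked example

```r
library(wellquant)

spec <- synthetic_well_spec(well_diameter = 150, tf_nc_ratio = 2,
                            actin_class = "peripheral", noise_sd = 5, seed = 42)
r <- render_microwell_image(spec)      # image + ground truth
q <- quantify_well(r$image, well_radius = 75)
q
q$zone_summary
q$nc[["tf1"]]
q$actin_class
```

prints

```
<well_quant> R = 75 um: 41 nuclei in well, 133 in control; actin peripheral
  zone count area_um2 density_cells_mm2
1    1     8 4417.865          1810.830
2    2    16 4417.865          3621.659
3    3    12 4417.865          2716.244
4    4     5 4417.865          1131.768
[1] 2.001421
<actin_class> peripheral (C=37.47, E=78.47, M=37.91, cv=0.396)
```

The four zones have identical area (4417.9 µm² for a 150 µm well), densities
are highest in the inner zones where the generator concentrated the nuclei,
the colony N:C ratio recovers the configured value of 2 to 0.05%, and the
edge-peaked actin profile is labelled peripheral (edge mean 78.5 vs centre
37.5 a.u.). Note the well reports 41 nuclei from 50 generated: at realistic
colony density the generator deliberately lets nuclei overlap in projection,
and overlapping pairs merge in segmentation — the exact-count guarantees hold
on non-overlapping renders (see the methods vignette).

The `analysis/` directory holds the narrative workflow built on the same
functions: `01_simulate.R` (demo imaging cohort), `02_quantify.R` (zone
densities, N:C, normalization, ANOVA across diameters),
`03_actin_architecture.R` (architecture distribution over timepoints),
`04_clusters.R` (PDX1-high aggregate detection), `05_stats.R` (modality
control and cohort simulation). Each writes its tables under `results/`.

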