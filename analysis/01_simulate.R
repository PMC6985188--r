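#!/usr/bin/env Rscript
# Simulate a demonstration imaging dataset: a 12-well micropattern cohort
# (150/300/500 um diameters, mixed actin architectures) plus one unconfined
# monolayer field with a spontaneous PDX1-high aggregate. Writes multi-page
# TIFFs with ground-truth sidecars under results/simulated/.

suppressMessages(library(wellquant))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260929L

wells <- expand.grid(diameter = c(150, 300, 500),
                     actin = c("uniform", "peripheral", "central"))
wells <- wells[rep(seq_len(nrow(wells)), length.out = 12), ]

for (i in seq_len(nrow(wells))) {
  sp <- synthetic_well_spec(well_diameter = wells$diameter[i],
                            actin_class = as.character(wells$actin[i]),
                            tf_nc_ratio = c(tf1 = 2, tf2 = 1.5),
                            seed = seed + i)
  r <- render_microwell_image(sp)
  write_synthetic_bundle(r, out, prefix = sprintf("well%02d", i))
  cat(sprintf("well%02d: %3.0f um, %-10s %3d nuclei\n",
              i, wells$diameter[i], wells$actin[i], sp$n_cells))
}

mono <- render_monolayer_image(
  synthetic_monolayer_spec(field_size = 700, n_clusters = 1,
                           high_fraction = 0.02, seed = seed))
write_synthetic_bundle(mono, out, prefix = "monolayer01")
cat(sprintf("monolayer01: %d cells, %d flagged high in truth\n",
            nrow(mono$truth$cells), sum(mono$truth$cells$high)))
cat("wrote", length(list.files(out)), "files to", out, "\n")
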