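test_that("identical spec and seed reproduce rasters and truth bit for bit", {
  sp <- quick_well_spec(seed = 42, noise_sd = 2)
  a <- render_microwell_image(sp)
  b <- render_microwell_image(sp)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
})

test_that("an empty well renders as pure background before noise", {
  sp <- quick_well_spec(seed = 1, n_cells = 0, control_density = 0)
  r <- render_microwell_image(sp, return_clean = TRUE)
  for (ch in r$clean$channels)
    expect_true(all(ch == sp$background_level))
})

test_that("noise-free rendered N:C integrates to the specified ratio", {
  sp <- quick_well_spec(seed = 5, tf_nc_ratio = 2, n_cells = 20)
  r <- render_microwell_image(sp, return_clean = TRUE)
  tf <- r$clean$channels$tf1 - sp$background_level
  px <- sp$pixel_size
  g <- list(x = outer(rep(1, nrow(tf)), (seq_len(ncol(tf)) - 1) * px),
            y = outer((seq_len(nrow(tf)) - 1) * px, rep(1, ncol(tf))))
  tr <- r$truth$nuclei[r$truth$nuclei$region == "well", ]
  # pixel-integrated nuclear mean over the true nucleus discs
  nuc_px <- matrix(FALSE, nrow(tf), ncol(tf))
  for (i in seq_len(nrow(tr)))
    nuc_px <- nuc_px | ((g$x - tr$x_um[i])^2 + (g$y - tr$y_um[i])^2
                        <= tr$radius_um[i]^2)
  w <- r$truth$well
  colony <- (g$x - w$cx)^2 + (g$y - w$cy)^2 <= w$R^2
  nuc_mean <- mean(tf[nuc_px])
  cyto_mean <- mean(tf[colony & !nuc_px])
  expect_true(all(tr$radius_um / px >= 4))
  expect_lt(abs(nuc_mean / cyto_mean - 2) / 2, 0.03)
})

test_that("truth zone counts sum to n_cells and follow the radial profile", {
  prof <- c(0.4, 0.3, 0.2, 0.1)
  n <- 30L; n_draws <- 200
  counts <- matrix(0, n_draws, 4)
  for (s in seq_len(n_draws)) {
    sp <- quick_well_spec(seed = 1000 + s, n_cells = n, control_density = 0,
                          radial_density_profile = prof)
    r <- render_microwell_image(sp, channels = "dapi")
    expect_identical(sum(r$truth$zone_counts), n)
    counts[s, ] <- r$truth$zone_counts
  }
  shares <- colSums(counts) / (n * n_draws)
  se <- sqrt(prof * (1 - prof) / (n * n_draws))
  expect_true(all(abs(shares - prof) <= 3 * se))
})

test_that("packing failure raises an informative error", {
  sp <- quick_well_spec(seed = 1, n_cells = 500, max_retries = 50)
  expect_error(render_microwell_image(sp, channels = "dapi"),
               "packing failure")
})

test_that("monolayer truth honours cluster geometry and flag bookkeeping", {
  # no clusters, no sporadic highs -> no flags
  sp0 <- synthetic_monolayer_spec(field_size = 400, cell_density = 1500,
                                  n_clusters = 0, high_fraction = 0, seed = 2)
  r0 <- render_monolayer_image(sp0)
  expect_false(any(r0$truth$cells$high))

  # one 150 um cluster: every high cell within 75 um of its centre
  sp1 <- synthetic_monolayer_spec(field_size = 500, cell_density = 2000,
                                  n_clusters = 1, high_fraction = 0, seed = 3)
  r1 <- render_monolayer_image(sp1)
  tr <- r1$truth$cells
  ctr <- r1$truth$cluster_centers
  expect_identical(nrow(ctr), 1L)
  hi <- tr[tr$high, ]
  d <- sqrt((hi$x_um - ctr$x_um)^2 + (hi$y_um - ctr$y_um)^2)
  expect_true(all(d <= 75))
  expect_gt(nrow(hi), 0)

  # clusters that cannot fit are refused
  expect_error(render_monolayer_image(
    synthetic_monolayer_spec(field_size = 100, cluster_diameter = 150,
                             n_clusters = 1, seed = 1)),
    "do not fit")
})

test_that("poisson sampling mode gives a density-consistent count", {
  sp <- synthetic_monolayer_spec(field_size = 1000, cell_density = 2000,
                                 sampling = "poisson", n_clusters = 0,
                                 high_fraction = 0, seed = 7)
  r <- render_monolayer_image(sp)
  n <- nrow(r$truth$cells)
  expect_lt(abs(n - 2000), 4 * sqrt(2000))
})

test_that("modality pair is exact at unit gain and scales linearly", {
  sp <- quick_well_spec(seed = 9, n_cells = 15, noise_sd = 0)
  pair1 <- render_modality_pair(sp, gain = 1, extra_noise_sd = 0)
  expect_identical(pair1$image1$channels, pair1$image2$channels)

  pair <- render_modality_pair(sp, gain = 0.5, extra_noise_sd = 0)
  tr <- pair$truth$nuclei[pair$truth$nuclei$region == "well", ]
  px <- sp$pixel_size
  m1 <- pair$image1$channels$tf1
  m2 <- pair$image2$channels$tf1
  g <- list(x = outer(rep(1, nrow(m1)), (seq_len(ncol(m1)) - 1) * px),
            y = outer((seq_len(nrow(m1)) - 1) * px, rep(1, ncol(m1))))
  ratios <- vapply(seq_len(nrow(tr)), function(i) {
    sel <- (g$x - tr$x_um[i])^2 + (g$y - tr$y_um[i])^2 <= tr$radius_um[i]^2
    mean(m2[sel]) / mean(m1[sel])
  }, numeric(1))
  expect_true(all(abs(ratios - 0.5) < 1e-12))
  expect_error(render_modality_pair(sp, gain = 0), "gain")
})

test_that("a 150-cell well yields 150 paired cells for the modality control", {
  sp <- quick_well_spec(seed = 3, well_diameter = 300, n_cells = 150,
                        control_density = 0, min_separation_frac = 0.9)
  pair <- render_modality_pair(sp, gain = 0.5, extra_noise_sd = 1)
  expect_identical(sum(pair$truth$nuclei$region == "well"), 150L)
})

test_that("a rendered bundle round-trips through TIFF and CSV", {
  sp <- quick_well_spec(seed = 4, n_cells = 8, control_density = 0)
  r <- render_microwell_image(sp)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_bundle(r, dir, prefix = "w1")
  expect_true(all(file.exists(paths)))
  img <- read_image_tiff(paths[["tiff"]])
  expect_identical(names(img$channels), names(r$image$channels))
  expect_equal(img$pixel_size, sp$pixel_size)
  # 32-bit float pages: values preserved to single precision
  expect_lt(max(abs(img$channels$dapi - r$image$channels$dapi)), 1e-3)
  tr <- utils::read.csv(paths[["truth"]])
  expect_identical(nrow(tr), nrow(r$truth$nuclei))
})
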