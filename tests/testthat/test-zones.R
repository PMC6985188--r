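test_that("equal-area zone boundaries follow the closed form", {
  z <- equal_area_zones(75, 4)
  expect_equal(z$boundaries, 75 * sqrt((1:4) / 4), tolerance = 1e-12)
  expect_equal(z$boundaries, c(37.5, 53.033, 64.952, 75.0), tolerance = 1e-4)
  expect_equal(equal_area_zones(250, 4)$boundaries,
               c(125, 176.777, 216.506, 250), tolerance = 1e-5)
  expect_equal(equal_area_zones(123, 1)$boundaries, 123)
  # annulus areas analytically equal
  for (K in c(2, 5, 8)) {
    z <- equal_area_zones(90, K)
    areas <- diff(c(0, z$boundaries^2)) * pi
    expect_true(all(abs(areas - z$area_um2) / z$area_um2 < 1e-9))
  }
  expect_error(equal_area_zones(75, 0), "K")
  expect_error(equal_area_zones(-1, 4), "R")
})

test_that("zone assignment uses half-open annuli with the edge in zone K", {
  w <- well_geometry(0, 0, 75)
  z <- equal_area_zones(75, 4)
  pts <- data.frame(
    x_um = c(0, 70, 37.5, 75, 80),
    y_um = 0
  )
  rec <- assign_zones(pts, w, z)
  expect_identical(rec$zone, c(1L, 4L, 2L, 4L, NA))
  expect_identical(rec$outside, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(rec$r_um, c(0, 70, 37.5, 75, 80))
})

test_that("zone counts are conserved and densities use cells per mm2", {
  w <- well_geometry(0, 0, 75)
  z <- equal_area_zones(75, 4)
  set.seed(1)
  th <- runif(60, 0, 2 * pi); r <- sqrt(runif(60)) * 85
  rec <- assign_zones(data.frame(x_um = r * cos(th), y_um = r * sin(th)), w, z)
  dens <- zone_densities(rec, z)
  expect_identical(sum(dens$count) + sum(rec$outside), 60L)

  rec10 <- assign_zones(
    data.frame(x_um = c(rep(10, 10), rep(45, 10), rep(60, 10), rep(70, 10)),
               y_um = 0), w, z)
  d <- zone_densities(rec10, z)
  expect_equal(d$count, rep(10L, 4))
  expect_equal(d$density_cells_mm2, rep(2263.537, 4), tolerance = 1e-6)

  empty <- zone_densities(assign_zones(data.frame(x_um = numeric(0),
                                                  y_um = numeric(0)), w, z), z)
  expect_true(all(empty$density_cells_mm2 == 0))
})

test_that("generated zone occupancies recover the density profile", {
  prof <- c(0.4, 0.3, 0.2, 0.1)
  n <- 100; n_seeds <- 50
  shares <- matrix(0, n_seeds, 4)
  for (s in seq_len(n_seeds)) {
    sp <- quick_well_spec(seed = 500 + s, n_cells = n, control_density = 0,
                          radial_density_profile = prof,
                          min_separation_frac = 0.6)
    r <- render_microwell_image(sp, channels = "dapi")
    tr <- r$truth$nuclei
    w <- well_geometry(r$truth$well$cx, r$truth$well$cy, r$truth$well$R)
    rec <- assign_zones(tr, w, equal_area_zones(75, 4))
    # assignment must agree with generator bookkeeping
    expect_identical(tabulate(rec$zone, 4), r$truth$zone_counts)
    shares[s, ] <- r$truth$zone_counts / n
  }
  est <- colMeans(shares)
  se <- sqrt(prof * (1 - prof) / (n * n_seeds))
  expect_true(all(abs(est - prof) <= 3 * se))
})

test_that("nuclear intensities are ROI means with linear response", {
  labels <- matrix(0L, 20, 20)
  labels[3:6, 3:6] <- 1L
  labels[12:15, 12:15] <- 2L
  rois <- segment_nuclei(matrix(0, 20, 20), 1, labels = labels, min_area = 0)
  ch <- matrix(5, 20, 20); ch[12:15, 12:15] <- 11
  m <- nuclear_intensities(ch, rois)
  expect_equal(unname(m), c(5, 11))
  expect_equal(unname(nuclear_intensities(2 * ch, rois)), 2 * unname(m))
  expect_error(nuclear_intensities(ch, wellquant:::empty_rois(c(20, 20))),
               "no ROIs")
})

test_that("N:C ratio follows the cytoplasm-total definition exactly", {
  # tissue mask 100 px with total 10000; one nucleus of 20 px totalling 3000
  # -> cytoplasmic mean (10000-3000)/80 = 87.5; nuclear mean 150; N:C 1.714
  ch <- matrix(0, 10, 20)
  mask <- matrix(FALSE, 10, 20); mask[1:10, 1:10] <- TRUE
  labels <- matrix(0L, 10, 20); labels[1:4, 1:5] <- 1L
  ch[mask] <- 7000 / 80
  ch[labels == 1L] <- 150
  rois <- segment_nuclei(matrix(0, 10, 20), 1, labels = labels, min_area = 0)
  res <- nc_ratio(ch, rois, mask)
  expect_equal(res$cyto_mean, 87.5)
  expect_equal(res$colony, 150 / 87.5, tolerance = 1e-12)
  expect_equal(unname(res$per_nucleus), 150 / 87.5)

  # uniform intensity -> exactly 1
  u <- matrix(3.7, 10, 20)
  expect_equal(nc_ratio(u, rois, mask)$colony, 1.0)

  # positive gain leaves N:C unchanged
  expect_equal(nc_ratio(3 * ch, rois, mask)$colony, res$colony)

  # no cytoplasm -> error
  allnuc <- matrix(1L, 10, 20)
  rall <- segment_nuclei(matrix(0, 10, 20), 1, labels = allnuc, min_area = 0)
  expect_error(nc_ratio(ch, rall, matrix(TRUE, 10, 20)), "no cytoplasmic")
})

test_that("normalization to the unconfined control is a ratio of means", {
  r <- normalize_to_control(300, 150, background = 50)
  expect_equal(r$normalized, 2.5)
  expect_equal(normalize_to_control(c(2, 4), c(2, 4))$normalized, 1.0)
  g <- 7.3
  expect_equal(normalize_to_control(g * c(120, 140), g * c(100, 90))$normalized,
               normalize_to_control(c(120, 140), c(100, 90))$normalized)
  expect_error(normalize_to_control(1, numeric(0)), "empty")
  expect_error(normalize_to_control(100, 40, background = 50), "control mean")
})

test_that("discretized zone areas track the analytic equal areas", {
  px <- 0.65
  for (R in c(50 * px, 75, 120)) {   # >= 50 px radius
    w <- well_geometry(150, 150, R)
    z <- equal_area_zones(R, 4)
    n <- ceiling(300 / px)
    areas <- zone_pixel_areas(c(n, n), w, z, px) * px^2
    expect_true(all(abs(areas - z$area_um2) / z$area_um2 < 0.02))
  }
})
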